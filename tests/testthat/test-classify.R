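# a features object built directly, bypassing the TFR path
toy_features <- function(x, y, positive = "perceived") {
  structure(list(x = as.matrix(x), y = factor(y), times = NA,
                 band = c(60, 75), roster = "OZ", positive = positive,
                 trial_id = seq_along(y),
                 excluded = tibble::tibble(trial_id = integer(),
                                           reason = character())),
            class = "gs_features")
}

test_that("balanced accuracy identities hold exactly", {
  expect_equal(balanced_accuracy(98.96, 93.34), 96.15)
  expect_equal(balanced_accuracy(99.34, 91.78), 95.56)
  m <- classification_metrics(
    truth = c("perceived", "perceived", "unperceived", "unperceived"),
    pred = c("perceived", "unperceived", "unperceived", "perceived"))
  expect_equal(m$balanced, (m$sensitivity + m$specificity) / 2)
  expect_equal(m$accuracy, 50)
})

test_that("feature extraction averages the roster and band correctly", {
  # hand-computable 2-channel, 2-bin, 3-timepoint toy
  power <- array(0, c(2, 2, 2, 3))
  power[1, 1, , ] <- 1; power[1, 2, , ] <- 3    # trial 1: mean 2
  power[2, 1, , ] <- 2; power[2, 2, , ] <- 6    # trial 2: mean 4
  tf <- gammasync:::new_tfr(power = power, coeffs = NULL, freqs = c(60, 61),
                            times = c(9, 10, 11), sr = 100,
                            labels = c("perceived", "unperceived"),
                            trial_id = 1:2,
                            channel_labels = c("OZ", "POZ"),
                            normalized = TRUE)
  fm <- extract_features(tf, band = c(60, 75), window = c(9, 11),
                         roster = c("OZ", "POZ"))
  expect_equal(dim(fm$x), c(2, 3))
  expect_true(all(fm$x[1, ] == 2))
  expect_true(all(fm$x[2, ] == 4))
  # collapse_time gives one scalar per trial
  fm2 <- extract_features(tf, band = c(60, 75), window = c(9, 11),
                          roster = c("OZ", "POZ"), collapse_time = TRUE)
  expect_equal(dim(fm2$x), c(2, 1))
  # constant power propagates as constant features
  tf$power[] <- 2
  fm3 <- extract_features(tf, band = c(60, 75), window = c(9, 11),
                          roster = c("OZ", "POZ"))
  expect_true(all(fm3$x == 2))
})

test_that("trials with responses inside the feature window are excluded", {
  power <- array(1, c(4, 1, 2, 3))
  tf <- gammasync:::new_tfr(power = power, coeffs = NULL, freqs = c(60, 61),
                            times = c(9, 10, 11), sr = 100,
                            labels = c("perceived", "perceived",
                                       "unperceived", "unperceived"),
                            trial_id = 1:4, channel_labels = "OZ",
                            normalized = TRUE)
  beh <- behaviour_log(1:4, c(10.2, 5, NA, NA),
                       perceived = c(TRUE, TRUE, FALSE, FALSE),
                       correct = c(TRUE, TRUE, FALSE, FALSE))
  fm <- extract_features(tf, band = c(60, 75), window = c(9, 12),
                         roster = "OZ", behaviour = beh)
  expect_equal(fm$excluded$trial_id, 1)
  expect_equal(length(fm$y), 3)
  # an exclusion that empties a class is an error
  beh2 <- behaviour_log(1:4, c(10.2, 9.5, NA, NA),
                        perceived = c(TRUE, TRUE, FALSE, FALSE),
                        correct = c(TRUE, TRUE, FALSE, FALSE))
  expect_error(extract_features(tf, band = c(60, 75), window = c(9, 12),
                                roster = "OZ", behaviour = beh2),
               "emptied")
})

test_that("a separable two-cluster problem decodes perfectly", {
  set.seed(1)
  n <- 30
  x <- rbind(matrix(rnorm(n * 3, 10), n),
             matrix(rnorm(n * 3, -10), n))
  fm <- toy_features(x, rep(c("perceived", "unperceived"), each = n))
  rep_out <- train_eval_cv(fm, repetitions = 5, seed = 2)
  g <- glance(rep_out)
  expect_equal(g$accuracy_mean, 100)
  expect_equal(g$balanced_mean, 100)
  expect_equal(g$balanced_sd, 0)
})

test_that("pure-noise features decode at chance", {
  set.seed(3)
  fm <- toy_features(matrix(rnorm(200 * 4), 200),
                     rep(c("perceived", "unperceived"), 100))
  g <- glance(train_eval_cv(fm, repetitions = 10, seed = 4))
  expect_gt(g$accuracy_mean, 42)
  expect_lt(g$accuracy_mean, 58)
})

test_that("cross-validation is deterministic under a fixed seed", {
  set.seed(5)
  x <- matrix(rnorm(40 * 3), 40)
  x[1:20, 1] <- x[1:20, 1] + 1.5
  fm <- toy_features(x, rep(c("perceived", "unperceived"), each = 20))
  a <- train_eval_cv(fm, repetitions = 4, seed = 7)
  b <- train_eval_cv(fm, repetitions = 4, seed = 7)
  expect_identical(tidy(a), tidy(b))
  expect_error(train_eval_cv(toy_features(x[1:22, ],
                                          c(rep("perceived", 20),
                                            rep("unperceived", 2))),
                             k_folds = 3), "fewer")
})

test_that("no information leaks from test folds", {
  set.seed(8)
  n <- 36
  y <- rep(c("perceived", "unperceived"), each = n / 2)
  # canary 1: a feature equal to the label decodes perfectly
  x_label <- cbind(as.numeric(y == "perceived"), rnorm(n))
  g1 <- glance(train_eval_cv(toy_features(x_label, y), repetitions = 3,
                             seed = 1))
  expect_equal(g1$accuracy_mean, 100)
  # canary 2: the same feature globally shuffled carries no information and
  # must score near chance on held-out folds
  x_shuf <- cbind(sample(x_label[, 1]), rnorm(n))
  g2 <- glance(train_eval_cv(toy_features(x_shuf, y), repetitions = 10,
                             seed = 2))
  expect_lt(g2$accuracy_mean, 70)
})

test_that("more synthetic effect never hurts decoding", {
  set.seed(9)
  accs <- vapply(c(0, 1, 2.5), function(effect) {
    x <- matrix(rnorm(60 * 5), 60)
    x[1:30, ] <- x[1:30, ] + effect
    glance(train_eval_cv(toy_features(
      x, rep(c("perceived", "unperceived"), each = 30)),
      repetitions = 5, seed = 10))$balanced_mean
  }, 0)
  expect_true(all(diff(accs) > -5))   # monotone up to Monte-Carlo noise
  expect_gt(accs[3], 95)
})

test_that("permutation test gives extreme p for real effects, ~1 for none", {
  set.seed(11)
  n <- 24
  y <- rep(c("perceived", "unperceived"), each = n / 2)
  x_strong <- cbind(c(rnorm(n / 2, 8), rnorm(n / 2, -8)), rnorm(n))
  pt <- permutation_test(toy_features(x_strong, y), n_permutations = 999,
                         seed = 12)
  expect_equal(pt$p_value, 1 / 1000)
  expect_equal(pt$observed, 100)

  # uninformative features score below chance under leave-one-out (the
  # majority-flip pathology), so most permutations beat the observed score
  # and the p-value is large, never significant
  x_null <- matrix(rnorm(n * 2, sd = 1e-6), n)
  pt2 <- permutation_test(toy_features(x_null, y),
                          n_permutations = 199, seed = 13)
  expect_gt(pt2$p_value, 0.3)
  expect_lte(pt2$p_value, 1)

  expect_error(permutation_test(toy_features(x_strong, y),
                                n_permutations = 10), "100")
  expect_error(permutation_test(toy_features(x_strong,
                                             rep("perceived", n)),
                                n_permutations = 199), "single-class")
})

test_that("subject eligibility filters on unperceived-trial counts", {
  logs <- list(
    s1 = behaviour_log(1:20, runif(20, 2, 8), perceived = rep(TRUE, 20),
                       correct = rep(TRUE, 20)),
    s2 = behaviour_log(1:20, c(runif(9, 2, 8), rep(NA, 11)),
                       perceived = c(rep(TRUE, 9), rep(FALSE, 11)),
                       correct = c(rep(TRUE, 9), rep(FALSE, 11))),
    s3 = behaviour_log(1:20, c(runif(11, 2, 8), rep(NA, 9)),
                       perceived = c(rep(TRUE, 11), rep(FALSE, 9)),
                       correct = c(rep(TRUE, 11), rep(FALSE, 9))))
  el <- subject_eligibility(logs, min_unperceived = 10)
  expect_equal(el$eligible, c(FALSE, TRUE, FALSE))
  expect_equal(el$n_unperceived, c(0, 11, 9))
  # threshold 0 admits everyone
  expect_true(all(subject_eligibility(logs, 0)$eligible))
})

test_that("a cohort with the study's eligibility pattern reproduces 6 of 14", {
  # construct 14 subjects: 6 with >= 10 unperceived trials, 8 below
  set.seed(14)
  n_unp <- c(rep(c(12, 15, 11, 20, 10, 13), 1), rep(c(2, 5, 8, 9), 2))
  logs <- lapply(seq_along(n_unp), function(i) {
    k <- n_unp[i]
    behaviour_log(1:60, c(runif(60 - k, 2, 8), rep(NA, k)),
                  perceived = c(rep(TRUE, 60 - k), rep(FALSE, k)),
                  correct = c(rep(TRUE, 60 - k), rep(FALSE, k)))
  })
  names(logs) <- paste0("s", seq_along(logs))
  el <- subject_eligibility(logs, min_unperceived = 10)
  expect_equal(sum(el$eligible), 6)
  expect_equal(nrow(el), 14)
})
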