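#' Balanced accuracy from sensitivity and specificity
#'
#' `(sensitivity + specificity) / 2`, on whatever scale its arguments use
#' (here conventionally percent).
#'
#' @param sensitivity,specificity numeric.
#' @return numeric balanced accuracy.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (recall of the positive class), specificity and
#' balanced accuracy, in percent, from pooled predictions.
#'
#' @param truth,pred factors or characters of equal length.
#' @param positive the positive-class label (default `"perceived"`).
#' @return one-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `balanced` (all %).
#' @export
classification_metrics <- function(truth, pred, positive = "perceived") {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  tibble::tibble(accuracy = 100 * (tp + tn) / length(truth),
                 sensitivity = sens, specificity = spec,
                 balanced = balanced_accuracy(sens, spec))
}

#' Extract decoding features from a normalized TFR
#'
#' Per trial, power is averaged over the roster channels and the band's
#' frequency bins; the time points inside `window` are retained as the
#' feature vector (or collapsed to one scalar with `collapse_time = TRUE`).
#' Perceived trials whose motor response falls inside the feature window
#' are excluded so that response-related activity cannot leak into the
#' features; pass the behaviour log to enable that screen.
#'
#' @param tfr a normalized `gs_tfr` (epochs locked so that epoch time equals
#'   the within-trial time of `window`, e.g. movie-onset-locked).
#' @param band `c(lo, hi)` in Hz, or a band name from `bands`.
#' @param window numeric length-2 (s), e.g. `c(9, 12)` for the final 3 s of
#'   a 12 s movie.
#' @param roster channel labels to average over; defaults to the
#'   occipito-parietal roster intersected with the available channels.
#' @param behaviour optional [behaviour_log()] used for the
#'   response-overlap exclusion.
#' @param positive label of the positive class (default `"perceived"`).
#' @param collapse_time average over time as well, one feature per trial.
#' @return a `gs_features` object: `x` (trials x features), `y` (factor),
#'   `times`, `band`, `roster`, `excluded` (tibble of excluded trials).
#' @export
extract_features <- function(tfr, band, window, roster = NULL,
                             behaviour = NULL, positive = "perceived",
                             collapse_time = FALSE) {
  stopifnot(inherits(tfr, "gs_tfr"), !is.null(tfr$power))
  if (!tfr$normalized)
    warning("features are usually extracted from baseline-normalized power")
  if (is.character(band)) {
    bs <- band_spec()
    if (!band %in% names(bs)) stop("unknown band name: ", band)
    band <- bs[[band]]
  }
  roster <- roster %||%
    intersect(occipitoparietal_roster(), tfr$channel_labels)
  ci <- match(roster, tfr$channel_labels)
  if (!length(ci) || anyNA(ci))
    stop("roster channels missing from the TFR")
  fsel <- which(tfr$freqs >= band[1] & tfr$freqs < band[2])
  tsel <- which(tfr$times >= window[1] & tfr$times <= window[2])
  if (!length(fsel)) stop("band contains no frequency bins")
  if (!length(tsel)) stop("window contains no time points")

  keep <- rep(TRUE, length(tfr$labels))
  excluded <- tibble::tibble(trial_id = integer(), reason = character())
  if (!is.null(behaviour)) {
    rt <- behaviour$response_time[match(tfr$trial_id, behaviour$trial_id)]
    overlap <- tfr$labels == positive & !is.na(rt) &
      rt >= window[1] & rt <= window[2]
    keep <- !overlap
    excluded <- tibble::tibble(trial_id = tfr$trial_id[overlap],
                               reason = "response inside feature window")
  }
  y <- factor(tfr$labels[keep])
  if (length(levels(y)) < 2)
    stop("a class was emptied by the response-overlap exclusion")
  x <- apply(tfr$power[keep, ci, fsel, tsel, drop = FALSE], c(1, 4), mean)
  if (collapse_time) x <- matrix(rowMeans(x), ncol = 1)
  if (any(!is.finite(x))) stop("features contain missing values")
  structure(
    list(x = x, y = y, times = if (collapse_time) NA else tfr$times[tsel],
         band = band, roster = roster, positive = positive,
         trial_id = tfr$trial_id[keep], excluded = excluded),
    class = "gs_features")
}

#' @export
print.gs_features <- function(x, ...) {
  cat(sprintf("<gs_features> %d trials x %d features (band %g-%g Hz)\n",
              nrow(x$x), ncol(x$x), x$band[1], x$band[2]))
  print(table(x$y))
  invisible(x)
}

# stratified fold assignment; every fold gets >= 1 trial of each class
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    if (length(idx) < k)
      stop("class '", cl, "' has ", length(idx), " trials, fewer than ", k,
           " folds; use fewer folds")
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

svm_scale <- function(x) apply(x, 2, sd) > 0

#' Cross-validated linear SVM evaluation
#'
#' The decoding harness: for each repetition, trials are split into
#' `k_folds` stratified folds at random; for every candidate `C` a linear
#' maximum-margin classifier (libsvm) is trained on each training split and
#' its predictions on the held-out fold are pooled into one confusion matrix
#' per repetition; the `C` with the best pooled balanced accuracy is
#' selected and its metrics recorded. Feature standardization is fitted on
#' the training folds only (no leakage into the held-out fold). Reported
#' metrics are means and SDs over repetitions.
#'
#' @param fm a `gs_features` object.
#' @param k_folds folds per repetition (default 3).
#' @param repetitions random re-splits (default 30).
#' @param C_grid regularization grid (default `10^(-3:3)`).
#' @param seed RNG seed controlling all fold assignments.
#' @return a `gs_clf_report`: per-repetition metrics plus their summary;
#'   see [tidy.gs_clf_report()] and [glance.gs_clf_report()].
#' @export
train_eval_cv <- function(fm, k_folds = 3, repetitions = 30,
                          C_grid = 10^(-3:3), seed = NULL) {
  stopifnot(inherits(fm, "gs_features"))
  scale_cols <- svm_scale(fm$x)
  with_seed(seed, {
    reps <- vector("list", repetitions)
    for (r in seq_len(repetitions)) {
      fold <- stratified_folds(fm$y, k_folds)
      best <- NULL
      for (C in C_grid) {
        pred <- factor(rep(NA_character_, length(fm$y)), levels = levels(fm$y))
        for (f in seq_len(k_folds)) {
          tr <- fold != f
          fit <- e1071::svm(fm$x[tr, , drop = FALSE], fm$y[tr],
                            kernel = "linear", cost = C, scale = scale_cols)
          pred[!tr] <- predict(fit, fm$x[!tr, , drop = FALSE])
        }
        m <- classification_metrics(fm$y, pred, fm$positive)
        if (is.null(best) || m$balanced > best$balanced)
          best <- dplyr::mutate(m, C = C)
      }
      reps[[r]] <- dplyr::mutate(best, repetition = r)
    }
    tab <- dplyr::bind_rows(reps)
    structure(list(repetitions = tab,
                   k_folds = k_folds, C_grid = C_grid,
                   n_trials = length(fm$y), band = fm$band),
              class = "gs_clf_report")
  })
}

#' @export
print.gs_clf_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<gs_clf_report> %d reps x %d-fold CV, %d trials, band %g-%g Hz\n",
              nrow(x$repetitions), x$k_folds, x$n_trials,
              x$band[1], x$band[2]))
  cat(sprintf(
    "  accuracy %.2f+-%.2f  sensitivity %.2f+-%.2f  specificity %.2f+-%.2f  balanced %.2f+-%.2f  (C = %g)\n",
    g$accuracy_mean, g$accuracy_sd, g$sensitivity_mean, g$sensitivity_sd,
    g$specificity_mean, g$specificity_sd, g$balanced_mean, g$balanced_sd,
    g$C_selected))
  invisible(x)
}

#' @rdname train_eval_cv
#' @param x a `gs_clf_report`.
#' @param ... unused.
#' @export
tidy.gs_clf_report <- function(x, ...) x$repetitions

#' @rdname train_eval_cv
#' @export
glance.gs_clf_report <- function(x, ...) {
  r <- x$repetitions
  tibble::tibble(
    accuracy_mean = mean(r$accuracy), accuracy_sd = sd(r$accuracy),
    sensitivity_mean = mean(r$sensitivity), sensitivity_sd = sd(r$sensitivity),
    specificity_mean = mean(r$specificity), specificity_sd = sd(r$specificity),
    balanced_mean = mean(r$balanced), balanced_sd = sd(r$balanced),
    C_selected = as.numeric(names(sort(table(r$C), decreasing = TRUE))[1]),
    n_repetitions = nrow(r))
}

# leave-one-out generalization accuracy (libsvm's internal n-fold CV with
# k = n, i.e. each trial held out once)
loo_accuracy <- function(x, y, cost = 1, scale_cols = svm_scale(x)) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost,
                    scale = scale_cols, cross = length(y))
  fit$tot.accuracy
}

#' Label-permutation significance of the decoder
#'
#' The observed score is the leave-one-out generalization accuracy of the
#' linear SVM on the true labels; each permutation reassigns the labels at
#' random and re-scores with the same leave-one-out scheme. Two p-values are
#' reported: the plug-in estimator
#' `(1 + #(permuted >= observed)) / (1 + n_permutations)`, and the
#' randomized (tie-broken) version `p_randomized = (#(permuted > observed) +
#' U * (1 + #(permuted == observed))) / (1 + n_permutations)` with
#' `U ~ Unif(0, 1)`. Leave-one-out accuracy is a coarse discrete score, so
#' permuted scores tie with the observed one often; ties make the plug-in
#' p-value conservative (super-uniform), while the randomized version is
#' exactly uniform under the null and is the one whose calibration the test
#' suite verifies.
#'
#' @param fm a `gs_features` object.
#' @param n_permutations at least 100 (default 999).
#' @param cost SVM regularization constant used throughout.
#' @param seed RNG seed for the permutations.
#' @return one-row tibble: `observed` (LOO accuracy, %), `p_value`,
#'   `p_randomized`, `n_permutations`.
#' @export
permutation_test <- function(fm, n_permutations = 999, cost = 1,
                             seed = NULL) {
  stopifnot(inherits(fm, "gs_features"))
  if (n_permutations < 100)
    stop("use at least 100 permutations")
  if (length(unique(fm$y)) < 2) stop("labels are single-class")
  scale_cols <- svm_scale(fm$x)
  with_seed(seed, {
    obs <- loo_accuracy(fm$x, fm$y, cost, scale_cols)
    gt <- 0L; eq <- 0L
    for (b in seq_len(n_permutations)) {
      score <- loo_accuracy(fm$x, sample(fm$y), cost, scale_cols)
      if (score > obs + 1e-9) gt <- gt + 1L
      else if (abs(score - obs) <= 1e-9) eq <- eq + 1L
    }
    tibble::tibble(observed = obs,
                   p_value = (1 + gt + eq) / (1 + n_permutations),
                   p_randomized = (gt + runif(1) * (1 + eq)) /
                     (1 + n_permutations),
                   n_permutations = n_permutations)
  })
}

#' Subject eligibility for decoding
#'
#' Subjects enter the decoding analysis only with enough unperceived trials
#' for honest cross-validation (default: at least 10).
#'
#' @param behaviour a tibble with a `subject` column and [behaviour_log()]
#'   columns, or a named list of behaviour logs.
#' @param min_unperceived minimum unperceived-trial count.
#' @return tibble: `subject`, `n_unperceived`, `eligible`.
#' @export
subject_eligibility <- function(behaviour, min_unperceived = 10) {
  if (is.list(behaviour) && !is.data.frame(behaviour)) {
    behaviour <- dplyr::bind_rows(
      lapply(behaviour, tibble::as_tibble), .id = "subject")
  }
  stopifnot("subject" %in% names(behaviour))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(behaviour), .data$subject),
    n_unperceived = sum(!.data$perceived, na.rm = TRUE), .groups = "drop")
  out$eligible <- out$n_unperceived >= min_unperceived
  out
}
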