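test_that("average reference zeroes the mean of good EEG channels only", {
  # hand-computable 3-channel toy with one BAD channel
  rec <- recording(rbind(c(1, 4), c(3, 8), c(100, 100)), sr = 500,
                   channel_labels = c("O1", "O2", "OZ"),
                   channel_kind = c("EEG", "EEG", "BAD"))
  out <- rereference_average(rec)
  expect_equal(out$data[1, ], c(-1, -2), ignore_attr = TRUE)
  expect_equal(out$data[2, ], c(1, 2), ignore_attr = TRUE)
  expect_equal(out$data[3, ], c(100, 100), ignore_attr = TRUE)  # untouched

  # already zero-mean data is unchanged; pairwise differences invariant
  rec2 <- recording(rbind(c(1, -2), c(-1, 2)), 500, c("O1", "O2"))
  out2 <- rereference_average(rec2)
  expect_equal(out2$data, rec2$data)
  rec3 <- generate_background(3, 1, 500, 1, 10, seed = 3,
                              channel_labels = c("O1", "OZ", "O2"))
  out3 <- rereference_average(rec3)
  expect_equal(out3$data[1, ] - out3$data[2, ],
               rec3$data[1, ] - rec3$data[2, ])
  expect_error(rereference_average(
    recording(matrix(0, 2, 4), 500, c("O1", "VEOG"),
              channel_kind = c("EEG", "EOG"))), "2 good EEG")
})

test_that("the band-pass filter has the advertised frequency response", {
  sr <- 500
  t <- seq(1 / sr, 60, by = 1 / sr)
  mk <- function(x) recording(matrix(x, 1), sr, "OZ")
  rms <- function(x) sqrt(mean(x^2))
  trim <- (10 * sr):(50 * sr)   # keep clear of convolution edges

  slow <- mk(sin(2 * pi * 0.1 * t))
  out <- bandpass(slow, 1, 100)
  expect_lt(rms(out$data[1, trim]), 0.1 * rms(slow$data[1, trim]))

  pass <- mk(sin(2 * pi * 40 * t))
  out2 <- bandpass(pass, 1, 100)
  expect_equal(rms(out2$data[1, trim]), rms(pass$data[1, trim]),
               tolerance = 0.1)

  dc <- mk(rep(50, length(t)))
  out3 <- bandpass(dc, 1, 100)
  expect_lt(mean(abs(out3$data[1, trim])), 1)

  # zero phase: a passband tone keeps its phase
  expect_gt(cor(out2$data[1, trim], pass$data[1, trim]), 0.999)
  expect_error(bandpass(pass, 1, 300), "Nyquist")
  expect_error(bandpass(pass, 100, 1), "highpass < lowpass")
})

test_that("epoching locks to events, labels conditions and drops edges", {
  sr <- 100
  rec <- recording(matrix(seq_len(2000), 1, byrow = TRUE), sr, "OZ")
  rec$events <- event_table(
    sample_index = c(10, 500, 1000, 1500),
    code = c("response", "response", "midpoint", "response"),
    trial_id = 1:4)
  ep <- epoch(rec, c("response", "midpoint"), -1.5, 0.5,
              label_map = c(response = "perceived",
                            midpoint = "unperceived"))
  # event at sample 10 cannot host a -1.5 s window: dropped and logged
  expect_equal(attr(ep, "n_dropped"), 1)
  expect_equal(dim(ep$data)[1], 3)
  expect_equal(ep$labels, c("perceived", "unperceived", "perceived"))
  expect_equal(dim(ep$data)[3], round(2 * sr) + 1)
  # time zero is the lock sample itself (0-based index 500 -> value 501)
  expect_equal(ep$data[1, 1, which(ep$times == 0)], 501)
  expect_error(epoch(rec, "movie_onset", -1, 1), "no events")
})

test_that("amplitude rejection removes exactly the offending trials", {
  ep <- toy_epochs(n_trials = 5, n_channels = 2, n_time = 100,
                   channel_labels = c("OZ", "VEOG"),
                   channel_kind = c("EEG", "EOG"))
  ep$data[3, 1, 50] <- 80          # one 80 uV EEG sample
  out <- reject_amplitude(ep, eeg_thresh = 75, eog_thresh = 100)
  expect_equal(dim(out$epochs$data)[1], 4)
  expect_equal(out$log$trial_id, 3)
  expect_equal(out$log$channel, "OZ")
  # thresholds Inf: identity
  out2 <- reject_amplitude(ep, Inf, Inf)
  expect_equal(dim(out2$epochs$data)[1], 5)
  # idempotent
  out3 <- reject_amplitude(out$epochs, 75, 100)
  expect_equal(out3$epochs$data, out$epochs$data)
  # EOG-only excursion is judged against the EOG threshold
  ep$data[2, 2, 10] <- 90
  out4 <- reject_amplitude(ep, 75, 100)
  expect_false(2 %in% out4$log$trial_id)
  ep$data[2, 2, 10] <- 150
  out5 <- reject_amplitude(ep, 75, 100)
  expect_true(2 %in% out5$log$trial_id)
  # everything rejected -> advisory error
  ep$data[] <- 500
  expect_error(reject_amplitude(ep, 75, 100), "review")
})

test_that("synthetic blinks are caught by the EOG screen exactly", {
  cfg <- synth_config("rotation", n_channels = 4, n_trials = 10, sr = 250,
                      blink_rate = 0.08, blink_amplitude = 150, seed = 31)
  ds <- generate_rotation_dataset(cfg)
  ep <- epoch(ds$recording, "movie_onset", 0, 12)
  out <- reject_amplitude(ep, eeg_thresh = Inf, eog_thresh = 100)
  # ground truth: which movie windows contain a blink
  onsets <- ds$events$sample_index[ds$events$code == "movie_onset"] / 250
  has_blink <- vapply(onsets, function(o)
    any(ds$truth$blink_times > o - 0.3 & ds$truth$blink_times < o + 12),
    TRUE)
  expect_setequal(out$log$trial_id, which(has_blink))
})

test_that("EOG regression removes a linear ocular contamination exactly", {
  set.seed(41)
  n_time <- 400
  clean <- matrix(rnorm(2 * n_time), 2)
  eog <- matrix(rnorm(2 * n_time), 2)    # two trials of EOG
  a <- array(0, c(2, 2, n_time))
  for (tr in 1:2) {
    a[tr, 1, ] <- clean[tr, ] + 0.3 * eog[tr, ]
    a[tr, 2, ] <- eog[tr, ]
  }
  ep <- epoch_set(a, 400, 0, (n_time - 1) / 400, "response",
                  labels = c("a", "a"), channel_labels = c("OZ", "VEOG"),
                  channel_kind = c("EEG", "EOG"))
  out <- correct_ocular_regression(ep)
  resid <- as.vector(out$data[, 1, ])
  expect_lt(abs(cor(resid, as.vector(eog))), 0.01)
  expect_equal(out$data[, 2, ], a[, 2, ])          # EOG untouched
  expect_gt(cor(resid, as.vector(clean)), 0.95)

  # orthogonal EOG leaves EEG essentially unchanged
  b <- a
  b[, 1, ] <- clean
  ep2 <- epoch_set(b, 400, 0, (n_time - 1) / 400, "response",
                   labels = c("a", "a"), channel_labels = c("OZ", "VEOG"),
                   channel_kind = c("EEG", "EOG"))
  out2 <- correct_ocular_regression(ep2)
  expect_equal(out2$data[, 1, ], b[, 1, ], tolerance = 0.1)

  ep$data[, 2, ] <- 0
  expect_error(correct_ocular_regression(ep), "variance")
})

test_that("trial selection applies rule intersections", {
  ep <- toy_epochs(n_trials = 4, n_time = 50)
  beh <- behaviour_log(1:4, c(0.5, 2, 5, 11.5),
                       perceived = c(TRUE, TRUE, TRUE, TRUE),
                       correct = c(TRUE, TRUE, FALSE, TRUE))
  out <- select_trials(ep, beh, response_window = c(1, 11))
  expect_equal(out$epochs$trial_id, c(2, 3))
  out2 <- select_trials(ep, beh, correct_only = TRUE)
  expect_equal(out2$epochs$trial_id, c(1, 2, 4))
  # intersection of both rules, checked against enumeration
  out3 <- select_trials(ep, beh, response_window = c(1, 11),
                        correct_only = TRUE)
  expect_equal(out3$epochs$trial_id, 2)
  expect_equal(sum(out3$counts$removed), 3)
  expect_error(select_trials(ep, beh, response_window = c(20, 30)), "every")
})

test_that("ERP averaging subtracts baselines and recovers injected peaks", {
  # identical trials: average equals any trial
  ep <- toy_epochs(n_trials = 3, n_channels = 1, n_time = 200,
                   channel_labels = "OZ", tmin = -0.25,
                   fill = function(tr, ch, i) sin(i / 20))
  avg <- erp_average(ep, c(-0.25, 0))
  base <- mean(ep$data[1, 1, ep$times >= -0.25 & ep$times <= 0])
  expect_equal(avg[1, ], ep$data[1, 1, ] - base, ignore_attr = TRUE)

  # a trial plus its negation averages to zero
  ep2 <- toy_epochs(n_trials = 2, n_channels = 1, n_time = 200,
                    channel_labels = "OZ", tmin = -0.25,
                    fill = function(tr, ch, i) (-1)^tr * sin(i / 15))
  expect_lt(max(abs(erp_average(ep2, c(-0.25, 0)))), 1e-12)

  # synthetic deflection at 220 ms is recovered within 10 ms
  sr <- 500
  deflect <- function(tr, ch, i) {
    t <- (i - 1) / sr - 0.25
    5 * exp(-((t - 0.22) / 0.02)^2) + rnorm(length(i), 0, 0.3)
  }
  set.seed(8)
  ep3 <- toy_epochs(n_trials = 30, n_channels = 1, n_time = 500,
                    channel_labels = "OZ", tmin = -0.25, fill = deflect)
  avg3 <- erp_average(ep3, c(-0.25, 0))
  peak_t <- attr(avg3, "times")[which.max(avg3[1, ])]
  expect_lt(abs(peak_t - 0.22), 0.01)
  expect_equal(attr(avg3, "n_trials"), 30)
})

test_that("preprocessing records its order in provenance", {
  cfg <- synth_config("rotation", n_channels = 4, n_trials = 3, sr = 250,
                      blink_rate = 0, seed = 17)
  ds <- generate_rotation_dataset(cfg)
  rec <- bandpass(rereference_average(ds$recording), 1, 100)
  ep <- epoch(rec, c("response", "midpoint"), -1.5, 0.5)
  ep <- reject_amplitude(ep, 100, 100)$epochs
  steps <- sub(":.*", "", provenance(ep))
  expect_equal(steps, c("rereference_average", "bandpass", "epoch",
                        "reject_amplitude"))
})
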