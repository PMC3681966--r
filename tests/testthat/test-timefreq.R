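test_that("analytic signal has unit envelope and advancing phase for a tone", {
  sr <- 500
  t <- seq(1 / sr, 2, by = 1 / sr)
  xa <- analytic_signal(cos(2 * pi * 25 * t))
  mid <- 100:900
  expect_equal(Mod(xa[mid]), rep(1, length(mid)), tolerance = 1e-3)
  # phase derivative tracks the tone frequency
  ph <- unwrap_phase(Arg(xa[mid]))
  f_inst <- diff(ph) * sr / (2 * pi)
  expect_equal(median(f_inst), 25, tolerance = 0.1)
  # a constant has (near-)zero imaginary part
  xc <- analytic_signal(rep(3, 64))
  expect_lt(max(abs(Im(xc))), 1e-9)
  expect_equal(Re(xa), cos(2 * pi * 25 * t), tolerance = 1e-9)
  expect_error(analytic_signal(rnorm(7)), "too short")
})

test_that("instantaneous frequency of a chirp is tracked within 2 Hz", {
  sr <- 500
  t <- seq(1 / sr, 4, by = 1 / sr)
  f0 <- 20; f1 <- 80
  finst_true <- f0 + (f1 - f0) * t / 4
  x <- cos(2 * pi * (f0 * t + (f1 - f0) * t^2 / 8))
  xa <- analytic_signal(x)
  ph <- unwrap_phase(Arg(xa))
  f_est <- diff(ph) * sr / (2 * pi)
  mid <- seq(round(0.1 * length(f_est)), round(0.9 * length(f_est)))
  expect_lt(max(abs(f_est[mid] - finst_true[mid])), 2)
})

test_that("pseudo Wigner-Ville localizes tones and suppresses cross-terms", {
  sr <- 500
  t <- seq(1 / sr, 2, by = 1 / sr)
  # single tone: ridge at the right bin everywhere in the interior
  W <- pwvd_power(analytic_signal(cos(2 * pi * 40 * t)), sr)
  interior <- 100:900
  ridge <- (15:90)[apply(W[, interior], 2, which.max)]
  expect_true(all(ridge == 40))

  # frequency accuracy within one bin across the gamma range
  for (f0 in c(20, 40, 70)) {
    Wf <- pwvd_power(analytic_signal(cos(2 * pi * f0 * t)), sr)
    rf <- (15:90)[apply(Wf[, interior], 2, which.max)]
    expect_lte(max(abs(rf - f0)), 1)
  }

  # two equal tones: mid-frequency cross-term well below the ridges
  W2 <- pwvd_power(analytic_signal(cos(2 * pi * 30 * t) +
                                     cos(2 * pi * 70 * t)), sr)
  expect_lt(mean(W2["50", interior]), 0.2 * mean(W2["30", interior]))
  expect_lt(mean(W2["50", interior]), 0.2 * mean(W2["70", interior]))

  # zero signal: all-zero map
  expect_equal(max(pwvd_power(complex(real = rep(0, 600),
                                      imaginary = rep(0, 600)), sr)), 0)
  expect_error(pwvd_power(analytic_signal(rnorm(600)), sr, freqs = 15:200),
               "sr/4")
})

test_that("power maps are time-shift covariant in the interior", {
  sr <- 500
  set.seed(5)
  x <- as.vector(stats::filter(rnorm(1200), rep(1, 5), "convolution",
                               sides = 2))
  x[is.na(x)] <- 0
  k <- 25
  Wa <- pwvd_power(analytic_signal(x), sr)
  Wb <- pwvd_power(analytic_signal(c(rep(0, k), x[1:(1200 - k)])), sr)
  a <- as.vector(Wa[, 300:800])
  b <- as.vector(Wb[, 300:800 + k])
  expect_gt(cor(a, b), 0.999)
})

test_that("tfr_decompose scales quadratically in amplitude, phase unchanged", {
  sr <- 500
  mk <- function(amp) toy_epochs(
    n_trials = 2, n_channels = 1, n_time = 1000, sr = sr,
    channel_labels = "OZ",
    fill = function(tr, ch, i) amp * cos(2 * pi * 40 * i / sr + 1))
  t1 <- tfr_decompose(mk(1), freqs = 30:50)
  t2 <- tfr_decompose(mk(2), freqs = 30:50)
  mid <- 300:700
  expect_equal(t2$power[1, 1, 11, mid], 4 * t1$power[1, 1, 11, mid],
               tolerance = 1e-6)
  expect_equal(Arg(t2$coeffs[1, 1, 11, mid]), Arg(t1$coeffs[1, 1, 11, mid]),
               tolerance = 1e-6)
  expect_error(tfr_decompose(toy_epochs(n_time = 50), freqs = 15:90),
               "4 cycles")
})

test_that("an injected 70 Hz burst is recovered at the right place", {
  sr <- 500
  set.seed(6)
  rec <- generate_background(1, 30, sr, 1, 10, channel_labels = "OZ")
  onsets <- seq(0.5, 28, by = 1.4)
  inj <- inject_burst(rec, onsets,
                      list(channels = "OZ", freq = 70, onset = 0.4,
                           duration = 0.4, amplitude = 8, kappa = 0),
                      seed = 2)
  rec2 <- inj$recording
  rec2$events <- event_table(round(onsets * sr), rep("movie_onset",
                                                     length(onsets)),
                             seq_along(onsets))
  ep <- epoch(rec2, "movie_onset", 0, 1.2)
  tf <- tfr_decompose(ep, keep = "power")
  tf <- baseline_normalize(tf, baseline_window = c(0, 0.3))
  avg <- apply(tf$power[, 1, , ], c(2, 3), mean)
  peak <- which(avg == max(avg), arr.ind = TRUE)
  peak_f <- tf$freqs[peak[1]]
  peak_t <- tf$times[peak[2]]
  expect_lte(abs(peak_f - 70), 3)
  # burst support is 0.4-0.8 s, envelope peak at 0.6 s
  expect_lte(abs(peak_t - 0.6), 0.1)
  # and the normalized increase is localized: outside +-3 Hz, +-100 ms of
  # the burst the map stays well below the peak
  mask <- outer(abs(tf$freqs - 70) <= 3,
                tf$times >= 0.3 & tf$times <= 0.9)
  expect_lt(max(avg[!mask]), 0.5 * max(avg))
})

test_that("white-noise maps have no spurious frequency structure", {
  sr <- 500
  set.seed(9)
  ep <- toy_epochs(n_trials = 8, n_channels = 1, n_time = 800, sr = sr,
                   channel_labels = "OZ",
                   fill = function(tr, ch, i) rnorm(length(i)))
  tf <- tfr_decompose(ep, keep = "power")
  m <- apply(tf$power[, 1, , 100:700], 2, mean)   # per-frequency average
  expect_lt(max(m - mean(m)) / sd(m), 5)
})

test_that("baseline normalization yields exact zero-mean unit-SD baselines", {
  sr <- 500
  set.seed(10)
  ep <- toy_epochs(n_trials = 6, n_channels = 2, n_time = 1000, sr = sr,
                   fill = function(tr, ch, i) rnorm(length(i), sd = 3))
  tf <- tfr_decompose(ep, freqs = 20:40, keep = "power")
  tfn <- baseline_normalize(tf, baseline_window = c(0.2, 0.8))
  bsel <- tfn$times >= 0.2 & tfn$times <= 0.8
  avg <- apply(tfn$power[, , , bsel], c(2, 3, 4), mean)
  mu <- apply(avg, c(1, 2), mean)
  sdv <- apply(avg, c(1, 2), sd)
  expect_lt(max(abs(mu)), 1e-6)
  expect_lt(max(abs(sdv - 1)), 1e-6)

  # affine-transformed power normalizes to the same map
  tf2 <- tf
  tf2$power <- 5 * tf$power + 7
  tfn2 <- baseline_normalize(tf2, baseline_window = c(0.2, 0.8))
  expect_equal(tfn2$power, tfn$power, tolerance = 1e-9)

  # constant power has zero baseline SD -> error names the location
  tf3 <- tf
  tf3$power[] <- 1
  expect_error(baseline_normalize(tf3, c(0.2, 0.8)), "zero baseline SD")
})

test_that("a constructed 3-SD effect reads ~3 after normalization", {
  # build power directly: baseline noise with known mean/SD plus a bump
  set.seed(11)
  n_tr <- 40; nt <- 100
  power <- array(rnorm(n_tr * 1 * 5 * nt, mean = 10, sd = 2),
                 c(n_tr, 1, 5, nt))
  bump <- 60:70
  # raise one frequency's bump window by 3 across-trial-average baseline SDs
  base_sd <- sd(apply(power[, 1, 3, 1:50], 2, mean))
  power[, 1, 3, bump] <- power[, 1, 3, bump] + 3 * base_sd
  tf <- gammasync:::new_tfr(power = power, coeffs = NULL, freqs = 20:24,
                            times = seq_len(nt) / 100, sr = 100,
                            labels = rep("a", n_tr), trial_id = seq_len(n_tr),
                            channel_labels = "CH1")
  tfn <- baseline_normalize(tf, baseline_window = c(0.01, 0.5))
  avg <- apply(tfn$power[, 1, 3, ], 2, mean)
  expect_equal(mean(avg[bump]), 3, tolerance = 0.35)
})

test_that("band averaging matches enumeration and respects half-open bins", {
  power <- array(0, c(2, 1, 4, 3))
  power[, , 1, ] <- 1   # 30 Hz
  power[, , 2, ] <- 2   # 31 Hz
  power[, , 3, ] <- 3   # 44 Hz
  power[, , 4, ] <- 4   # 45 Hz (belongs to the next band)
  tf <- gammasync:::new_tfr(power = power, coeffs = NULL,
                            freqs = c(30, 31, 44, 45),
                            times = c(0.1, 0.2, 0.3), sr = 100,
                            labels = c("x", "y"), trial_id = 1:2,
                            channel_labels = "CH1")
  ba <- band_average(tf, band_spec(list("30-45" = c(30, 45),
                                        "45-60" = c(45, 60))))
  expect_equal(unique(ba$power[ba$band == "30-45"]), 2)  # mean(1,2,3)
  expect_equal(unique(ba$power[ba$band == "45-60"]), 4)  # single bin
  expect_equal(nrow(ba), 2 * 3 * 2)
  # single-bin band is the identity
  ba2 <- band_average(tf, band_spec(list(one = c(44, 45))))
  expect_true(all(ba2$power == 3))
  expect_error(band_spec(list(a = c(30, 20))), "lo < hi")
  expect_error(band_spec(list(a = c(10, 30), b = c(20, 40))), "overlap")
})

test_that("induced mode removes the phase-locked component", {
  sr <- 500
  # identical evoked tone in every trial: induced power collapses
  ep <- toy_epochs(n_trials = 6, n_channels = 1, n_time = 1000, sr = sr,
                   channel_labels = "OZ",
                   fill = function(tr, ch, i) cos(2 * pi * 40 * i / sr))
  tf_ev <- tfr_decompose(ep, freqs = 35:45, keep = "power")
  tf_in <- tfr_decompose(ep, freqs = 35:45, keep = "power", induced = TRUE)
  mid <- 300:700
  expect_gt(mean(tf_ev$power[, 1, 6, mid]), 100 * mean(tf_in$power[, 1, 6, mid]))
})
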