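#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used for inter-trial phase jitter of
#' injected oscillatory bursts: the mean resultant length of
#' `rvonmises(n, 0, kappa)` converges to `besselI(kappa, 1) / besselI(kappa, 0)`,
#' which is what calibrates the expected phase-locking value of coupled
#' channel pairs. `kappa = 0` is the uniform circle; very large `kappa`
#' (> 1e5) uses the wrapped-normal limit.
#'
#' @param n number of draws.
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) {
    th <- runif(n, -pi, pi)
  } else if (kappa > 1e5) {
    th <- mu + rnorm(n, 0, 1 / sqrt(kappa))
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    i <- 1L
    while (i <= n) {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        th[i] <- mu + sign(u[3] - 0.5) * acos(f)
        i <- i + 1L
      }
    }
  }
  ((th + pi) %% (2 * pi)) - pi
}

# truncated normal via inverse-CDF; exact for the scalar bounds used here
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# mean of a normal truncated to [lo, hi]
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / Z
}

#' Generate 1/f background EEG noise
#'
#' Independent per-channel noise with power spectral density proportional to
#' `1/f^alpha`, produced by spectral shaping of white Gaussian noise (the DC
#' bin is zeroed) and rescaled to an exact per-channel RMS. Inter-channel
#' correlation is deliberately absent here; volume conduction is modelled
#' separately via [apply_mixing()].
#'
#' @param n_channels number of channels.
#' @param duration_s recording length (s).
#' @param sr sampling rate (Hz).
#' @param alpha spectral exponent (>= 0); 0 gives white noise, ~1-1.5 is
#'   typical of resting EEG.
#' @param rms per-channel root-mean-square amplitude (microvolts).
#' @param seed RNG seed (`NULL` to use the current stream).
#' @param channel_labels,channel_kind optional channel metadata; defaults to
#'   the first `n_channels` labels of the packaged 64-channel montage.
#' @return a [recording()].
#' @export
generate_background <- function(n_channels, duration_s, sr, alpha = 1,
                                rms = 10, seed = NULL,
                                channel_labels = NULL, channel_kind = NULL) {
  if (alpha < 0) stop("`alpha` must be >= 0")
  stopifnot(duration_s > 0, sr > 0, n_channels >= 1)
  n <- round(duration_s * sr)
  channel_labels <- channel_labels %||% default_labels(n_channels)
  with_seed(seed, {
    data <- matrix(0, n_channels, n)
    f <- (seq_len(n) - 1) * sr / n
    f_fold <- pmin(f, sr - f)                 # two-sided spectrum
    scale <- c(0, f_fold[-1]^(-alpha / 2))    # zero the DC bin
    for (ch in seq_len(n_channels)) {
      x <- rnorm(n)
      y <- Re(fft(fft(x) * scale, inverse = TRUE)) / n
      data[ch, ] <- y * rms / sqrt(mean(y^2))
    }
    recording(data, sr = sr, channel_labels = channel_labels,
              channel_kind = channel_kind)
  })
}

# labels for small synthetic montages: occipito-parietal first so that the
# decoding roster is always populated
default_labels <- function(n, n_eog = 0) {
  base <- c("O1", "OZ", "O2", "PO3", "POZ", "PO4", "P1", "PZ", "P4",
            "CP1", "CPZ", "CP2", "C1", "CZ", "C2", "FZ", "F3", "F4",
            "FC1", "FC2", "P7", "P8", "PO7", "PO8", "FP1", "FP2")
  extra <- setdiff(standard_montage(64)$label, base)
  eeg <- c(base, extra)[seq_len(n)]
  c(eeg, c("VEOG", "HEOG", "EOG3", "EOG4")[seq_len(n_eog)])
}

#' Inject narrow-band oscillatory bursts into a recording
#'
#' Adds `amplitude * w(t) * cos(2*pi*f*(t - t0) + phi_trial + lag_ch +
#' jitter_ch)` to each target channel in each trial. The envelope `w` is a
#' raised-cosine (Hann) of length `duration`; when `sustain_s > 0` the Hann
#' is split into a half ramp-up, a plateau of `sustain_s` seconds and a half
#' ramp-down, modelling sustained oscillatory state activity rather than a
#' transient.
#'
#' The per-trial reference phase `phi_trial` is uniform across trials. The
#' first listed channel carries the reference exactly; every other channel
#' adds independent von Mises jitter with concentration `kappa` about
#' (reference + its lag). Hence the expected inter-trial PLV between the
#' first channel and any other is the Bessel ratio
#' `besselI(kappa, 1) / besselI(kappa, 0)` (1 for `kappa = Inf`, 0 for
#' `kappa = 0`), the calibration the synthetic phase-coupling tests rely on.
#'
#' @param rec a [recording()].
#' @param trial_onsets trial start times (s).
#' @param burst a list with elements `channels` (labels), `freq` (Hz),
#'   `onset` (s, burst start relative to trial onset), `duration` (s, Hann
#'   length), `amplitude` (microvolts), and optionally `kappa`
#'   (concentration, default `Inf`), `lags` (rad, recycled over channels,
#'   default 0) and `sustain_s` (s, default 0).
#' @param seed RNG seed.
#' @return list with the modified recording (`recording`) and a tibble of
#'   ground truth (`truth`: trial, start/end of the burst support, phase).
#' @export
inject_burst <- function(rec, trial_onsets, burst, seed = NULL) {
  stopifnot(inherits(rec, "gs_recording"))
  kappa <- burst$kappa %||% Inf
  sustain <- burst$sustain_s %||% 0
  lags <- rep(burst$lags %||% 0, length.out = length(burst$channels))
  ch_idx <- match(burst$channels, rec$channel_labels)
  if (anyNA(ch_idx))
    stop("burst channels not in recording: ",
         paste(burst$channels[is.na(ch_idx)], collapse = ", "))
  sr <- rec$sr
  n <- ncol(rec$data)
  ramp <- round(burst$duration * sr)
  half <- floor(ramp / 2)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, ramp - 1) / (ramp - 1))
  env <- c(hann[seq_len(half)],
           rep(1, round(sustain * sr)),
           hann[(half + 1):ramp])
  len <- length(env)
  truth <- vector("list", length(trial_onsets))
  with_seed(seed, {
    for (k in seq_along(trial_onsets)) {
      start <- round((trial_onsets[k] + burst$onset) * sr)  # 0-based sample
      if (start < 0 || start + len > n)
        stop("burst extends past recording bounds in trial ", k)
      phi_ref <- runif(1, -pi, pi)
      tt <- (seq_len(len) - 1) / sr
      for (j in seq_along(ch_idx)) {
        jit <- if (j == 1) 0 else
          if (is.infinite(kappa)) 0 else rvonmises(1, 0, kappa)
        phase <- phi_ref + lags[j] + jit
        rec$data[ch_idx[j], start + seq_len(len)] <-
          rec$data[ch_idx[j], start + seq_len(len)] +
          burst$amplitude * env * cos(2 * pi * burst$freq * tt + phase)
      }
      truth[[k]] <- tibble::tibble(trial = k, t_start = start / sr,
                                   t_end = (start + len - 1) / sr,
                                   phase_ref = phi_ref)
    }
  })
  list(recording = rec, truth = dplyr::bind_rows(truth))
}

#' Instantaneous (zero-lag) volume-conduction mixing
#'
#' Replaces the channel data with `mixing %*% data`: every output channel is
#' an instantaneous weighted sum of the input channels, the sensor-space
#' model of a single neural source being measurable at many electrodes.
#' Zero-lag mixing leaves the imaginary part of coherency at zero in
#' expectation, which is why ImCoh is used alongside PLV downstream.
#'
#' @param rec a [recording()]; rows are treated as sources.
#' @param mixing square numeric matrix, channels x sources.
#' @return the mixed [recording()] (channel metadata preserved).
#' @export
apply_mixing <- function(rec, mixing) {
  stopifnot(inherits(rec, "gs_recording"))
  mixing <- as.matrix(mixing)
  if (ncol(mixing) != nrow(rec$data) || nrow(mixing) != nrow(rec$data))
    stop("mixing matrix must be square channels x sources (",
         nrow(rec$data), " x ", nrow(rec$data), "); got ",
         nrow(mixing), " x ", ncol(mixing))
  rec$data <- mixing %*% rec$data
  rownames(rec$data) <- rec$channel_labels
  rec
}

#' Add ocular (blink) artifacts
#'
#' Blinks arrive as a Poisson process at `rate` per second, each a ~300 ms
#' half-sine deflection at full `amplitude` on every EOG channel and scaled
#' by `decay` on EEG channels (frontal channels see more of the blink than
#' occipital ones in real data; pass a named vector to model that profile).
#' Ground-truth blink times are returned so artifact screening can be tested
#' against construction.
#'
#' @param rec a [recording()] containing at least one EOG channel.
#' @param rate blink rate (Hz).
#' @param amplitude peak EOG deflection (microvolts).
#' @param decay scalar or named numeric (per EEG label) propagation factor.
#' @param seed RNG seed.
#' @param blink_s blink duration (s).
#' @return list: `recording`, `blink_times` (s, blink onsets).
#' @export
add_ocular_artifacts <- function(rec, rate, amplitude, decay = 0.05,
                                 seed = NULL, blink_s = 0.3) {
  stopifnot(inherits(rec, "gs_recording"))
  eog <- chan_idx(rec, "EOG")
  if (!length(eog)) stop("recording has no EOG channels")
  eeg <- chan_idx(rec, "EEG")
  dur <- ncol(rec$data) / rec$sr
  if (is.null(names(decay))) {
    decay_vec <- rep(decay[1], length(eeg))
  } else {
    decay_vec <- unname(decay[rec$channel_labels[eeg]])
    decay_vec[is.na(decay_vec)] <- 0
  }
  with_seed(seed, {
    blink_times <- numeric(0)
    if (rate > 0) {
      t <- stats::rexp(1, rate)
      while (t < dur - blink_s) {
        blink_times <- c(blink_times, t)
        t <- t + stats::rexp(1, rate)
      }
    }
    n_blink <- round(blink_s * rec$sr)
    shape <- sin(pi * seq(0, 1, length.out = n_blink))
    for (bt in blink_times) {
      idx <- round(bt * rec$sr) + seq_len(n_blink)
      for (i in eog)
        rec$data[i, idx] <- rec$data[i, idx] + amplitude * shape
      for (j in seq_along(eeg))
        rec$data[eeg[j], idx] <- rec$data[eeg[j], idx] +
          amplitude * decay_vec[j] * shape
    }
    list(recording = rec, blink_times = blink_times)
  })
}
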