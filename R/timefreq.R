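#' Analytic signal via the Hilbert transform
#'
#' One-sided spectrum construction: the FFT of the input has its
#' negative-frequency half zeroed (positive half doubled), so the real part
#' of the result equals the input and the imaginary part is its Hilbert
#' transform. Input to the Wigner-Ville estimator, where it suppresses
#' spectral aliasing between positive and negative frequencies.
#'
#' @param x real numeric vector (length >= 8).
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) stop("`x` must be finite numeric")
  n <- length(x)
  if (n < 8) stop("signal too short for analytic-signal estimation (n < 8)")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Smoothed pseudo Wigner-Ville energy distribution
#'
#' Windowed quadratic time-frequency estimate of an analytic signal:
#' `W(t, f) = sum_tau h(tau) r_g(t, tau) exp(-i 4 pi f tau / sr)` with
#' `r_g(t, tau) = sum_s g(s) x(t+s+tau) x*(t+s-tau)`, where `h` is a Hamming
#' lag window (frequency smoothing, suppressing the quadratic cross-terms)
#' and `g` a short Hamming time window. The result is real; residual
#' negative values are clipped to zero and the clipped fraction is recorded
#' in the `clip_fraction` attribute.
#'
#' Because the lag product doubles frequencies, the analysis grid must stay
#' below `sr / 4` (e.g. up to 90 Hz needs at least 360 Hz sampling).
#'
#' @param x analytic (complex) signal, e.g. from [analytic_signal()].
#' @param sr sampling rate (Hz).
#' @param freqs frequency grid in Hz (default 15-90 Hz in 1 Hz steps).
#' @param freq_window lag-window length in samples (odd; default
#'   `round(sr / 4)`, about 4 Hz of frequency smoothing).
#' @param time_smooth time-smoothing window length in seconds (default
#'   0.06 s, long enough to null the difference-frequency
#'   oscillation of gamma-band cross-terms).
#' @param stride keep every `stride`-th time point (power is smooth on the
#'   scale of `time_smooth`, so striding loses little).
#' @return frequencies x time real matrix (attributes: `times_idx`,
#'   `clip_fraction`).
#' @export
pwvd_power <- function(x, sr, freqs = 15:90, freq_window = NULL,
                       time_smooth = 0.06, stride = 1L) {
  stopifnot(is.complex(x))
  if (max(freqs) > sr / 4)
    stop("frequency grid exceeds sr/4 = ", sr / 4,
         " Hz: the Wigner-Ville lag product doubles frequencies, so ",
         "frequencies above sr/4 alias; resample or lower the grid")
  n <- length(x)
  Lh <- freq_window %||% round(sr / 4)
  if (Lh %% 2 == 0) Lh <- Lh + 1
  M <- (Lh - 1) / 2
  if (n < Lh) stop("signal shorter than the lag window (", Lh, " samples)")
  ham <- signal::hamming(Lh)
  h <- ham[(M + 1):Lh]                       # h[tau+1], tau = 0..M

  # lag-product matrix P[t, tau+1] = x[t+tau] * Conj(x[t-tau]) (0 off-edge)
  P <- matrix(0 + 0i, n, M + 1)
  P[, 1] <- x * Conj(x)
  for (tau in seq_len(M)) {
    idx <- (tau + 1):(n - tau)
    P[idx, tau + 1] <- x[idx + tau] * Conj(x[idx - tau])
  }
  # time smoothing with g (unit-sum Hamming), per lag column
  Lg <- max(3, round(time_smooth * sr))
  if (Lg %% 2 == 0) Lg <- Lg + 1
  g <- signal::hamming(Lg)
  g <- g / sum(g)
  Pr <- stats::filter(Re(P), g, sides = 2)
  Pi <- stats::filter(Im(P), g, sides = 2)
  P <- matrix(complex(real = ifelse(is.na(Pr), 0, Pr),
                      imaginary = ifelse(is.na(Pi), 0, Pi)), n, M + 1)

  t_idx <- seq(1, n, by = stride)
  Ps <- t(P[t_idx, , drop = FALSE])          # (M+1) x T
  E <- exp(-4i * pi * outer(freqs, seq_len(M)) / sr) *
    matrix(h[-1], length(freqs), M, byrow = TRUE)
  W <- matrix(h[1] * Re(Ps[1, ]), length(freqs), length(t_idx),
              byrow = TRUE) + 2 * Re(E %*% Ps[-1, , drop = FALSE])
  clip <- mean(W < 0)
  W[W < 0] <- 0
  dimnames(W) <- list(freqs, NULL)
  attr(W, "times_idx") <- t_idx
  attr(W, "clip_fraction") <- clip
  W
}

# internal TFR constructor shared by tfr_decompose and read_container
new_tfr <- function(power, coeffs, freqs, times, sr, labels, trial_id,
                    channel_labels, channel_kind = NULL, normalized = FALSE,
                    baseline = NULL, clip_fraction = NA_real_) {
  structure(
    list(power = power, coeffs = coeffs, freqs = freqs, times = times,
         sr = sr, labels = labels, trial_id = trial_id,
         channel_labels = channel_labels,
         channel_kind = channel_kind %||% rep("EEG", length(channel_labels)),
         normalized = normalized, baseline = baseline,
         clip_fraction = clip_fraction),
    class = "gs_tfr")
}

#' @export
print.gs_tfr <- function(x, ...) {
  a <- x$power %||% x$coeffs
  cat(sprintf(
    "<gs_tfr> %d trials x %d channels x %d freqs (%g-%g Hz) x %d times\n",
    dim(a)[1], dim(a)[2], dim(a)[3], min(x$freqs), max(x$freqs), dim(a)[4]))
  cat(sprintf("  power: %s | phase coeffs: %s | normalized: %s\n",
              if (is.null(x$power)) "no" else "yes",
              if (is.null(x$coeffs)) "no" else "yes", x$normalized))
  invisible(x)
}

#' Per-trial time-frequency decomposition
#'
#' Power comes from the smoothed pseudo Wigner-Ville distribution of the
#' analytic signal ([pwvd_power()]). Phase cannot come from the
#' Wigner-Ville estimate itself (it is real-valued), so complex coefficients
#' are obtained by convolution with Gaussian-windowed complex exponentials
#' (4-cycle support per frequency), the standard auxiliary decomposition;
#' their angle supplies the phase used by the synchrony measures.
#'
#' @param ep an [epoch_set()].
#' @param freqs frequency grid (Hz), default 15-90 in 1 Hz steps.
#' @param stride time decimation factor for the output grid.
#' @param keep which arrays to retain: any of `"power"`, `"coeffs"`.
#'   Dropping `"coeffs"` roughly halves time and memory when only power is
#'   needed (e.g. for decoding features).
#' @param induced if `TRUE`, the across-trial average (ERP) is subtracted
#'   from every trial before decomposition, leaving non-phase-locked
#'   activity only.
#' @param freq_window,time_smooth smoothing windows, see [pwvd_power()].
#' @return a `gs_tfr` object: arrays are trials x channels x frequencies x
#'   time; `times` are epoch-relative seconds.
#' @export
tfr_decompose <- function(ep, freqs = 15:90, stride = 1L,
                          keep = c("power", "coeffs"), induced = FALSE,
                          freq_window = NULL, time_smooth = 0.06) {
  stopifnot(inherits(ep, "gs_epochs"))
  keep <- match.arg(keep, several.ok = TRUE)
  d <- dim(ep$data)
  n <- d[3]
  if (n < 4 * ep$sr / min(freqs))
    stop("epoch too short: need at least 4 cycles of ", min(freqs),
         " Hz (", round(4 / min(freqs), 3), " s)")
  if (max(freqs) > ep$sr / 4)
    stop("frequency grid exceeds sr/4 = ", ep$sr / 4, " Hz (see ?pwvd_power)")
  dat <- ep$data
  if (induced) {
    erp <- apply(dat, c(2, 3), mean)
    dat <- sweep(dat, c(2, 3), erp)
  }
  t_idx <- seq(1, n, by = stride)
  nf <- length(freqs); nt <- length(t_idx)
  want_pow <- "power" %in% keep
  want_coef <- "coeffs" %in% keep
  power <- if (want_pow) array(0, c(d[1], d[2], nf, nt))
  coeffs <- if (want_coef) array(0 + 0i, c(d[1], d[2], nf, nt))

  # precompute narrow-band kernels in the frequency domain
  nfft <- stats::nextn(n + round(4 * ep$sr / min(freqs)), 2)
  K <- if (want_coef) {
    ks <- matrix(0 + 0i, nf, nfft)
    for (j in seq_len(nf)) {
      f <- freqs[j]
      L <- round(4 / f * ep$sr)
      if (L %% 2 == 0) L <- L + 1
      Mk <- (L - 1) / 2
      s <- (-Mk):Mk
      g <- exp(-(s / (L / 6))^2 / 2)
      w <- (2 / sum(g)) * g * exp(2i * pi * f * s / ep$sr)
      kpad <- complex(length.out = nfft)
      kpad[1:(Mk + 1)] <- w[(Mk + 1):L]        # s = 0..Mk
      kpad[(nfft - Mk + 1):nfft] <- w[1:Mk]    # s = -Mk..-1 wrapped
      ks[j, ] <- fft(kpad)
    }
    ks
  }
  clip_tot <- 0
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- dat[tr, ch, ]
      if (want_pow) {
        xa <- analytic_signal(x)
        W <- pwvd_power(xa, ep$sr, freqs, freq_window = freq_window,
                        time_smooth = time_smooth, stride = stride)
        power[tr, ch, , ] <- W
        clip_tot <- clip_tot + attr(W, "clip_fraction")
      }
      if (want_coef) {
        X <- fft(c(x, rep(0, nfft - n)))
        for (j in seq_len(nf)) {
          y <- fft(X * K[j, ], inverse = TRUE) / nfft
          coeffs[tr, ch, j, ] <- y[t_idx]
        }
      }
    }
  }
  new_tfr(power = power, coeffs = coeffs, freqs = freqs,
          times = ep$times[t_idx], sr = ep$sr, labels = ep$labels,
          trial_id = ep$trial_id, channel_labels = ep$channel_labels,
          channel_kind = ep$channel_kind,
          clip_fraction = if (want_pow) clip_tot / (d[1] * d[2]) else NA_real_)
}

#' Baseline z-normalization of time-frequency power
#'
#' For every channel and frequency bin, subtracts the baseline mean and
#' divides by the baseline standard deviation, where the baseline statistics
#' are those of the across-trial average power: either over the time bins of
#' `baseline_window` (pre-stimulus normalization), or -- when
#' `reference_label` is given -- over the epochs of that condition (e.g.
#' normalizing perception maps against the no-perception state). After
#' normalization the across-trial average power has mean 0 and SD 1 within
#' the baseline, and units are "normalized" (baseline SDs).
#'
#' @param tfr a `gs_tfr` with power.
#' @param baseline_window numeric length-2 (s, epoch-relative), or `NULL`
#'   together with `reference_label` to use that condition's whole window.
#' @param reference_label optional condition label whose trials define the
#'   baseline statistics.
#' @return the normalized `gs_tfr`.
#' @export
baseline_normalize <- function(tfr, baseline_window = NULL,
                               reference_label = NULL) {
  stopifnot(inherits(tfr, "gs_tfr"), !is.null(tfr$power))
  if (is.null(baseline_window) && is.null(reference_label))
    stop("give a baseline_window, a reference_label, or both")
  tsel <- if (is.null(baseline_window)) seq_along(tfr$times) else
    which(tfr$times >= baseline_window[1] & tfr$times <= baseline_window[2])
  if (!length(tsel)) stop("baseline window outside the epoch")
  rsel <- if (is.null(reference_label)) seq_along(tfr$labels) else
    which(tfr$labels == reference_label)
  if (!length(rsel)) stop("no trials with label ", reference_label)
  avg <- apply(tfr$power[rsel, , , tsel, drop = FALSE], c(2, 3, 4), mean)
  mu <- apply(avg, c(1, 2), mean)
  sdv <- apply(avg, c(1, 2), sd)
  bad <- which(sdv <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("zero baseline SD at channel ", tfr$channel_labels[bad[1, 1]],
         ", ", tfr$freqs[bad[1, 2]], " Hz; cannot z-normalize")
  d <- dim(tfr$power)
  for (tr in seq_len(d[1]))
    tfr$power[tr, , , ] <- (tfr$power[tr, , , ] - as.vector(mu)) /
      as.vector(sdv)
  tfr$normalized <- TRUE
  tfr$baseline <- list(window = baseline_window,
                       reference_label = reference_label)
  tfr
}

#' Frequency bands of interest
#'
#' The four 15 Hz bands spanning high beta to high gamma. Bands are
#' half-open `[lo, hi)` so each 1 Hz bin belongs to exactly one band.
#'
#' @param bands named list of `c(lo, hi)` pairs (Hz).
#' @return validated named list of class `gs_bands`.
#' @export
band_spec <- function(bands = list("15-30" = c(15, 30), "30-45" = c(30, 45),
                                   "45-60" = c(45, 60), "60-75" = c(60, 75))) {
  stopifnot(length(bands) >= 1, !is.null(names(bands)))
  m <- do.call(rbind, bands)
  if (any(m[, 2] <= m[, 1])) stop("each band needs lo < hi")
  o <- order(m[, 1])
  if (length(bands) > 1 && any(m[o, 2][-length(bands)] > m[o, 1][-1]))
    stop("bands overlap")
  structure(bands[o], class = "gs_bands")
}

#' Band- and channel-averaged power series
#'
#' Averages normalized (or raw) power over the frequency bins of each band
#' (`lo <= f < hi`) and over a channel subset, retaining trials and time: the
#' band series that the statistical contrasts and the decoder consume.
#'
#' @param tfr a `gs_tfr` with power.
#' @param bands a [band_spec()].
#' @param channels labels to average over (default: all EEG channels).
#' @return tibble: `trial_id`, `label`, `band`, `time`, `power`.
#' @export
band_average <- function(tfr, bands = band_spec(), channels = NULL) {
  stopifnot(inherits(tfr, "gs_tfr"), !is.null(tfr$power))
  channels <- channels %||% tfr$channel_labels[tfr$channel_kind == "EEG"]
  ci <- match(channels, tfr$channel_labels)
  if (anyNA(ci)) stop("unknown channel(s): ",
                      paste(channels[is.na(ci)], collapse = ", "))
  out <- list()
  for (bn in names(bands)) {
    fsel <- which(tfr$freqs >= bands[[bn]][1] & tfr$freqs < bands[[bn]][2])
    if (!length(fsel)) stop("band ", bn, " contains no frequency bins")
    m <- apply(tfr$power[, ci, fsel, , drop = FALSE], c(1, 4), mean)
    out[[bn]] <- tibble::tibble(
      trial_id = rep(tfr$trial_id, times = length(tfr$times)),
      label = rep(tfr$labels, times = length(tfr$times)),
      band = bn,
      time = rep(tfr$times, each = length(tfr$trial_id)),
      power = as.vector(m))
  }
  dplyr::bind_rows(out)
}
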