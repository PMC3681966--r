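# Small in-code fixtures shared across the suite.

# a tiny all-zeros recording with valid montage labels
toy_recording <- function(n_channels = 4, n_samples = 500, sr = 500,
                          labels = c("O1", "OZ", "O2", "POZ"),
                          kind = NULL) {
  recording(matrix(0, n_channels, n_samples), sr = sr,
            channel_labels = labels[seq_len(n_channels)],
            channel_kind = kind)
}

# an epoch set filled from a function of (trial, channel, time index)
toy_epochs <- function(n_trials = 4, n_channels = 2, n_time = 500, sr = 500,
                       fill = function(tr, ch, i) 0,
                       labels = rep("a", n_trials),
                       channel_labels = c("OZ", "POZ")[seq_len(n_channels)],
                       channel_kind = NULL, tmin = 0) {
  a <- array(0, c(n_trials, n_channels, n_time))
  for (tr in seq_len(n_trials))
    for (ch in seq_len(n_channels))
      a[tr, ch, ] <- fill(tr, ch, seq_len(n_time))
  epoch_set(a, sr = sr, tmin = tmin, tmax = tmin + (n_time - 1) / sr,
            lock = "movie_onset", labels = labels,
            channel_labels = channel_labels, channel_kind = channel_kind)
}

# band/time/unit series tibble for the stats module
toy_series <- function(values, band = "30-45", times = NULL) {
  # values: units x time matrix
  values <- as.matrix(values)
  times <- times %||% (seq_len(ncol(values)) / 100)
  tibble::tibble(
    band = band,
    time = rep(times, each = nrow(values)),
    unit = rep(seq_len(nrow(values)), times = ncol(values)),
    value = as.vector(values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic phase-only TFR for synchrony tests: phases is a list of
# trials x freq x time arrays, one per channel
phase_tfr <- function(phases, freqs, times = NULL, amplitudes = NULL) {
  n_ch <- length(phases)
  d <- dim(phases[[1]])
  co <- array(0 + 0i, c(d[1], n_ch, d[2], d[3]))
  for (ch in seq_len(n_ch)) {
    amp <- if (is.null(amplitudes)) 1 else amplitudes[[ch]]
    co[, ch, , ] <- amp * exp(1i * phases[[ch]])
  }
  gammasync:::new_tfr(
    power = NULL, coeffs = co, freqs = freqs,
    times = times %||% seq_len(d[3]) / 100, sr = 100,
    labels = rep("a", d[1]), trial_id = seq_len(d[1]),
    channel_labels = paste0("CH", seq_len(n_ch)))
}

# simple 1-D phase unwrapping
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}
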