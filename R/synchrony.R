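# resolve a channel pair given as labels or indices; returns c(i, j)
resolve_pair <- function(tfr, pair) {
  if (is.character(pair)) {
    idx <- match(pair, tfr$channel_labels)
    if (anyNA(idx)) stop("unknown channel(s): ",
                         paste(pair[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(pair)
}

#' Inter-trial phase-locking value of a channel pair
#'
#' `PLV(f, t) = | mean_trials exp(i * (phi_i - phi_j)) |`: the magnitude of
#' the across-trial mean unit phasor of the phase difference. 1 when the
#' phase difference is identical in every trial, and of order
#' `sqrt(pi / (4 N))` under independent uniform phases. Symmetric in the
#' pair and invariant to any common phase offset.
#'
#' @param tfr a `gs_tfr` with complex coefficients.
#' @param pair two channel labels or indices.
#' @return frequencies x time matrix of PLV in `[0, 1]`.
#' @export
plv <- function(tfr, pair) {
  stopifnot(inherits(tfr, "gs_tfr"), !is.null(tfr$coeffs))
  ij <- resolve_pair(tfr, pair)
  n <- dim(tfr$coeffs)[1]
  if (n < 2) stop("PLV needs at least 2 trials")
  ci <- tfr$coeffs[, ij[1], , , drop = FALSE]
  cj <- tfr$coeffs[, ij[2], , , drop = FALSE]
  z <- ci * Conj(cj)
  mag <- Mod(z)
  z <- ifelse(mag > 0, z / mag, 0 + 0i)
  out <- apply(z, c(3, 4), function(v) Mod(mean(v)))
  dimnames(out) <- list(tfr$freqs, NULL)
  out
}

#' Across-trial coherency and its imaginary part
#'
#' `C_ij(f, t) = S_ij / sqrt(S_ii * S_jj)` with `S_ab` the across-trial mean
#' of `a * Conj(b)` at each time-frequency bin (trial-ensemble cross-spectra
#' at the TFR's own time resolution). `|C| <= 1`. The imaginary part
#' ([imcoh()]) is insensitive to instantaneous volume-conduction mixing:
#' zero-lag mixed sources produce real coherency, so a nonzero ImCoh
#' requires a genuine time-lagged interaction. Bins where either channel
#' has zero power are returned as `NA`.
#'
#' @param tfr a `gs_tfr` with complex coefficients.
#' @param pair two channel labels or indices.
#' @return complex (or, for [imcoh()], real) frequencies x time matrix.
#' @export
coherency <- function(tfr, pair) {
  stopifnot(inherits(tfr, "gs_tfr"), !is.null(tfr$coeffs))
  ij <- resolve_pair(tfr, pair)
  if (dim(tfr$coeffs)[1] < 2) stop("coherency needs at least 2 trials")
  ci <- tfr$coeffs[, ij[1], , ]
  cj <- tfr$coeffs[, ij[2], , ]
  dim(ci) <- dim(cj) <- dim(tfr$coeffs)[c(1, 3, 4)]
  Sij <- apply(ci * Conj(cj), c(2, 3), mean)
  Sii <- apply(Mod(ci)^2, c(2, 3), mean)
  Sjj <- apply(Mod(cj)^2, c(2, 3), mean)
  denom <- sqrt(Sii * Sjj)
  C <- Sij / denom
  C[denom == 0] <- NA_complex_
  dimnames(C) <- list(tfr$freqs, NULL)
  C
}

#' @rdname coherency
#' @export
imcoh <- function(tfr, pair) {
  C <- coherency(tfr, pair)
  out <- Im(C)
  out[is.na(C)] <- NA_real_
  dimnames(out) <- dimnames(C)
  out
}

#' Synchrony over all channel pairs
#'
#' Applies [plv()] or [imcoh()] to every unordered pair (i < j) of the
#' selected channels. Pair ordering follows the channel order of the TFR
#' (1-2, 1-3, ..., 2-3, ...), recorded in the returned `pairs` tibble.
#'
#' @param tfr a `gs_tfr` with complex coefficients.
#' @param measure `"plv"` or `"imcoh"`.
#' @param channels channel labels to include (default: all EEG channels).
#' @return a `gs_syncmap`: `values` (pairs x frequencies x time array),
#'   `pairs` tibble, `measure`, `n_trials`, plus the frequency/time axes.
#' @export
plv_all_pairs <- function(tfr, measure = c("plv", "imcoh"), channels = NULL) {
  stopifnot(inherits(tfr, "gs_tfr"), !is.null(tfr$coeffs))
  measure <- match.arg(measure)
  channels <- channels %||% tfr$channel_labels[tfr$channel_kind == "EEG"]
  ci <- match(channels, tfr$channel_labels)
  if (anyNA(ci)) stop("unknown channel(s): ",
                      paste(channels[is.na(ci)], collapse = ", "))
  pairs <- which(upper.tri(diag(length(ci))), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  nf <- dim(tfr$coeffs)[3]; nt <- dim(tfr$coeffs)[4]
  values <- array(NA_real_, c(nrow(pairs), nf, nt))
  fun <- if (measure == "plv") plv else imcoh
  for (p in seq_len(nrow(pairs)))
    values[p, , ] <- fun(tfr, c(ci[pairs[p, 1]], ci[pairs[p, 2]]))
  structure(
    list(values = values,
         pairs = tibble::tibble(
           i = pairs[, 1], j = pairs[, 2],
           label_i = channels[pairs[, 1]], label_j = channels[pairs[, 2]]),
         measure = measure, n_trials = dim(tfr$coeffs)[1],
         channels = channels, freqs = tfr$freqs, times = tfr$times,
         normalized = FALSE),
    class = "gs_syncmap")
}

#' @export
print.gs_syncmap <- function(x, ...) {
  cat(sprintf("<gs_syncmap> %s over %d pairs x %d freqs x %d times (N = %d trials)%s\n",
              x$measure, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$n_trials, if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Baseline z-normalization of a synchrony map
#'
#' Per pair and frequency, subtracts the baseline-window mean and divides by
#' the baseline SD of the synchrony time course (same convention as
#' [baseline_normalize()] for power).
#'
#' @param map a `gs_syncmap`.
#' @param baseline_window numeric length-2 (s).
#' @return the normalized `gs_syncmap` (units: baseline SDs).
#' @export
normalize_plv <- function(map, baseline_window) {
  stopifnot(inherits(map, "gs_syncmap"))
  tsel <- which(map$times >= baseline_window[1] &
                  map$times <= baseline_window[2])
  if (length(tsel) < 2) stop("baseline window needs at least 2 time bins")
  for (p in seq_len(dim(map$values)[1])) {
    base <- map$values[p, , tsel, drop = FALSE]
    mu <- apply(base, 2, mean)
    sdv <- apply(base, 2, sd)
    if (any(sdv <= 0, na.rm = TRUE))
      stop("zero baseline SD for pair ", map$pairs$label_i[p], "-",
           map$pairs$label_j[p], " at ",
           map$freqs[which(sdv <= 0)[1]], " Hz")
    map$values[p, , ] <- (map$values[p, , ] - mu) / sdv
  }
  map$normalized <- TRUE
  map$measure <- paste0("normalized-", map$measure)
  map
}

#' Per-channel connectivity summary
#'
#' Time-averages the synchrony map over `time_window`, frequency-averages
#' per band, and aggregates per channel as the mean absolute connectivity to
#' all partners (head-in-head style summaries). The full symmetric
#' channel x channel matrix per band is kept in the `matrices` attribute.
#'
#' @param map a `gs_syncmap`.
#' @param bands a [band_spec()].
#' @param time_window numeric length-2 (s), e.g. `c(-1, 0)` for the second
#'   before the report.
#' @return tibble: `channel`, `band`, `mean_abs`; attribute `matrices` holds
#'   a named list of per-band matrices (signed band/time averages).
#' @export
connectivity_summary <- function(map, bands = band_spec(),
                                 time_window = NULL) {
  stopifnot(inherits(map, "gs_syncmap"))
  tsel <- if (is.null(time_window)) seq_along(map$times) else
    which(map$times >= time_window[1] & map$times <= time_window[2])
  if (!length(tsel)) stop("time window outside the map")
  nch <- length(map$channels)
  mats <- list()
  rows <- list()
  for (bn in names(bands)) {
    fsel <- which(map$freqs >= bands[[bn]][1] & map$freqs < bands[[bn]][2])
    if (!length(fsel)) stop("band ", bn, " contains no frequency bins")
    m <- matrix(0, nch, nch, dimnames = list(map$channels, map$channels))
    pv <- apply(map$values[, fsel, tsel, drop = FALSE], 1, mean, na.rm = TRUE)
    for (p in seq_along(pv)) {
      m[map$pairs$i[p], map$pairs$j[p]] <- pv[p]
      m[map$pairs$j[p], map$pairs$i[p]] <- pv[p]
    }
    mats[[bn]] <- m
    rows[[bn]] <- tibble::tibble(
      channel = map$channels, band = bn,
      mean_abs = unname(rowSums(abs(m))) / (nch - 1))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "matrices") <- mats
  class(out) <- c("gs_connectivity", class(out))
  out
}

#' Shuffle-null screen for volume-conduction artifacts
#'
#' For each channel pair and band, compares the band-averaged |ImCoh| at
#' each time bin against the 95th percentile of its trial-shuffle null
#' (channel j's trials permuted, breaking the trial pairing while keeping
#' both marginals). Genuine zero-lag (volume-conducted) coupling should
#' stay below the null threshold in ~95% of bins; lagged interactions
#' exceed it.
#'
#' @param tfr a `gs_tfr` with complex coefficients.
#' @param bands a [band_spec()].
#' @param channels channels to screen (default all EEG).
#' @param n_shuffle number of trial permutations (default 100).
#' @param prob null quantile (default 0.95).
#' @param seed RNG seed for the permutations.
#' @return tibble: `label_i`, `label_j`, `band`, `time`, `imcoh_abs`,
#'   `null_q` (the null quantile), `exceeds`.
#' @export
imcoh_shuffle_screen <- function(tfr, bands = band_spec(), channels = NULL,
                                 n_shuffle = 100, prob = 0.95, seed = NULL) {
  stopifnot(inherits(tfr, "gs_tfr"), !is.null(tfr$coeffs))
  channels <- channels %||% tfr$channel_labels[tfr$channel_kind == "EEG"]
  ci <- match(channels, tfr$channel_labels)
  n <- dim(tfr$coeffs)[1]
  band_idx <- lapply(bands, function(b)
    which(tfr$freqs >= b[1] & tfr$freqs < b[2]))
  pairs <- which(upper.tri(diag(length(ci))), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  nf <- dim(tfr$coeffs)[3]; nt <- dim(tfr$coeffs)[4]
  with_seed(seed, {
    perms <- replicate(n_shuffle, sample.int(n), simplify = FALSE)
    rows <- list()
    for (p in seq_len(nrow(pairs))) {
      a <- ci[pairs[p, 1]]; b <- ci[pairs[p, 2]]
      # trials x (freq*time) matrices so the trial mean is a fast colMeans
      ca <- matrix(tfr$coeffs[, a, , ], n, nf * nt)
      cb <- matrix(tfr$coeffs[, b, , ], n, nf * nt)
      denom <- sqrt(colMeans(Mod(ca)^2) * colMeans(Mod(cb)^2))
      band_avg <- function(Sij) {
        icoh <- matrix(Im(Sij / denom), nf, nt)
        vapply(band_idx, function(fi) colMeans(abs(icoh[fi, , drop = FALSE])),
               numeric(nt))
      }
      obs <- band_avg(colMeans(ca * Conj(cb)))                # time x band
      null <- vapply(perms, function(pm)
        band_avg(colMeans(ca[pm, ] * Conj(cb))),
        obs)                                                  # time x band x shuffle
      q <- apply(null, c(1, 2), quantile, probs = prob, names = FALSE)
      for (bi in seq_along(bands)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          label_i = channels[pairs[p, 1]], label_j = channels[pairs[p, 2]],
          band = names(bands)[bi], time = tfr$times,
          imcoh_abs = obs[, bi], null_q = q[, bi],
          exceeds = obs[, bi] > q[, bi])
      }
    }
    dplyr::bind_rows(rows)
  })
}
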