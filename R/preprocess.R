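# append a provenance entry (order audit: rereference -> filter -> reject ->
# correct -> epoch -> select); stored as an attribute on the object
add_prov <- function(x, step, detail = "") {
  prov <- attr(x, "provenance") %||% character(0)
  attr(x, "provenance") <- c(prov, paste0(step, if (nzchar(detail)) ": ", detail))
  x
}

#' Provenance trail of a processed object
#' @param x a recording or epoch set that has passed through preprocessing.
#' @return character vector of applied steps, in order.
#' @export
provenance <- function(x) attr(x, "provenance") %||% character(0)

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over good EEG channels from each EEG
#' channel. EOG and BAD channels neither contribute to the mean nor are
#' re-referenced. Pairwise differences between EEG channels are unchanged by
#' construction.
#'
#' @param rec a [recording()].
#' @return the re-referenced [recording()].
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "gs_recording"))
  eeg <- chan_idx(rec, "EEG")
  if (length(eeg) < 2)
    stop("average reference needs at least 2 good EEG channels; found ",
         length(eeg))
  avg <- colMeans(rec$data[eeg, , drop = FALSE])
  rec$data[eeg, ] <- sweep(rec$data[eeg, , drop = FALSE], 2, avg)
  add_prov(rec, "rereference_average",
           paste0(length(eeg), " EEG channels in mean"))
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed linear-phase FIR (transition width 25% of the low
#' cutoff), applied by FFT convolution with the group delay compensated, so
#' the net filter is zero-phase. All channels (EEG and EOG) are filtered.
#'
#' @param rec a [recording()].
#' @param highpass,lowpass band edges in Hz (defaults 1 and 100).
#' @return the filtered [recording()].
#' @export
bandpass <- function(rec, highpass = 1, lowpass = 100) {
  stopifnot(inherits(rec, "gs_recording"))
  nyq <- rec$sr / 2
  if (highpass <= 0 || lowpass <= highpass)
    stop("need 0 < highpass < lowpass")
  if (lowpass >= nyq)
    stop("lowpass cutoff ", lowpass, " Hz is at or above Nyquist (", nyq, " Hz)")
  tw <- 0.25 * highpass
  ntaps <- ceiling(3.3 * rec$sr / tw)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  if (ntaps >= ncol(rec$data))
    stop("recording too short for the requested filter (", ntaps,
         " taps); raise the high-pass cutoff or record longer")
  h <- signal::fir1(ntaps - 1, c(highpass, lowpass) / nyq, type = "pass")
  rec$data <- fft_filter(rec$data, h)
  add_prov(rec, "bandpass",
           sprintf("%g-%g Hz FIR, %d taps, zero-phase", highpass, lowpass, ntaps))
}

# zero-phase application of a symmetric FIR via FFT convolution; rows of
# `data` are channels. The (ntaps-1)/2 group delay is removed.
fft_filter <- function(data, h) {
  n <- ncol(data)
  ntaps <- length(h)
  nfft <- stats::nextn(n + ntaps - 1, 2)
  H <- fft(c(h, rep(0, nfft - ntaps)))
  delay <- (ntaps - 1) / 2
  out <- data
  for (i in seq_len(nrow(data))) {
    X <- fft(c(data[i, ], rep(0, nfft - n)))
    y <- Re(fft(X * H, inverse = TRUE)) / nfft
    out[i, ] <- y[delay + seq_len(n)]
  }
  out
}

#' Cut epochs around lock events
#'
#' One epoch per event whose code is in `lock`. Time zero of each epoch is
#' the first sample at or after the event (events carry exact 0-based sample
#' indices, so it is the event sample itself). Epochs that would run past
#' either edge of the recording are dropped and counted in the `n_dropped`
#' attribute. Condition labels come from `label_map` (lock code -> label;
#' codes map to themselves by default).
#'
#' @param rec a [recording()] with events.
#' @param lock character vector of lock event codes (e.g. `"response"` or
#'   `c("response", "midpoint")`).
#' @param tmin,tmax epoch window relative to the lock (s), `tmin < tmax`.
#' @param label_map named character vector mapping lock codes to condition
#'   labels, e.g. `c(response = "perceived", midpoint = "unperceived")`.
#' @return a [epoch_set()]; attribute `n_dropped` counts edge-truncated
#'   epochs that were discarded.
#' @export
epoch <- function(rec, lock, tmin, tmax, label_map = NULL) {
  stopifnot(inherits(rec, "gs_recording"), tmin < tmax)
  ev <- rec$events[rec$events$code %in% lock, , drop = FALSE]
  if (!nrow(ev)) stop("no events with code(s): ", paste(lock, collapse = ", "))
  rel <- seq(round(tmin * rec$sr), round(tmax * rec$sr))
  n <- ncol(rec$data)
  keep <- ev$sample_index + 1 + rel[1] >= 1 &
    ev$sample_index + 1 + rel[length(rel)] <= n
  n_dropped <- sum(!keep)
  ev <- ev[keep, , drop = FALSE]
  if (!nrow(ev)) stop("all epochs fall outside the recording")
  dat <- array(0, c(nrow(ev), nrow(rec$data), length(rel)))
  for (k in seq_len(nrow(ev)))
    dat[k, , ] <- rec$data[, ev$sample_index[k] + 1 + rel, drop = FALSE]
  labels <- ev$code
  if (!is.null(label_map)) labels <- unname(label_map[labels])
  ep <- epoch_set(dat, sr = rec$sr, tmin = tmin, tmax = tmax,
                  lock = paste(lock, collapse = "|"), labels = labels,
                  channel_labels = rec$channel_labels,
                  channel_kind = rec$channel_kind,
                  positions = rec$positions, trial_id = ev$trial_id)
  attr(ep, "n_dropped") <- n_dropped
  attr(ep, "provenance") <- attr(rec, "provenance")
  add_prov(ep, "epoch", sprintf("[%g, %g] s on %s; %d dropped at edges",
                                tmin, tmax, ep$lock, n_dropped))
}

#' Amplitude-based artifact rejection
#'
#' Removes every trial in which any EEG sample exceeds `eeg_thresh`
#' microvolts in magnitude or any EOG sample exceeds `eog_thresh`. The
#' returned log names each rejected trial and the first offending channel.
#' The operation is idempotent: surviving trials pass the same screen again.
#'
#' @param ep an [epoch_set()].
#' @param eeg_thresh,eog_thresh rejection thresholds in microvolts
#'   (defaults 75 and 100; use `eeg_thresh = 100` for the screen applied to
#'   response-locked rotation data). `Inf` disables a screen.
#' @return list: `epochs` (survivors), `log` (tibble: trial_id, channel,
#'   max_abs).
#' @export
reject_amplitude <- function(ep, eeg_thresh = 75, eog_thresh = 100) {
  stopifnot(inherits(ep, "gs_epochs"), eeg_thresh > 0, eog_thresh > 0)
  kinds <- ep$channel_kind
  thr <- ifelse(kinds == "EEG", eeg_thresh,
                ifelse(kinds == "EOG", eog_thresh, Inf))
  n_trial <- dim(ep$data)[1]
  bad <- logical(n_trial)
  log <- list()
  for (k in seq_len(n_trial)) {
    mx <- apply(abs(ep$data[k, , , drop = FALSE]), 2, max)
    over <- which(mx > thr)
    if (length(over)) {
      bad[k] <- TRUE
      log[[length(log) + 1]] <- tibble::tibble(
        trial_id = ep$trial_id[k],
        channel = ep$channel_labels[over[1]],
        max_abs = mx[over[1]])
    }
  }
  if (all(bad))
    stop("all ", n_trial, " trials exceed the amplitude thresholds; ",
         "review eeg_thresh/eog_thresh")
  out <- subset_trials(ep, !bad)
  out <- add_prov(out, "reject_amplitude",
                  sprintf("%d of %d trials rejected", sum(bad), n_trial))
  list(epochs = out,
       log = if (length(log)) dplyr::bind_rows(log) else
         tibble::tibble(trial_id = integer(), channel = character(),
                        max_abs = numeric()))
}

subset_trials <- function(ep, keep) {
  prov <- attr(ep, "provenance")
  out <- epoch_set(ep$data[keep, , , drop = FALSE], sr = ep$sr,
                   tmin = ep$tmin, tmax = ep$tmax, lock = ep$lock,
                   labels = ep$labels[keep],
                   channel_labels = ep$channel_labels,
                   channel_kind = ep$channel_kind, positions = ep$positions,
                   trial_id = ep$trial_id[keep])
  attr(out, "provenance") <- prov
  out
}

#' Regression-based ocular correction
#'
#' Estimates least-squares propagation coefficients of the EOG channels into
#' every EEG channel (on the concatenated epoch data) and subtracts the
#' fitted EOG contribution. A deterministic, automated alternative to
#' manual ICA component selection. EOG channels are left untouched.
#'
#' @param ep an [epoch_set()] containing at least one EOG channel.
#' @param eog_channels labels of the regressor channels (default: all
#'   channels of kind EOG).
#' @return the corrected [epoch_set()].
#' @export
correct_ocular_regression <- function(ep, eog_channels = NULL) {
  stopifnot(inherits(ep, "gs_epochs"))
  eog_channels <- eog_channels %||%
    ep$channel_labels[ep$channel_kind == "EOG"]
  eog_idx <- match(eog_channels, ep$channel_labels)
  if (!length(eog_idx) || anyNA(eog_idx))
    stop("EOG channel(s) not found")
  eeg_idx <- which(ep$channel_kind == "EEG")
  d <- dim(ep$data)
  flat <- function(i) as.vector(aperm(ep$data[, i, , drop = FALSE], c(3, 1, 2)))
  E <- vapply(eog_idx, flat, numeric(d[1] * d[3]))
  E <- sweep(E, 2, colMeans(E))
  if (any(apply(E, 2, stats::var) < 1e-12))
    stop("an EOG channel has (near-)zero variance; cannot regress")
  # propagation coefficients b = (E'E)^-1 E'y per EEG channel
  EtE_inv <- solve(crossprod(E))
  for (i in eeg_idx) {
    y <- flat(i)
    b <- EtE_inv %*% crossprod(E, y - mean(y))
    fitted <- as.vector(E %*% b)
    ep$data[, i, ] <- ep$data[, i, ] -
      aperm(array(fitted, c(d[3], d[1])), c(2, 1))
  }
  add_prov(ep, "correct_ocular_regression",
           paste(eog_channels, collapse = "+"))
}

#' Select trials by behavioural rules
#'
#' Keeps trials satisfying every requested rule (intersection semantics):
#' `response_window` keeps trials whose response time lies inside the given
#' closed interval (trials without a response fail the rule);
#' `correct_only` keeps correctly categorized trials; `perceived` keeps
#' trials with the given perceived flag.
#'
#' @param ep an [epoch_set()].
#' @param behaviour a [behaviour_log()] matched by `trial_id`.
#' @param response_window numeric length-2, seconds, or `NULL` to skip.
#' @param correct_only logical.
#' @param perceived `TRUE`, `FALSE` or `NULL` to skip.
#' @return list: `epochs`, `counts` (tibble of trials removed per rule).
#' @export
select_trials <- function(ep, behaviour, response_window = NULL,
                          correct_only = FALSE, perceived = NULL) {
  stopifnot(inherits(ep, "gs_epochs"))
  beh <- behaviour[match(ep$trial_id, behaviour$trial_id), , drop = FALSE]
  keep <- rep(TRUE, length(ep$trial_id))
  counts <- list()
  if (!is.null(response_window)) {
    ok <- !is.na(beh$response_time) &
      beh$response_time >= response_window[1] &
      beh$response_time <= response_window[2]
    counts$response_window <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (isTRUE(correct_only)) {
    ok <- !is.na(beh$correct) & beh$correct
    counts$correct_only <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (!is.null(perceived)) {
    ok <- !is.na(beh$perceived) & beh$perceived == perceived
    counts$perceived <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (!any(keep)) stop("trial selection removed every trial")
  out <- subset_trials(ep, keep)
  out <- add_prov(out, "select_trials",
                  sprintf("%d of %d kept", sum(keep), length(keep)))
  list(epochs = out,
       counts = tibble::tibble(rule = names(counts),
                               removed = unlist(counts, use.names = FALSE)))
}

#' Baseline-corrected event-related-potential average
#'
#' Per-trial baseline mean (over `baseline_window`) is subtracted before
#' averaging across trials.
#'
#' @param ep an [epoch_set()].
#' @param baseline_window numeric length-2, seconds relative to the lock
#'   (e.g. `c(-0.25, 0)`).
#' @return channels x time matrix with attributes `times` and `n_trials`.
#' @export
erp_average <- function(ep, baseline_window = c(-0.25, 0)) {
  stopifnot(inherits(ep, "gs_epochs"))
  bidx <- which(ep$times >= baseline_window[1] & ep$times <= baseline_window[2])
  if (!length(bidx)) stop("baseline window outside the epoch")
  d <- ep$data
  base <- apply(d[, , bidx, drop = FALSE], c(1, 2), mean)
  d <- sweep(d, c(1, 2), base)
  out <- apply(d, c(2, 3), mean)
  rownames(out) <- ep$channel_labels
  attr(out, "times") <- ep$times
  attr(out, "n_trials") <- dim(ep$data)[1]
  out
}
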