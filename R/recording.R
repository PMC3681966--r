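#' Multi-channel continuous EEG recording
#'
#' A `gs_recording` holds a channels-by-samples signal matrix in microvolts
#' together with its sampling rate, channel metadata and an event table.
#' Channels are typed as `"EEG"`, `"EOG"` or `"BAD"`; downstream operations
#' (average reference, artifact screening, synchrony) use the type to decide
#' which channels participate. Scalp positions live on a unit head circle
#' (vertex at the origin) and are required for EEG channels so that
#' topographic exports always have coordinates.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sr sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel names
#'   (10-20 convention, e.g. `"OZ"`, `"PO3"`).
#' @param channel_kind character vector, one of `"EEG"`, `"EOG"`, `"BAD"`
#'   per channel. Defaults to all-EEG.
#' @param positions data frame with columns `label`, `x`, `y` (unit head
#'   circle) or `NULL` to look the labels up in the packaged montages.
#' @param events an event table as returned by [event_table()].
#' @return an object of class `gs_recording`.
#' @seealso [event_table()], [read_edf()], [standard_montage()]
#' @export
recording <- function(data, sr, channel_labels,
                      channel_kind = NULL, positions = NULL,
                      events = event_table()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(sr) || length(sr) != 1 || !is.finite(sr) || sr <= 0)
    stop("`sr` must be a single positive number (Hz)")
  channel_labels <- as.character(channel_labels)
  if (nrow(data) != length(channel_labels))
    stop("`data` has ", nrow(data), " rows but ", length(channel_labels),
         " channel labels were given")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  channel_kind <- channel_kind %||% rep("EEG", length(channel_labels))
  channel_kind <- toupper(as.character(channel_kind))
  if (length(channel_kind) != length(channel_labels))
    stop("`channel_kind` length must match channel count")
  bad_kind <- setdiff(unique(channel_kind), c("EEG", "EOG", "BAD"))
  if (length(bad_kind))
    stop("unknown channel kind(s): ", paste(bad_kind, collapse = ", "))
  if (is.null(positions)) {
    positions <- montage_lookup(channel_labels)
  } else {
    positions <- as.data.frame(positions)
    stopifnot(all(c("label", "x", "y") %in% names(positions)))
  }
  eeg <- channel_labels[channel_kind == "EEG"]
  missing_pos <- setdiff(eeg, positions$label)
  if (length(missing_pos))
    stop("no scalp position for EEG channel(s): ",
         paste(missing_pos, collapse = ", "))
  events <- validate_events(events, n_samples = ncol(data))
  rownames(data) <- channel_labels
  structure(
    list(data = data, sr = sr, channel_labels = channel_labels,
         channel_kind = channel_kind, positions = positions, events = events),
    class = "gs_recording")
}

#' @export
print.gs_recording <- function(x, ...) {
  cat(sprintf("<gs_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$sr, ncol(x$data) / x$sr))
  cat(sprintf("  kinds: %s\n",
              paste(sprintf("%s=%d", names(table(x$channel_kind)),
                            table(x$channel_kind)), collapse = " ")))
  cat(sprintf("  events: %d rows\n", nrow(x$events)))
  invisible(x)
}

#' @export
dim.gs_recording <- function(x) dim(x$data)

# indices of channels of a given kind
chan_idx <- function(rec, kind) which(rec$channel_kind %in% kind)

#' Event table for a recording
#'
#' Events are stored as a tibble with 0-based `sample_index` (so that
#' `time = sample_index / sr` exactly), an event `code` and a `trial_id`.
#' Recognised codes are `target_face`, `target_guitar`, `frequent`,
#' `movie_onset`, `response`, `trial_end` and `midpoint` (the synthetic lock
#' used for unperceived rotating-stimulus trials). Tables are kept sorted by
#' `sample_index`.
#'
#' @param sample_index integer vector of 0-based sample indices (>= 0).
#' @param code character vector of event codes.
#' @param trial_id non-negative integer vector of trial ids.
#' @return a tibble of class `gs_events`.
#' @export
event_table <- function(sample_index = integer(), code = character(),
                        trial_id = integer()) {
  tb <- tibble::tibble(sample_index = as.integer(sample_index),
                       code = as.character(code),
                       trial_id = as.integer(trial_id))
  validate_events(tb)
}

gs_event_codes <- c("target_face", "target_guitar", "frequent",
                    "movie_onset", "response", "trial_end", "midpoint")

validate_events <- function(ev, n_samples = NULL) {
  ev <- tibble::as_tibble(ev)
  needed <- c("sample_index", "code", "trial_id")
  if (!all(needed %in% names(ev)))
    stop("event table needs columns: ", paste(needed, collapse = ", "))
  if (nrow(ev)) {
    if (any(ev$sample_index < 0)) stop("negative sample index in event table")
    unknown <- setdiff(unique(ev$code), gs_event_codes)
    if (length(unknown))
      stop("unknown event code(s): ", paste(unknown, collapse = ", "))
    if (any(ev$trial_id < 0)) stop("negative trial_id in event table")
    if (!is.null(n_samples) && any(ev$sample_index >= n_samples))
      stop("event sample_index beyond recording length")
    ev <- ev[order(ev$sample_index), , drop = FALSE]
  }
  class(ev) <- unique(c("gs_events", class(ev)))
  ev
}

#' Epoched EEG data
#'
#' Trials x channels x time array cut around a lock event. Time zero is the
#' first sample at or after the lock event; the time axis is
#' `seq(round(tmin*sr), round(tmax*sr)) / sr`.
#'
#' @param data numeric array, trials x channels x time.
#' @param sr sampling rate (Hz).
#' @param tmin,tmax epoch bounds relative to the lock event (s).
#' @param lock event code used for time zero.
#' @param labels per-trial condition labels (e.g. `"perceived"`).
#' @param channel_labels,channel_kind,positions channel metadata, normally
#'   inherited from the source recording.
#' @param trial_id optional integer ids tying trials back to the event table.
#' @return an object of class `gs_epochs`.
#' @export
epoch_set <- function(data, sr, tmin, tmax, lock, labels,
                      channel_labels, channel_kind = NULL, positions = NULL,
                      trial_id = NULL) {
  stopifnot(length(dim(data)) == 3)
  n_time <- round((tmax - tmin) * sr) + 1
  if (abs(dim(data)[3] - n_time) > 1)
    stop("time axis length ", dim(data)[3], " inconsistent with window [",
         tmin, ", ", tmax, "] at ", sr, " Hz (expected ", n_time, ")")
  if (dim(data)[1] != length(labels))
    stop("labels length must equal trial count")
  if (dim(data)[2] != length(channel_labels))
    stop("channel_labels length must equal channel count")
  channel_kind <- channel_kind %||% rep("EEG", length(channel_labels))
  trial_id <- trial_id %||% seq_len(dim(data)[1])
  times <- seq(round(tmin * sr), length.out = dim(data)[3]) / sr
  structure(
    list(data = data, sr = sr, tmin = tmin, tmax = tmax, lock = lock,
         labels = as.character(labels), times = times,
         channel_labels = as.character(channel_labels),
         channel_kind = channel_kind, positions = positions,
         trial_id = as.integer(trial_id)),
    class = "gs_epochs")
}

#' @export
print.gs_epochs <- function(x, ...) {
  cat(sprintf("<gs_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sr))
  cat(sprintf("  window [%g, %g] s locked to '%s'\n", x$tmin, x$tmax, x$lock))
  lt <- table(x$labels)
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", names(lt), lt), collapse = " ")))
  invisible(x)
}

#' @export
dim.gs_epochs <- function(x) dim(x$data)

#' Behavioural log
#'
#' One row per trial: response time in seconds (`NA` when no response),
#' whether the subject reported perceiving the stimulus, and whether the
#' response/categorization was correct.
#'
#' @param trial_id integer trial ids.
#' @param response_time numeric seconds, `NA` if absent.
#' @param perceived,correct logical flags.
#' @param trial_duration optional scalar; response times are checked to lie
#'   inside `(0, trial_duration)` when given.
#' @return tibble of class `gs_behaviour`.
#' @export
behaviour_log <- function(trial_id, response_time, perceived, correct,
                          trial_duration = NULL) {
  tb <- tibble::tibble(trial_id = as.integer(trial_id),
                       response_time = as.numeric(response_time),
                       perceived = as.logical(perceived),
                       correct = as.logical(correct))
  rt <- tb$response_time[!is.na(tb$response_time)]
  if (any(rt <= 0)) stop("response_time must be positive when present")
  if (!is.null(trial_duration) && any(rt >= trial_duration))
    stop("response_time beyond trial duration")
  class(tb) <- unique(c("gs_behaviour", class(tb)))
  tb
}
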