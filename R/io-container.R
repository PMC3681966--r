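#' Single-file array container
#'
#' The package's native interchange format for recordings, epoch sets and
#' time-frequency objects: a magic string, a JSON metadata block (class,
#' sampling rate, channel metadata, event rows, array names/dims) and the
#' arrays as little-endian doubles (complex arrays as real then imaginary
#' parts). Unlike EDF it is lossless (no 16-bit quantization), so it is the
#' format used between pipeline stages.
#'
#' @param x a `gs_recording`, `gs_epochs` or `gs_tfr` object.
#' @param path file path (conventionally `.gsc`).
#' @return `path` invisibly for the writer; the reconstructed object for the
#'   reader.
#' @export
write_container <- function(x, path) {
  UseMethod("write_container")
}

gsc_write <- function(path, meta, arrays) {
  con <- file(path, "wb")
  on.exit(close(con))
  meta$arrays <- lapply(arrays, function(a)
    list(dim = dim(a) %||% length(a), complex = is.complex(a)))
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null")
  raw_json <- charToRaw(as.character(json))
  writeChar("GSC1", con, eos = NULL)
  writeBin(length(raw_json), con, size = 4, endian = "little")
  writeBin(raw_json, con)
  for (a in arrays) {
    if (is.complex(a)) {
      writeBin(as.double(Re(a)), con, size = 8, endian = "little")
      writeBin(as.double(Im(a)), con, size = 8, endian = "little")
    } else {
      writeBin(as.double(a), con, size = 8, endian = "little")
    }
  }
  invisible(path)
}

gsc_read_raw <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "GSC1")) stop("not a gammasync container: ", path)
  n <- readBin(con, "integer", size = 4, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n)),
                             simplifyDataFrame = TRUE)
  arrays <- lapply(meta$arrays, function(spec) {
    len <- prod(unlist(spec$dim))
    if (isTRUE(spec$complex)) {
      re <- readBin(con, "double", len, size = 8, endian = "little")
      im <- readBin(con, "double", len, size = 8, endian = "little")
      a <- complex(real = re, imaginary = im)
    } else {
      a <- readBin(con, "double", len, size = 8, endian = "little")
    }
    if (length(a) < len) stop("truncated container: ", path)
    array(a, dim = unlist(spec$dim))
  })
  list(meta = meta, arrays = arrays)
}

events_to_meta <- function(ev) {
  if (nrow(ev) == 0) NULL else as.list(as.data.frame(ev))
}

meta_to_events <- function(m) {
  if (is.null(m) || length(m) == 0) return(event_table())
  event_table(sample_index = m$sample_index, code = m$code,
              trial_id = m$trial_id)
}

#' @export
write_container.gs_recording <- function(x, path) {
  meta <- list(class = "gs_recording", sr = x$sr,
               channel_labels = x$channel_labels,
               channel_kind = x$channel_kind,
               positions = as.list(x$positions),
               events = events_to_meta(x$events))
  gsc_write(path, meta, list(data = x$data))
}

#' @export
write_container.gs_epochs <- function(x, path) {
  meta <- list(class = "gs_epochs", sr = x$sr, tmin = x$tmin, tmax = x$tmax,
               lock = x$lock, labels = x$labels, trial_id = x$trial_id,
               channel_labels = x$channel_labels,
               channel_kind = x$channel_kind,
               positions = if (is.null(x$positions)) NULL else as.list(x$positions))
  gsc_write(path, meta, list(data = x$data))
}

#' @export
write_container.gs_tfr <- function(x, path) {
  meta <- list(class = "gs_tfr", sr = x$sr, freqs = x$freqs, times = x$times,
               labels = x$labels, trial_id = x$trial_id,
               channel_labels = x$channel_labels,
               channel_kind = x$channel_kind,
               normalized = x$normalized,
               baseline = x$baseline,
               clip_fraction = x$clip_fraction)
  arrays <- list()
  if (!is.null(x$power)) arrays$power <- x$power
  if (!is.null(x$coeffs)) arrays$coeffs <- x$coeffs
  gsc_write(path, meta, arrays)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  r <- gsc_read_raw(path)
  m <- r$meta
  switch(m$class,
    gs_recording = recording(
      r$arrays$data, sr = m$sr, channel_labels = m$channel_labels,
      channel_kind = m$channel_kind,
      positions = as.data.frame(m$positions),
      events = meta_to_events(m$events)),
    gs_epochs = epoch_set(
      r$arrays$data, sr = m$sr, tmin = m$tmin, tmax = m$tmax, lock = m$lock,
      labels = m$labels, channel_labels = m$channel_labels,
      channel_kind = m$channel_kind,
      positions = if (is.null(m$positions)) NULL else as.data.frame(m$positions),
      trial_id = m$trial_id),
    gs_tfr = new_tfr(
      power = r$arrays$power, coeffs = r$arrays$coeffs,
      freqs = m$freqs, times = m$times, sr = m$sr, labels = m$labels,
      trial_id = m$trial_id, channel_labels = m$channel_labels,
      channel_kind = m$channel_kind,
      normalized = isTRUE(m$normalized), baseline = m$baseline,
      clip_fraction = m$clip_fraction),
    stop("unknown container class: ", m$class))
}

#' Read or write event tables as CSV
#'
#' Plain comma- or tab-separated text with a header row and columns
#' `sample_index` (0-based), `code`, `trial_id`. Rows are sorted by sample
#' index on read; unknown codes or negative indices are rejected.
#'
#' @param path file path.
#' @param events an [event_table()].
#' @return [read_events()] returns an [event_table()];
#'   [write_events()] returns `path` invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  event_table(sample_index = df$sample_index, code = df$code,
              trial_id = df$trial_id)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write behaviour logs as CSV
#'
#' Columns `trial_id`, `response_time` (s, empty when absent), `perceived`,
#' `correct`.
#'
#' @param path file path.
#' @param log a [behaviour_log()].
#' @return [read_behaviour()] returns a [behaviour_log()];
#'   [write_behaviour()] returns `path` invisibly.
#' @export
read_behaviour <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  behaviour_log(trial_id = df$trial_id, response_time = df$response_time,
                perceived = df$perceived, correct = df$correct)
}

#' @rdname read_behaviour
#' @export
write_behaviour <- function(log, path) {
  write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a recording in a chosen format
#'
#' Dispatch wrappers over the two storage backends: `"edf"` (16-bit
#' interchange, see [read_edf()]) and `"container"` (the lossless
#' single-file array store, see [read_container()]). The format is inferred
#' from the file extension when not given.
#'
#' @param path file path (`.edf` or `.gsc`).
#' @param format `"edf"`, `"container"`, or `NULL` to infer.
#' @param rec a [recording()] (writer only).
#' @return [read_recording()] returns a [recording()];
#'   [write_recording()] returns `path` invisibly.
#' @export
read_recording <- function(path, format = NULL) {
  format <- format %||%
    if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "container"
  switch(match.arg(format, c("edf", "container")),
         edf = read_edf(path),
         container = read_container(path))
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "gs_recording"))
  format <- format %||%
    if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "container"
  switch(match.arg(format, c("edf", "container")),
         edf = write_edf(rec, path),
         container = write_container(rec, path))
}
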