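#' Read a continuous EDF file
#'
#' A minimal reader for the European Data Format (EDF, 16-bit continuous
#' recordings): ASCII header, per-signal headers, little-endian int16 data
#' records. Channel kind is recovered from the conventional label prefix
#' written by [write_edf()] (`"EEG OZ"`, `"EOG VEOG"`, ...); labels without a
#' recognised prefix are kept and marked `BAD` rather than dropped. Events
#' are not part of EDF and travel separately (see [read_events()]).
#'
#' @param path path to an EDF file.
#' @return a [recording()].
#' @seealso [write_edf()] for the quantization note.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    x <- readChar(con, n, useBytes = TRUE)
    if (length(x) == 0 || nchar(x, type = "bytes") < n)
      stop("malformed EDF header: truncated file")
    x
  }
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) stop("malformed EDF header: bad ", what, " field ('",
                       trimws(s), "')")
    v
  }
  version <- trimws(rd(8))
  if (version != "0") stop("malformed EDF header: version '", version, "'")
  rd(80); rd(80); rd(8); rd(8)                  # patient, recording, date, time
  header_bytes <- num(rd(8), "header size")
  rd(44)                                        # reserved
  n_records <- num(rd(8), "record count")
  rec_dur <- num(rd(8), "record duration")
  ns <- as.integer(num(rd(4), "signal count"))
  if (ns < 1) stop("malformed EDF header: no signals")
  if (rec_dur <= 0)
    stop("malformed EDF header: record duration missing or non-positive ",
         "(sampling rate undefined)")
  fields <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels_raw <- fields(16)
  fields(80)                                    # transducer
  fields(8)                                     # physical dimension
  pmin <- as.numeric(fields(8)); pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  if (anyNA(c(pmin, pmax, dmin, dmax)))
    stop("malformed EDF header: non-numeric calibration fields")
  fields(80)                                    # prefilter
  spr <- as.integer(as.numeric(fields(8)))
  fields(32)                                    # reserved
  if (length(unique(spr)) != 1)
    stop("EDF files with per-signal sampling rates are not supported")
  expected_header <- 256 * (ns + 1)
  if (header_bytes != expected_header)
    stop("malformed EDF header: header size ", header_bytes,
         " != ", expected_header)
  sr <- spr[1] / rec_dur

  n_samp <- n_records * spr[1]
  data <- matrix(0, ns, n_samp)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     signed = TRUE, endian = "little")
    if (length(block) < ns * spr[1]) stop("malformed EDF file: short record")
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- matrix(block, nrow = spr[1])[, seq_len(ns)] |> t()
  }
  # digital -> physical calibration
  gain <- (pmax - pmin) / (dmax - dmin)
  for (i in seq_len(ns)) data[i, ] <- (data[i, ] - dmin[i]) * gain[i] + pmin[i]

  kind <- rep("BAD", ns)
  label <- labels_raw
  m <- regexpr("^(EEG|EOG|BAD) ", labels_raw)
  has_prefix <- m > 0
  kind[has_prefix] <- substr(labels_raw[has_prefix], 1, 3)
  label[has_prefix] <- trimws(substring(labels_raw[has_prefix], 5))
  # unprefixed labels that resolve in the packaged montages are usable EEG
  plain <- !has_prefix & toupper(label) %in% montage_lookup(toupper(label))$label
  kind[plain] <- "EEG"
  if (anyDuplicated(label))
    stop("duplicate channel labels in EDF: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  pos <- montage_lookup(label)
  # EEG channels with no montage position cannot be used downstream -> BAD
  kind[kind == "EEG" & !(label %in% pos$label)] <- "BAD"
  recording(data, sr = sr, channel_labels = label, channel_kind = kind,
            positions = pos)
}

#' Write a recording to EDF
#'
#' Writes 16-bit EDF with 1-second data records. EDF quantizes each channel
#' to 65534 steps over its physical range; the per-channel quantization step
#' is `2 * max(abs(x)) / 65534` microvolts and round-trips are exact to half
#' that step. The sampling rate must be a whole number of samples per second
#' and the signal is zero-padded to a whole number of records.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "gs_recording"))
  if (abs(rec$sr - round(rec$sr)) > 1e-9)
    stop("EDF export needs an integer sampling rate (whole samples per ",
         "1-s record); got ", rec$sr)
  sr <- round(rec$sr)
  ns <- nrow(rec$data)
  n_records <- ceiling(ncol(rec$data) / sr)
  data <- cbind(rec$data,
                matrix(0, ns, n_records * sr - ncol(rec$data)))
  pmax <- pmax(apply(abs(data), 1, max), 1)    # physical range, symmetric
  dig <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) {
    s <- as.character(s)
    if (nchar(s) > w) s <- substr(s, 1, w)
    writeChar(formatC(s, width = -w), con, eos = NULL)
  }
  pad("0", 8); pad("X", 80); pad("gammasync", 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  pad(256 * (ns + 1), 8); pad("", 44)
  pad(n_records, 8); pad(1, 8); pad(ns, 4)
  for (i in seq_len(ns)) pad(paste(rec$channel_kind[i], rec$channel_labels[i]), 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(format(-pmax[i], digits = 6), 8)
  for (i in seq_len(ns)) pad(format(pmax[i], digits = 6), 8)
  for (i in seq_len(ns)) pad(-dig, 8)
  for (i in seq_len(ns)) pad(dig, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(sr, 8)
  for (i in seq_len(ns)) pad("", 32)

  # header fields are re-read on import, so physical max must match what we
  # scale by: use the rounded text representation
  pmax_used <- as.numeric(format(pmax, digits = 6))
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * sr + 1):(r * sr)
    block <- vapply(seq_len(ns), function(i)
      as.integer(round(data[i, idx] / pmax_used[i] * dig)), integer(sr))
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}
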