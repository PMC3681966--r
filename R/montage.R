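#' Packaged scalp montages
#'
#' Channel positions on a unit head circle (vertex at the origin; radius 1 is
#' the circumference ring through FPZ, T7/T8 and OZ; inferior electrodes such
#' as PO9/PO10 sit slightly outside it). Two tables ship with the package:
#' the 64-channel 10-10 set, and a best-effort 128-channel layout
#' (`montage_128_standard.tsv`) extending it with intermediate 10-5 rows --
#' best effort because no channel list is published for 128-channel caps and
#' coordinates here follow a standard interpolated grid, not digitized
#' positions.
#'
#' @param n montage size, 64 or 128.
#' @return tibble with columns `label`, `x`, `y`.
#' @examples
#' standard_montage(64)
#' @export
standard_montage <- function(n = 64) {
  file <- switch(as.character(n),
                 "64" = "montage_64.tsv",
                 "128" = "montage_128_standard.tsv",
                 stop("no packaged montage with ", n, " channels"))
  path <- system.file("extdata", file, package = "gammasync", mustWork = TRUE)
  tb <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  tb$label <- toupper(tb$label)
  tb
}

# positions for a set of labels, searched in the 64- then 128-channel tables;
# labels absent from both (e.g. EOG) are returned without coordinates
montage_lookup <- function(labels) {
  tabs <- rbind(standard_montage(64), standard_montage(128))
  tabs <- tabs[!duplicated(tabs$label), ]
  hit <- match(toupper(labels), tabs$label)
  out <- tibble::tibble(label = labels,
                        x = tabs$x[hit], y = tabs$y[hit])
  out[!is.na(out$x), , drop = FALSE]
}

#' Occipito-parietal channel roster used for perceptual-state decoding
#'
#' The centro/occipito-parietal channels over which decoding features are
#' averaged: C1/Z/2, CP1/3/Z/2/4, P1/Z/4, PO9/7/5/3/Z/4/6/8/10, O1/Z/2.
#'
#' @return character vector of channel labels.
#' @export
occipitoparietal_roster <- function() {
  c("C1", "CZ", "C2",
    "CP1", "CP3", "CPZ", "CP2", "CP4",
    "P1", "PZ", "P4",
    "PO9", "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8", "PO10",
    "O1", "OZ", "O2")
}
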