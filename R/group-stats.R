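# signed-rank / rank-sum z statistic with continuity correction and tie
# handling (normal approximation; p-values come from wilcox.test, which is
# exact for small untied samples)
wilcox_z <- function(a, b, paired) {
  if (paired) {
    d <- a - b
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) return(0)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  } else {
    n1 <- length(a); n2 <- length(b)
    r <- rank(c(a, b))
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(r)
    v <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  }
  if (v <= 0) return(0)
  (W - mu - 0.5 * sign(W - mu)) / sqrt(v)
}

#' Per-timepoint Wilcoxon contrast maps
#'
#' Runs a Wilcoxon test at every (band, time) cell of two condition series:
#' signed-rank for paired data, rank-sum for independent samples. P-values
#' are exact for small untied samples (n <= 25) and use the
#' continuity-corrected normal approximation otherwise; a z statistic with
#' continuity correction is always reported. Within each band, p-values are
#' Holm-corrected over time points and maximal runs of corrected
#' significance are extracted as windows.
#'
#' @param cond_a,cond_b tibbles with columns `band`, `time`, `unit`
#'   (subject or trial id) and `value`, e.g. reshaped from [band_average()].
#' @param paired if `TRUE`, units are matched across conditions
#'   (signed-rank); otherwise rank-sum.
#' @param alpha family-wise level for the Holm correction.
#' @param min_duration minimum window length (s) for
#'   [significant_windows()].
#' @return a `gs_contrast` object; see [tidy.gs_contrast()].
#' @export
wilcoxon_map <- function(cond_a, cond_b, paired = TRUE, alpha = 0.05,
                         min_duration = 0) {
  check_series <- function(x, nm) {
    if (!all(c("band", "time", "unit", "value") %in% names(x)))
      stop(nm, " needs columns band, time, unit, value")
    x
  }
  cond_a <- check_series(tibble::as_tibble(cond_a), "cond_a")
  cond_b <- check_series(tibble::as_tibble(cond_b), "cond_b")
  bands <- intersect(unique(cond_a$band), unique(cond_b$band))
  rows <- list()
  windows <- list()
  for (bn in bands) {
    a <- cond_a[cond_a$band == bn, ]
    b <- cond_b[cond_b$band == bn, ]
    times <- sort(intersect(unique(a$time), unique(b$time)))
    stat <- p <- numeric(length(times))
    tied <- logical(length(times))
    for (k in seq_along(times)) {
      av <- a$value[a$time == times[k]][order(a$unit[a$time == times[k]])]
      bv <- b$value[b$time == times[k]][order(b$unit[b$time == times[k]])]
      n_min <- min(length(av), length(bv))
      if (n_min < 5) stop("need at least 5 observations per condition")
      if (paired && length(av) != length(bv))
        stop("paired test needs matched units")
      if ((paired && all(av - bv == 0)) ||
          (!paired && length(unique(c(av, bv))) == 1)) {
        # a fully tied cell carries no evidence either way
        tied[k] <- TRUE
        stat[k] <- 0
        p[k] <- 1
        next
      }
      wt <- suppressWarnings(
        wilcox.test(av, bv, paired = paired,
                    exact = n_min <= 25, correct = TRUE))
      stat[k] <- wilcox_z(av, bv, paired)
      p[k] <- wt$p.value
    }
    if (all(tied))
      stop("all-tied data in band ", bn, "; nothing to test")
    hc <- holm_correct(p, alpha)
    rows[[bn]] <- tibble::tibble(band = bn, time = times, z = stat, p = p,
                                 p_adj = hc$p_adj, sig = hc$mask)
    win <- significant_windows(hc$mask, times, min_duration)
    if (nrow(win)) windows[[bn]] <- tibble::tibble(band = bn, win)
  }
  new_contrast(dplyr::bind_rows(rows),
               windows = dplyr::bind_rows(windows),
               test = if (paired) "wilcoxon_signed_rank" else "rank_sum",
               alpha = alpha)
}

new_contrast <- function(table, windows, test, alpha) {
  structure(list(table = table,
                 windows = windows %||%
                   tibble::tibble(band = character(), t_start = numeric(),
                                  t_end = numeric()),
                 test = test, alpha = alpha),
            class = "gs_contrast")
}

#' @export
print.gs_contrast <- function(x, ...) {
  cat(sprintf("<gs_contrast> %s, alpha = %g\n", x$test, x$alpha))
  print(x$table, n = 8)
  if (nrow(x$windows)) {
    cat("significant windows:\n")
    print(x$windows)
  }
  invisible(x)
}

#' @rdname wilcoxon_map
#' @param x a `gs_contrast`.
#' @param ... unused.
#' @export
tidy.gs_contrast <- function(x, ...) x$table

#' @rdname wilcoxon_map
#' @export
glance.gs_contrast <- function(x, ...) {
  tibble::tibble(test = x$test, alpha = x$alpha,
                 n_tests = nrow(x$table),
                 n_significant = sum(x$table$sig),
                 n_windows = nrow(x$windows))
}

#' Paired t contrast of band power over a declared window
#'
#' Averages each unit's values over `window` per band and runs a two-sided
#' paired t-test per band, Holm-corrected across the band family. The t
#' statistic has the sign of `mean(cond_a - cond_b)`: passing the
#' no-perception condition as `cond_a` yields negative t when perception
#' power is higher.
#'
#' @param cond_a,cond_b tibbles with columns `band`, `time`, `unit`,
#'   `value`; units must match across conditions.
#' @param window numeric length-2 (s); default `c(-1, 0)`, the second
#'   before the report.
#' @param alpha Holm family-wise level.
#' @return a `gs_contrast` whose table has one row per band (`t`, `df`,
#'   `p`, `p_adj`, `sig`).
#' @export
paired_t_band <- function(cond_a, cond_b, window = c(-1, 0), alpha = 0.05) {
  win_mean <- function(x) {
    x <- x[x$time >= window[1] & x$time <= window[2], ]
    if (!nrow(x)) stop("declared window contains no time points")
    stats::aggregate(value ~ band + unit, data = as.data.frame(x), FUN = mean)
  }
  a <- win_mean(tibble::as_tibble(cond_a))
  b <- win_mean(tibble::as_tibble(cond_b))
  bands <- intersect(unique(a$band), unique(b$band))
  rows <- list()
  for (bn in bands) {
    av <- a[a$band == bn, ]; bv <- b[b$band == bn, ]
    m <- merge(av, bv, by = "unit", suffixes = c("_a", "_b"))
    if (nrow(m) < 3) stop("paired t needs at least 3 units")
    d <- m$value_a - m$value_b
    if (sd(d) == 0) stop("zero variance of paired differences in band ", bn)
    tt <- t.test(m$value_a, m$value_b, paired = TRUE)
    rows[[bn]] <- tibble::tibble(band = bn, n = nrow(m),
                                 t = unname(tt$statistic),
                                 df = unname(tt$parameter),
                                 p = tt$p.value)
  }
  tb <- dplyr::bind_rows(rows)
  hc <- holm_correct(tb$p, alpha)
  tb$p_adj <- hc$p_adj
  tb$sig <- hc$mask
  new_contrast(tb, windows = NULL, test = "paired_t", alpha = alpha)
}

#' Step-down Holm correction
#'
#' Sorts p-values ascending and rejects while `p_(k) <= alpha / (m - k + 1)`
#' (adjusted p-values via [stats::p.adjust()], monotone non-decreasing in
#' rank). Rejections are always a superset of Bonferroni's and a subset of
#' the uncorrected ones.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error level.
#' @return list: `mask` (logical rejections), `p_adj` (adjusted p-values).
#' @export
holm_correct <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p_adj <- p.adjust(pvals, method = "holm")
  list(mask = !is.na(p_adj) & p_adj <= alpha, p_adj = p_adj)
}

#' Contiguous significant windows
#'
#' Maximal runs of consecutive significant time points, reported in seconds;
#' runs shorter than `min_duration` are discarded.
#'
#' @param mask logical vector (significance per time point).
#' @param times numeric vector of time stamps (s), same length.
#' @param min_duration minimum `t_end - t_start` to keep (s).
#' @return tibble: `t_start`, `t_end`, `n_points`.
#' @export
significant_windows <- function(mask, times, min_duration = 0) {
  stopifnot(length(mask) == length(times))
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- tibble::tibble(t_start = times[starts[keep]],
                        t_end = times[ends[keep]],
                        n_points = r$lengths[keep])
  out[out$t_end - out$t_start >= min_duration, , drop = FALSE]
}

#' Behavioural summary
#'
#' Hit rate over all trials; detection-time mean and SD over perceived
#' trials with a response.
#'
#' @param log a [behaviour_log()].
#' @return one-row tibble: `n_trials`, `hit_rate` (%), `n_perceived`,
#'   `detection_mean`, `detection_sd` (s; `NA` when no perceived trials).
#' @export
behaviour_summary <- function(log) {
  stopifnot(all(c("perceived", "correct", "response_time") %in% names(log)))
  rt <- log$response_time[log$perceived & !is.na(log$response_time)]
  tibble::tibble(
    n_trials = nrow(log),
    hit_rate = 100 * mean(log$correct, na.rm = TRUE),
    n_perceived = sum(log$perceived, na.rm = TRUE),
    detection_mean = if (length(rt)) mean(rt) else NA_real_,
    detection_sd = if (length(rt) > 1) sd(rt) else NA_real_)
}

#' Convert detection time to stimulus rotation angle
#'
#' The rotating stimulus turns 180 degrees from inverted to upright over the
#' first 9 s of the movie (20 degrees/s) and then holds, so
#' `angle = min(t, 9) * 20`. A mean detection time of 4.30 s corresponds to
#' 86 degrees from the inverted position.
#'
#' @param t detection time(s) in seconds (>= 0).
#' @param span_s rotation duration (default 9 s).
#' @param total_deg total rotation (default 180 degrees).
#' @return rotation angle(s) in degrees from inverted.
#' @export
time_to_angle <- function(t, span_s = 9, total_deg = 180) {
  if (any(t < 0, na.rm = TRUE)) stop("detection time must be non-negative")
  pmin(t, span_s) * total_deg / span_s
}
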