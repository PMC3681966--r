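pipeline_schema <- list(
  top = c("seed", "out_dir", "paradigm", "stages", "simulate", "preprocess",
          "tfr", "sync", "stats", "classify"),
  simulate = c("n_channels", "sr", "n_trials", "perceived_prob",
               "exact_counts", "hit_prob", "noise_exponent", "noise_rms",
               "blink_rate", "blink_amplitude", "blink_decay", "burst_lead"),
  preprocess = c("highpass", "lowpass", "eeg_reject", "eog_reject",
                 "tmin", "tmax", "ocular_correction", "response_window"),
  tfr = c("fmin", "fmax", "stride", "induced"),
  sync = c("measure", "channels", "window", "n_channels_max"),
  stats = c("window", "min_duration"),
  classify = c("band_lo", "band_hi", "window_start", "window_end",
               "epoch_start", "folds", "reps", "perms", "stride"))

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  offending <- setdiff(names(config), pipeline_schema$top)
  for (sec in intersect(names(config), names(pipeline_schema)[-1])) {
    bad <- setdiff(names(config[[sec]]), pipeline_schema[[sec]])
    if (length(bad)) offending <- c(offending, paste0(sec, ".", bad))
  }
  if (length(offending))
    stop("unknown config key(s): ", paste(offending, collapse = ", "))
  if (is.null(config$seed))
    stop("config must declare a seed (seeds are mandatory)")
  if (is.null(config$out_dir)) stop("config must declare out_dir")
  config$paradigm <- config$paradigm %||% "rotation"
  config$stages <- config$stages %||%
    c("simulate", "preprocess", "tfr", "stats", "classify")
  config
}

#' Default pipeline configuration
#'
#' A desk-scale rotation-paradigm demo configuration: small montage,
#' moderate trial count, all stages enabled. Override any entry before
#' passing it to [run_pipeline()].
#'
#' @param out_dir output directory.
#' @param seed RNG seed (mandatory for every stage).
#' @return a nested configuration list.
#' @export
default_pipeline_config <- function(out_dir, seed = 1) {
  list(
    seed = seed, out_dir = out_dir, paradigm = "rotation",
    stages = c("simulate", "preprocess", "tfr", "stats", "classify"),
    simulate = list(n_channels = 16, sr = 500, n_trials = 90,
                    perceived_prob = 2 / 3, exact_counts = TRUE),
    preprocess = list(highpass = 1, lowpass = 100, eeg_reject = 100,
                      eog_reject = 100, tmin = -1.5, tmax = 0.5,
                      ocular_correction = "regression",
                      response_window = c(1, 11)),
    tfr = list(fmin = 15, fmax = 90, stride = 10),
    stats = list(window = c(-1, 0)),
    classify = list(band_lo = 60, band_hi = 75, window_start = 9,
                    window_end = 12, epoch_start = 8.6, folds = 3,
                    reps = 30, perms = 0, stride = 20))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order -- simulate, preprocess (average
#' reference, zero-phase FIR band-pass, epoching, amplitude rejection,
#' optional EOG regression, behavioural trial selection), time-frequency
#' decomposition with baseline normalization, synchrony maps, band-wise
#' statistics, and perception/no-perception decoding -- writing each stage's
#' outputs plus a JSON run manifest (config snapshot, per-stage counts,
#' output hashes) into `out_dir`. Re-running the same configuration
#' reproduces byte-identical stage outputs.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file with the same structure.
#' @return the manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, started = format(Sys.time()),
                   stages = list())
  paths <- character(0)
  counts <- function(...) list(...)
  state <- new.env(parent = emptyenv())

  for (stage in config$stages) {
    res <- switch(stage,
      simulate = stage_simulate(config, out_dir, state),
      preprocess = stage_preprocess(config, out_dir, state),
      tfr = stage_tfr(config, out_dir, state),
      sync = stage_sync(config, out_dir, state),
      stats = stage_stats(config, out_dir, state),
      classify = stage_classify(config, out_dir, state),
      stop("unknown stage: ", stage))
    paths <- c(paths, res$paths)
    manifest$stages[[stage]] <- res$info
  }
  manifest$outputs <- as.list(tools::md5sum(paths))
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}

stage_simulate <- function(config, out_dir, state) {
  sim <- config$simulate %||% list()
  cfg <- do.call(synth_config, c(list(paradigm = config$paradigm,
                                      seed = config$seed), sim))
  ds <- if (config$paradigm == "rotation") generate_rotation_dataset(cfg)
        else generate_rsvp_dataset(cfg)
  state$dataset <- ds
  state$synth_config <- cfg
  p <- c(rec = file.path(out_dir, "recording.gsc"),
         ev = file.path(out_dir, "events.csv"),
         beh = file.path(out_dir, "behaviour.csv"),
         truth = file.path(out_dir, "ground_truth.json"))
  write_container(ds$recording, p["rec"])
  write_events(ds$events, p["ev"])
  write_behaviour(ds$behaviour, p["beh"])
  jsonlite::write_json(
    list(blink_times = ds$truth$blink_times,
         bursts = ds$truth$bursts,
         kappa = vapply(cfg$bursts, function(b) b$kappa %||% Inf, 0)),
    p["truth"], auto_unbox = TRUE, digits = NA, null = "null")
  list(paths = unname(p),
       info = list(n_trials = cfg$n_trials,
                   n_channels = cfg$n_channels, sr = cfg$sr))
}

stage_preprocess <- function(config, out_dir, state) {
  if (is.null(state$dataset)) stop("preprocess stage needs simulate outputs")
  pp <- config$preprocess %||% list()
  rec <- state$dataset$recording
  rec <- rereference_average(rec)
  rec <- bandpass(rec, pp$highpass %||% 1, pp$lowpass %||% 100)
  state$filtered <- rec
  if (config$paradigm == "rotation") {
    ep <- epoch(rec, c("response", "midpoint"),
                pp$tmin %||% -1.5, pp$tmax %||% 0.5,
                label_map = c(response = "perceived",
                              midpoint = "unperceived"))
  } else {
    ep <- epoch(rec, c("target_face", "target_guitar"),
                pp$tmin %||% -0.2, pp$tmax %||% 0.8,
                label_map = c(target_face = "target",
                              target_guitar = "target"))
  }
  rej <- reject_amplitude(ep, pp$eeg_reject %||% 100, pp$eog_reject %||% 100)
  ep <- rej$epochs
  if (identical(pp$ocular_correction %||% "regression", "regression"))
    ep <- correct_ocular_regression(ep)
  sel_counts <- NULL
  if (config$paradigm == "rotation" && !is.null(pp$response_window %||% c(1, 11))) {
    # keep unperceived trials, screen perceived ones by response latency
    beh <- state$dataset$behaviour
    rw <- pp$response_window %||% c(1, 11)
    lab <- ep$labels
    rt <- beh$response_time[match(ep$trial_id, beh$trial_id)]
    keep <- lab != "perceived" |
      (!is.na(rt) & rt >= rw[1] & rt <= rw[2])
    sel_counts <- sum(!keep)
    ep <- subset_trials(ep, keep)
  }
  state$epochs <- ep
  path <- file.path(out_dir, "epochs.gsc")
  write_container(ep, path)
  list(paths = path,
       info = list(n_rejected = nrow(rej$log),
                   n_selected_out = sel_counts,
                   n_epochs = dim(ep$data)[1],
                   provenance = provenance(ep)))
}

stage_tfr <- function(config, out_dir, state) {
  if (is.null(state$epochs)) stop("tfr stage needs preprocess outputs")
  tf <- config$tfr %||% list()
  eeg <- which(state$epochs$channel_kind == "EEG")
  ep <- state$epochs
  ep$data <- ep$data[, eeg, , drop = FALSE]
  ep$channel_labels <- ep$channel_labels[eeg]
  ep$channel_kind <- ep$channel_kind[eeg]
  keep <- if ("sync" %in% config$stages) c("power", "coeffs") else "power"
  tfr <- tfr_decompose(ep, freqs = seq(tf$fmin %||% 15, tf$fmax %||% 90),
                       stride = tf$stride %||% 10, keep = keep,
                       induced = isTRUE(tf$induced))
  tfr <- if (config$paradigm == "rotation")
    baseline_normalize(tfr, reference_label = "unperceived")
  else baseline_normalize(tfr, baseline_window = c(tfr$times[1], 0))
  state$tfr <- tfr
  path <- file.path(out_dir, "tfr.gsc")
  write_container(tfr, path)
  list(paths = path,
       info = list(clip_fraction = tfr$clip_fraction,
                   n_freqs = length(tfr$freqs), n_times = length(tfr$times)))
}

stage_sync <- function(config, out_dir, state) {
  if (is.null(state$tfr)) stop("sync stage needs tfr outputs")
  sy <- config$sync %||% list()
  channels <- sy$channels %||% {
    eeg <- state$tfr$channel_labels[state$tfr$channel_kind == "EEG"]
    utils::head(eeg, sy$n_channels_max %||% 12)
  }
  maps <- list()
  for (m in (sy$measure %||% c("plv", "imcoh")))
    maps[[m]] <- plv_all_pairs(state$tfr, measure = m, channels = channels)
  state$sync <- maps
  paths <- character(0)
  for (m in names(maps)) {
    cs <- connectivity_summary(maps[[m]],
                               time_window = sy$window %||% c(-1, 0))
    p <- file.path(out_dir, paste0("connectivity_", m, ".csv"))
    utils::write.csv(as.data.frame(cs), p, row.names = FALSE)
    pm <- export_connectivity_matrices(attr(cs, "matrices"), out_dir, m)
    paths <- c(paths, p, pm)
  }
  list(paths = paths, info = list(n_pairs = nrow(maps[[1]]$pairs)))
}

stage_stats <- function(config, out_dir, state) {
  if (is.null(state$tfr)) stop("stats stage needs tfr outputs")
  st <- config$stats %||% list()
  ba <- band_average(state$tfr)
  ser <- dplyr::rename(ba, unit = "trial_id", value = "power")
  win <- st$window %||% c(-1, 0)
  grp <- split(ser, ser$label)
  if (length(grp) < 2) stop("stats stage needs two conditions")
  a <- grp[[setdiff(names(grp), "perceived")[1]]]
  b <- grp[["perceived"]] %||% grp[[2]]
  con <- wilcoxon_map(dplyr::filter(a, .data$time >= win[1],
                                    .data$time <= win[2]),
                      dplyr::filter(b, .data$time >= win[1],
                                    .data$time <= win[2]),
                      paired = FALSE,
                      min_duration = st$min_duration %||% 0)
  state$contrast <- con
  p1 <- file.path(out_dir, "contrast_map.csv")
  p2 <- file.path(out_dir, "contrast_windows.csv")
  utils::write.csv(as.data.frame(tidy(con)), p1, row.names = FALSE)
  utils::write.csv(as.data.frame(con$windows), p2, row.names = FALSE)
  list(paths = c(p1, p2),
       info = list(n_significant = sum(tidy(con)$sig)))
}

stage_classify <- function(config, out_dir, state) {
  if (is.null(state$filtered)) stop("classify stage needs preprocess outputs")
  cl <- config$classify %||% list()
  beh <- state$dataset$behaviour
  ep <- epoch(state$filtered, "movie_onset",
              cl$epoch_start %||% 8.6, cl$window_end %||% 12,
              label_map = NULL)
  ep$labels <- ifelse(beh$perceived[match(ep$trial_id, beh$trial_id)],
                      "perceived", "unperceived")
  eeg <- which(ep$channel_kind == "EEG")
  ep$data <- ep$data[, eeg, , drop = FALSE]
  ep$channel_labels <- ep$channel_labels[eeg]
  ep$channel_kind <- ep$channel_kind[eeg]
  band <- c(cl$band_lo %||% 60, cl$band_hi %||% 75)
  tfr <- tfr_decompose(ep, freqs = seq(15, 90),
                       stride = cl$stride %||% 20, keep = "power")
  tfr <- baseline_normalize(tfr, reference_label = "unperceived")
  fm <- extract_features(tfr, band = band,
                         window = c(cl$window_start %||% 9,
                                    cl$window_end %||% 12),
                         behaviour = beh)
  rep_out <- train_eval_cv(fm, k_folds = cl$folds %||% 3,
                           repetitions = cl$reps %||% 30,
                           seed = config$seed)
  state$classifier <- rep_out
  perm <- NULL
  if ((cl$perms %||% 0) >= 100)
    perm <- permutation_test(fm, n_permutations = cl$perms,
                             seed = config$seed)
  g <- glance(rep_out)
  if (!is.null(perm)) g$permutation_p <- perm$p_value
  p1 <- file.path(out_dir, "classifier_report.csv")
  p2 <- file.path(out_dir, "classifier_repetitions.csv")
  utils::write.csv(as.data.frame(g), p1, row.names = FALSE)
  utils::write.csv(as.data.frame(tidy(rep_out)), p2, row.names = FALSE)
  list(paths = c(p1, p2),
       info = list(balanced_mean = g$balanced_mean,
                   n_excluded = nrow(fm$excluded),
                   n_trials = length(fm$y)))
}

#' Export figure-ready tabular data
#'
#' Writes plain tabular text that any plotting tool can consume: a
#' frequency x time matrix of condition-averaged normalized power
#' ([export_tfr_matrix()]), per-channel band values with montage
#' coordinates ([export_topography()]), and labelled connectivity matrices.
#' Re-importing an export reproduces the source array exactly.
#'
#' @param tfr a `gs_tfr` with power.
#' @param path output file.
#' @param label condition label to average (default: all trials).
#' @param channels channel subset to average over (default: all EEG).
#' @return the path, invisibly.
#' @export
export_tfr_matrix <- function(tfr, path, label = NULL, channels = NULL) {
  stopifnot(inherits(tfr, "gs_tfr"), !is.null(tfr$power))
  channels <- channels %||% tfr$channel_labels[tfr$channel_kind == "EEG"]
  ci <- match(channels, tfr$channel_labels)
  tsel <- if (is.null(label)) seq_along(tfr$labels) else
    which(tfr$labels == label)
  m <- apply(tfr$power[tsel, ci, , , drop = FALSE], c(3, 4), mean)
  dimnames(m) <- list(tfr$freqs, tfr$times)
  utils::write.table(m, path, sep = "\t", col.names = NA, quote = FALSE)
  invisible(path)
}

#' @rdname export_tfr_matrix
#' @param band `c(lo, hi)` Hz; power is averaged over the band and `window`.
#' @param window numeric length-2 (s).
#' @export
export_topography <- function(tfr, path, band, window, label = NULL) {
  stopifnot(inherits(tfr, "gs_tfr"), !is.null(tfr$power))
  fsel <- which(tfr$freqs >= band[1] & tfr$freqs < band[2])
  tsel <- which(tfr$times >= window[1] & tfr$times <= window[2])
  rsel <- if (is.null(label)) seq_along(tfr$labels) else
    which(tfr$labels == label)
  v <- apply(tfr$power[rsel, , fsel, tsel, drop = FALSE], 2, mean)
  pos <- montage_lookup(tfr$channel_labels)
  tb <- tibble::tibble(label = tfr$channel_labels, value = v)
  tb <- dplyr::left_join(tb, pos, by = "label")
  utils::write.table(as.data.frame(tb), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

export_connectivity_matrices <- function(matrices, out_dir, measure) {
  paths <- character(0)
  for (bn in names(matrices)) {
    p <- file.path(out_dir,
                   paste0("connectivity_", measure, "_",
                          gsub("[^0-9A-Za-z]", "_", bn), ".tsv"))
    utils::write.table(matrices[[bn]], p, sep = "\t", col.names = NA,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  paths
}

#' @rdname export_tfr_matrix
#' @param out_dir directory for the bundle written by [export_figure_data()].
#' @param connectivity optional `gs_connectivity` (from
#'   [connectivity_summary()]) whose per-band matrices are exported too.
#' @export
export_figure_data <- function(tfr, out_dir, band = c(60, 75),
                               window = NULL, label = NULL,
                               connectivity = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  window <- window %||% range(tfr$times)
  paths <- c(
    export_tfr_matrix(tfr, file.path(out_dir, "tfr_matrix.tsv"),
                      label = label),
    export_topography(tfr, file.path(out_dir, "topography.tsv"),
                      band = band, window = window, label = label))
  if (!is.null(connectivity))
    paths <- c(paths, export_connectivity_matrices(
      attr(connectivity, "matrices"), out_dir, "imcoh"))
  invisible(paths)
}
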