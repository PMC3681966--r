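#' Configuration for the synthetic EEG generator
#'
#' Bundles every knob of the simulator with defaults that mirror the two
#' experimental paradigms: rapid serial visual presentation (150 ms frames,
#' 4.5 s trials, exactly one target per trial at a frame onset drawn
#' uniformly in 1.5-3.0 s, i.e. target probability 1/30) and rotating
#' two-tone stimuli (12 s movies, 180 degrees of rotation over the first
#' 9 s, 3 s inter-stimulus interval, detection latencies truncated-normal
#' with mean 4.30 s and SD 2.95 s on [1, 11] s).
#'
#' The default burst amplitude is calibrated so that, after pseudo
#' Wigner-Ville decomposition and baseline z-normalization against
#' unperceived trials, the sustained 60-75 Hz component of perceived trials
#' sits at roughly +3 baseline standard deviations in the final 3 s of the
#' movie.
#'
#' @param paradigm `"rotation"` or `"rsvp"`.
#' @param n_channels number of EEG channels (default 16; 2 EOG channels are
#'   always appended).
#' @param sr sampling rate, Hz. 500 by default to keep desk-scale runs fast;
#'   all analyses are rate-agnostic (use 2000 to match lab acquisition).
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param noise_rms background RMS per channel, microvolts.
#' @param bursts list of burst specs (see [inject_burst()]); `NULL` installs
#'   the paradigm default (gamma burst on occipito-parietal channels).
#' @param mixing optional square mixing matrix applied to the EEG+EOG data
#'   (volume conduction); `NULL` = identity.
#' @param blink_rate,blink_amplitude,blink_decay ocular artifact model
#'   passed to [add_ocular_artifacts()].
#' @param n_trials trials to simulate.
#' @param perceived_prob probability a rotation trial reaches a percept.
#' @param exact_counts if `TRUE`, exactly `round(n_trials * perceived_prob)`
#'   trials are perceived (flags shuffled); otherwise Bernoulli draws.
#' @param hit_prob probability of a correct categorization (RSVP).
#' @param response_mean,response_sd,response_range truncated-normal
#'   detection-latency model (s).
#' @param burst_lead seconds by which the gamma component precedes the
#'   response in perceived rotation trials.
#' @param seed mandatory RNG seed.
#' @return a list of class `gs_synth_config`.
#' @export
synth_config <- function(paradigm = c("rotation", "rsvp"),
                         n_channels = 16, sr = 500,
                         noise_exponent = 1.2, noise_rms = 10,
                         bursts = NULL, mixing = NULL,
                         blink_rate = 0.01, blink_amplitude = 150,
                         blink_decay = 0.05,
                         n_trials = if (match.arg(paradigm) == "rotation") 90 else 30,
                         perceived_prob = 2 / 3, exact_counts = FALSE,
                         hit_prob = 0.9187,
                         response_mean = 4.30, response_sd = 2.95,
                         response_range = c(1, 11),
                         burst_lead = 0.8,
                         seed = 1) {
  paradigm <- match.arg(paradigm)
  stopifnot(noise_exponent >= 0, noise_rms >= 0,
            perceived_prob >= 0, perceived_prob <= 1,
            hit_prob >= 0, hit_prob <= 1,
            sr > 0, n_trials >= 1, !is.null(seed))
  labels <- default_labels(n_channels, n_eog = 2)
  burst_channels <- intersect(
    c("PO3", "POZ", "PO4", "O1", "OZ", "O2"), labels)
  if (is.null(bursts)) {
    bursts <- if (paradigm == "rotation") {
      list(list(channels = burst_channels, freq = 68,
                duration = 0.4, amplitude = 1.3, kappa = 5, lags = 0))
    } else {
      list(list(channels = burst_channels, freq = 40, onset = 0.25,
                duration = 0.4, amplitude = 2.5, kappa = 5, lags = 0))
    }
  }
  cfg <- list(
    paradigm = paradigm, n_channels = n_channels, sr = sr,
    noise_exponent = noise_exponent, noise_rms = noise_rms,
    bursts = bursts, mixing = mixing,
    blink_rate = blink_rate, blink_amplitude = blink_amplitude,
    blink_decay = blink_decay,
    n_trials = n_trials, perceived_prob = perceived_prob,
    exact_counts = exact_counts, hit_prob = hit_prob,
    response_mean = response_mean, response_sd = response_sd,
    response_range = response_range, burst_lead = burst_lead,
    # paradigm constants
    frame_s = 0.150, trial_s = 4.5, target_window = c(1.5, 3.0),
    rsvp_isi_s = 2, movie_s = 12, rotation_span_s = 9, isi_s = 3,
    fixation_s = 10,
    channel_labels = labels,
    channel_kind = c(rep("EEG", n_channels), rep("EOG", 2)),
    seed = as.integer(seed))
  class(cfg) <- "gs_synth_config"
  cfg
}

#' Simulate a rapid-serial-visual-presentation dataset
#'
#' Continuous EEG for `n_trials` trials of 4.5 s (30 frames of 150 ms each,
#' 2 s inter-trial gap). Each trial has exactly one target frame
#' (alternately face/guitar) whose onset is drawn uniformly from the frame
#' grid restricted to 1.5-3.0 s; the other 29 frames are `frequent` events.
#' Target trials receive the configured evoked burst(s) locked to target
#' onset. The behaviour log marks correct categorizations with probability
#' `hit_prob`.
#'
#' @param cfg a [synth_config()] with `paradigm = "rsvp"`.
#' @return list: `recording` (with events attached), `events`, `behaviour`,
#'   `truth` (per-trial burst ground truth and blink times).
#' @export
generate_rsvp_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "gs_synth_config"), cfg$paradigm == "rsvp")
  with_seed(cfg$seed, {
    lead_in <- 2
    step <- cfg$trial_s + cfg$rsvp_isi_s
    onsets <- lead_in + (seq_len(cfg$n_trials) - 1) * step
    duration <- lead_in + cfg$n_trials * step + 2
    rec <- generate_background(
      cfg$n_channels + 2, duration, cfg$sr, cfg$noise_exponent,
      cfg$noise_rms, channel_labels = cfg$channel_labels,
      channel_kind = cfg$channel_kind)

    frame_onsets <- seq(0, by = cfg$frame_s,
                        length.out = round(cfg$trial_s / cfg$frame_s))
    eligible <- which(frame_onsets >= cfg$target_window[1] &
                        frame_onsets <= cfg$target_window[2])
    ev <- list()
    target_onset <- numeric(cfg$n_trials)
    for (k in seq_len(cfg$n_trials)) {
      tf <- sample(eligible, 1)
      target_onset[k] <- onsets[k] + frame_onsets[tf]
      code <- rep("frequent", length(frame_onsets))
      code[tf] <- if (k %% 2 == 1) "target_face" else "target_guitar"
      ev[[k]] <- tibble::tibble(
        sample_index = round((onsets[k] + frame_onsets) * cfg$sr),
        code = code, trial_id = k)
      ev[[k]] <- dplyr::bind_rows(ev[[k]], tibble::tibble(
        sample_index = round((onsets[k] + cfg$trial_s) * cfg$sr),
        code = "trial_end", trial_id = k))
    }
    events <- validate_events(dplyr::bind_rows(ev), ncol(rec$data))

    truth <- list()
    for (b in cfg$bursts) {
      inj <- inject_burst(rec, target_onset, b)
      rec <- inj$recording
      truth[[length(truth) + 1]] <- inj$truth
    }
    if (!is.null(cfg$mixing)) rec <- apply_mixing(rec, cfg$mixing)
    oc <- add_ocular_artifacts(rec, cfg$blink_rate, cfg$blink_amplitude,
                               cfg$blink_decay)
    rec <- oc$recording
    rec$events <- events

    behaviour <- behaviour_log(
      trial_id = seq_len(cfg$n_trials),
      response_time = NA_real_,
      perceived = TRUE,
      correct = runif(cfg$n_trials) < cfg$hit_prob)
    list(recording = rec, events = events, behaviour = behaviour,
         truth = list(bursts = dplyr::bind_rows(truth),
                      blink_times = oc$blink_times,
                      target_onset = target_onset))
  })
}

#' Simulate a rotating-stimulus (dynamic two-tone) dataset
#'
#' Movies of 12 s separated by 3 s of black screen after a 10 s fixation
#' lead-in. Each trial is perceived with probability `perceived_prob`;
#' perceived trials get a `response` event at a truncated-normal latency in
#' [1, 11] s and a narrow-band gamma component that ramps up `burst_lead`
#' seconds before the response and is sustained until movie offset
#' (perception-state activity). Unperceived trials get no burst and carry a
#' `midpoint` lock event at 6 s for epoching. The behaviour log is
#' consistent with the events by construction.
#'
#' @param cfg a [synth_config()] with `paradigm = "rotation"`.
#' @return list: `recording`, `events`, `behaviour`, `truth`.
#' @export
generate_rotation_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "gs_synth_config"), cfg$paradigm == "rotation")
  with_seed(cfg$seed, {
    step <- cfg$movie_s + cfg$isi_s
    onsets <- cfg$fixation_s + (seq_len(cfg$n_trials) - 1) * step
    duration <- cfg$fixation_s + cfg$n_trials * step + 2
    rec <- generate_background(
      cfg$n_channels + 2, duration, cfg$sr, cfg$noise_exponent,
      cfg$noise_rms, channel_labels = cfg$channel_labels,
      channel_kind = cfg$channel_kind)

    if (cfg$exact_counts) {
      n_perc <- round(cfg$n_trials * cfg$perceived_prob)
      perceived <- sample(rep(c(TRUE, FALSE),
                              c(n_perc, cfg$n_trials - n_perc)))
    } else {
      perceived <- runif(cfg$n_trials) < cfg$perceived_prob
    }
    latency <- rep(NA_real_, cfg$n_trials)
    latency[perceived] <- rtruncnorm(sum(perceived), cfg$response_mean,
                                     cfg$response_sd,
                                     cfg$response_range[1],
                                     cfg$response_range[2])

    ev <- list()
    for (k in seq_len(cfg$n_trials)) {
      rows <- tibble::tibble(
        sample_index = round(onsets[k] * cfg$sr),
        code = "movie_onset", trial_id = k)
      if (perceived[k]) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          sample_index = round((onsets[k] + latency[k]) * cfg$sr),
          code = "response", trial_id = k))
      } else {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          sample_index = round((onsets[k] + cfg$movie_s / 2) * cfg$sr),
          code = "midpoint", trial_id = k))
      }
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        sample_index = round((onsets[k] + cfg$movie_s) * cfg$sr),
        code = "trial_end", trial_id = k))
      ev[[k]] <- rows
    }
    events <- validate_events(dplyr::bind_rows(ev), ncol(rec$data))

    # sustained perception-state gamma: Hann ramp starting burst_lead before
    # the response, plateau to movie offset, half-Hann release at the end
    truth <- list()
    for (b in cfg$bursts) {
      for (k in which(perceived)) {
        start_rel <- max(latency[k] - cfg$burst_lead, 0.05)
        spec <- b
        spec$onset <- start_rel
        spec$sustain_s <- cfg$movie_s - start_rel - b$duration
        inj <- inject_burst(rec, onsets[k], spec)
        rec <- inj$recording
        tr <- inj$truth
        tr$trial <- k
        truth[[length(truth) + 1]] <- tr
      }
    }
    if (!is.null(cfg$mixing)) rec <- apply_mixing(rec, cfg$mixing)
    oc <- add_ocular_artifacts(rec, cfg$blink_rate, cfg$blink_amplitude,
                               cfg$blink_decay)
    rec <- oc$recording
    rec$events <- events

    behaviour <- behaviour_log(
      trial_id = seq_len(cfg$n_trials),
      response_time = latency,
      perceived = perceived,
      correct = perceived,
      trial_duration = cfg$movie_s)
    list(recording = rec, events = events, behaviour = behaviour,
         truth = list(bursts = dplyr::bind_rows(truth),
                      blink_times = oc$blink_times,
                      perceived = perceived, latency = latency))
  })
}
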