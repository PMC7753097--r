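#' Configuration of a synthetic study cohort
#'
#' Defines the population the generators draw from: three gaming groups
#' (non-video gamers, non-action video gamers, action video gamers) of
#' sizes 14/15/9, each subject with per-block TVA parameters and a
#' per-block, per-duration alpha attenuation `d` on the log10-ratio
#' scale. The defaults encode the structure the analysis expects: a
#' group-by-block crossover in processing speed C (NVGs fastest in block
#' 1, gamers overtaking in block 2 with AVGs showing the largest
#' increase), a matching block-2 gain in alpha attenuation, an
#' inverted-U modulation of `d` across exposure durations peaking at
#' 144.6 ms, a positive subject-level coupling between C and alpha
#' attenuation, and a strongly positive AVG-specific coupling between the
#' block-2 minus block-1 changes in both quantities.
#'
#' @param group_sizes named integer vector, subjects per group.
#' @param C_mean 3x2 matrix (group x block) of mean processing speeds
#'   (items/s).
#' @param C_between_sd between-subject SD of the subject's average C.
#' @param C_block_sd within-subject block-level SD of C.
#' @param K_mean,K_sd mean and SD of short-term memory capacity (items).
#' @param t0 perceptual threshold (ms), shared across subjects.
#' @param d_base 3x2 matrix (group x block) of mean alpha attenuation on
#'   the log10 scale.
#' @param d_between_sd between-subject SD of the attenuation level.
#' @param d_block_sd within-subject block-level SD of the attenuation.
#' @param d_duration_profile multiplier applied to `d` per exposure
#'   duration (length 6, inverted-U peaking at the fifth duration,
#'   144.6 ms).
#' @param alpha_coupling correlation between a subject's C level and
#'   their alpha-attenuation level (0..1).
#' @param diff_slope named vector, per-group slope linking a subject's
#'   block-2 minus block-1 attenuation change to their C change
#'   (items/s per log10 unit).
#' @param eeg list of EEG signal parameters: `alpha_freq` (Hz),
#'   `alpha_amp` (microvolt amplitude of the pre-window posterior alpha),
#'   `noise_sd` (microvolt SD of the 1/f-like background), `noise_ar`
#'   (AR(1) coefficient of the background), `sfreq` (Hz), `pad` (samples
#'   of context around each trial epoch).
#' @param timing_offsets named vector of modal display-duration
#'   deviations (ms) per nominal duration; the defaults reproduce the
#'   corrected durations 17.8, 35.6, 53.4, 89, 144.6 and 198 ms.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(
    group_sizes = c(NVG = 14, NAVG = 15, AVG = 9),
    C_mean = rbind(NVG = c(44, 42), NAVG = c(39, 45), AVG = c(38, 52)),
    C_between_sd = 7,
    C_block_sd = 2.5,
    K_mean = 3.3, K_sd = 0.5,
    t0 = 15,
    d_base = rbind(NVG = c(0.04, 0.05), NAVG = c(0.04, 0.08), AVG = c(0.04, 0.13)),
    d_between_sd = 0.03,
    d_block_sd = 0.02,
    d_duration_profile = c(0.5, 0.7, 0.85, 1.0, 1.15, 0.9),
    alpha_coupling = 0.55,
    diff_slope = c(NVG = 0, NAVG = 0, AVG = 150),
    eeg = list(alpha_freq = 11, alpha_amp = 20, noise_sd = 4,
               noise_ar = 0.95, sfreq = 1024, pad = 128),
    timing_offsets = c(`16.7` = 1.1, `33.4` = 2.2, `50.1` = 3.3,
                       `83.5` = 5.5, `150.3` = -5.7, `200.4` = -2.4)) {
  stopifnot(all(group_sizes >= 2), C_between_sd >= 0, C_block_sd >= 0,
            K_sd >= 0, d_between_sd >= 0, d_block_sd >= 0,
            all(is.finite(d_base)), length(d_duration_profile) == 6,
            alpha_coupling >= 0, alpha_coupling <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws per-subject true parameters and group-consistent questionnaires.
#' The subject's C level and alpha-attenuation level share a latent
#' factor with correlation `alpha_coupling`; the block-2 C gain of each
#' subject additionally tracks their idiosyncratic block-2 attenuation
#' gain with the group's `diff_slope`. Questionnaire hours are drawn
#' inside the classification region of the subject's group, so
#' [classify_gamer()] reproduces the generating labels exactly.
#'
#' @param config a [cohort_config()].
#' @param seed master seed.
#' @return object of class `synthetic_cohort`: `subjects` (data frame
#'   with group, per-block C, K, t0), `d` (subject x block x duration
#'   array of true attenuations), `questionnaires` (long table), and the
#'   config.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  groups <- names(config$group_sizes)
  n <- sum(config$group_sizes)
  group <- factor(rep(groups, config$group_sizes), levels = groups)
  with_local_seed(seed, {
    z_c <- stats::rnorm(n)          # latent C factor
    z_eps <- stats::rnorm(n)        # independent part of the alpha level
    rho <- config$alpha_coupling
    z_d <- rho * z_c + sqrt(1 - rho^2) * z_eps

    C_avg <- rowMeans(config$C_mean)[group] + config$C_between_sd * z_c
    d_level <- config$d_between_sd * z_d

    # block-level attenuation: group base + subject level + block noise
    d_block <- matrix(0, n, 2)
    for (b in 1:2) {
      d_block[, b] <- config$d_base[cbind(as.integer(group), b)] + d_level +
        stats::rnorm(n, 0, config$d_block_sd)
    }

    # block-level C: group trajectory + subject level + noise, plus the
    # group-specific coupling to the idiosyncratic attenuation change
    delta_g <- config$C_mean[, 2] - config$C_mean[, 1]
    d_change <- d_block[, 2] - d_block[, 1]
    d_change_expected <- (config$d_base[, 2] - config$d_base[, 1])[as.integer(group)]
    slope <- config$diff_slope[as.character(group)]
    C1 <- C_avg - delta_g[as.integer(group)] / 2 +
      stats::rnorm(n, 0, config$C_block_sd)
    C2 <- C_avg + delta_g[as.integer(group)] / 2 +
      stats::rnorm(n, 0, config$C_block_sd) +
      slope * (d_change - d_change_expected)
    C1 <- pmax(C1, 5); C2 <- pmax(C2, 5)

    K <- pmin(pmax(stats::rnorm(n, config$K_mean, config$K_sd), 1), 6)

    d <- array(0, c(n, 2, 6),
               dimnames = list(NULL, c("block1", "block2"), NULL))
    for (b in 1:2) d[, b, ] <- outer(d_block[, b], config$d_duration_profile)

    subjects <- data.frame(
      subject = sprintf("S%02d", seq_len(n)), group = as.character(group),
      C_block1 = C1, C_block2 = C2, K = K, t0 = config$t0,
      stringsAsFactors = FALSE)

    questionnaires <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(subject = subjects$subject[i],
                 genre = gaming_genres(),
                 hours_per_week = draw_profile(as.character(group[i])),
                 stringsAsFactors = FALSE)
    }))

    structure(list(subjects = subjects, d = d,
                   questionnaires = questionnaires, config = config,
                   seed = as.integer(as.numeric(seed) %% 2147483647)),
              class = "synthetic_cohort")
  })
}

# hours/week inside the classification region of `group`
draw_profile <- function(group) {
  h <- stats::setNames(numeric(8), gaming_genres())
  if (group == "AVG") {
    h["fps_tps"] <- 5 + stats::rexp(1, 1 / 4)
    h["action_rpg_adventure"] <- stats::runif(1, 0, 4)
    h["sports_driving"] <- stats::runif(1, 0, 2)
  } else if (group == "NAVG") {
    # breaks an NVG cap while staying below the 5 h action threshold
    h["sports_driving"] <- stats::runif(1, 1.5, 6)
    h["fps_tps"] <- stats::runif(1, 0, 2)
    h["action_rpg_adventure"] <- stats::runif(1, 0, 2)
    h["music"] <- stats::runif(1, 0, 3)
  } else {
    h["turnbased_rpg_fantasy"] <- stats::runif(1, 0, 2)
    h["music"] <- stats::runif(1, 0, 2)
    h["sports_driving"] <- stats::runif(1, 0, 1)
  }
  round(h, 1)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), seed %d\n",
              nrow(x$subjects),
              paste(table(factor(x$subjects$group,
                                 levels = names(x$config$group_sizes))),
                    collapse = "/"),
              x$seed))
  invisible(x)
}

#' Simulate whole-report behaviour for a cohort
#'
#' Delegates to [simulate_trials()] with each subject's per-block true
#' parameters: 420 experimental trials per subject (two blocks of 210)
#' under the supplied schedule.
#'
#' @param cohort a [generate_cohort()] result.
#' @param schedule schedule with corrected durations filled in.
#' @param seed master seed (per-subject streams derived from it).
#' @return data frame of trials with a `subject` column.
#' @export
generate_behavior <- function(cohort, schedule, seed = 1) {
  subs <- cohort$subjects
  out <- vector("list", nrow(subs))
  for (i in seq_len(nrow(subs))) {
    rows <- list()
    for (b in 1:2) {
      bl <- paste0("block", b)
      prm <- tva_params(C = subs[[paste0("C_", bl)]][i], K = subs$K[i],
                        t0 = subs$t0[i])
      tr <- simulate_trials(prm, schedule[schedule$block == bl, , drop = FALSE],
                            seed = as.numeric(seed) * 1000 + i * 10 + b)
      rows[[b]] <- tr
    }
    tr <- do.call(rbind, rows)
    tr$subject <- subs$subject[i]
    out[[i]] <- tr
  }
  do.call(rbind, out)
}

#' Synthesise a 62-channel EEG recording for one subject
#'
#' Builds a compact continuous recording from the experimental trials of
#' a schedule: each trial contributes an epoch of `pad` context samples,
#' a 500 ms pre-stimulus window, the exposure gap, a 500 ms post-mask
#' window and trailing context. Posterior-ROI channels carry an ongoing
#' alpha oscillation (centre frequency `alpha_freq`, random phase per
#' trial) whose amplitude ramps from the pre-window value `A` to
#' `A * 10^(-d/2)` across the exposure gap, so the pre/post band power
#' log10-ratio equals the trial's programmed attenuation `d`. All
#' channels carry AR(1) background noise; non-ROI channels carry noise
#' only.
#'
#' @param cohort a [generate_cohort()] result.
#' @param schedule schedule with corrected durations.
#' @param subject subject identifier (row of `cohort$subjects`).
#' @param seed master seed.
#' @param trials_per_cell optionally subsample the schedule to this many
#'   trials per block-by-duration cell (`NULL` keeps all 35).
#' @return an [eeg_recording()] at the configured sampling rate.
#' @export
generate_eeg <- function(cohort, schedule, subject, seed = 1,
                         trials_per_cell = NULL) {
  cfg <- cohort$config$eeg
  si <- match(subject, cohort$subjects$subject)
  if (is.na(si)) stop_tvalpha("unknown subject", "tvalpha_unknown_subject")
  sched <- schedule[schedule$block %in% c("block1", "block2"), , drop = FALSE]
  dur <- sched$duration_ms
  if (anyNA(dur)) dur <- sched$duration_nominal_ms
  durs <- sort(unique(dur))
  if (!is.null(trials_per_cell)) {
    keep <- unlist(lapply(split(seq_len(nrow(sched)),
                                list(sched$block, dur)), function(ix) {
      ix[seq_len(min(trials_per_cell, length(ix)))]
    }), use.names = FALSE)
    sched <- sched[sort(keep), , drop = FALSE]
    dur <- dur[sort(keep)]
  }
  fs <- cfg$sfreq
  nw <- round(0.5 * fs)
  pad <- cfg$pad
  gap <- round(dur / 1000 * fs)
  ep_len <- pad + nw + gap + nw + pad
  starts <- cumsum(c(1, ep_len[-length(ep_len)]))
  total <- sum(ep_len)
  ch <- montage_1010()
  nch <- length(ch)
  roi_idx <- which(ch %in% posterior_roi())

  with_local_seed(as.numeric(seed) * 1000 + si, {
    # AR(1) background on every channel
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$noise_ar^2)
    data <- matrix(stats::rnorm(total * nch, sd = innov_sd), total, nch)
    if (cfg$noise_sd > 0) {
      # strip the ts class stats::filter attaches: ts-dispatched
      # subassignment on a matrix this size is prohibitively slow
      data <- stats::filter(data, cfg$noise_ar, method = "recursive")
      data <- matrix(as.numeric(data), total, nch)
    } else {
      data[] <- 0
    }
    amp_jitter <- stats::runif(length(roi_idx), 0.8, 1.2)
    block_idx <- ifelse(sched$block == "block1", 1L, 2L)
    dur_idx <- match(dur, durs)
    phase <- stats::runif(nrow(sched), 0, 2 * pi)
    omega <- 2 * pi * cfg$alpha_freq / fs
    # single full-length waveform, then one matrix update (a per-trial
    # matrix subassignment would copy the whole recording each time)
    wave <- numeric(total)
    stim_at <- pad + nw            # samples before stimulus onset
    for (i in seq_len(nrow(sched))) {
      d_i <- cohort$d[si, block_idx[i], dur_idx[i]]
      n_i <- ep_len[i]
      att <- 10^(-d_i / 2)
      env <- c(rep(1, stim_at),
               seq(1, att, length.out = max(gap[i], 1)),
               rep(att, n_i - stim_at - gap[i]))[seq_len(n_i)]
      t_idx <- seq_len(n_i) - 1
      wave[starts[i]:(starts[i] + n_i - 1)] <-
        cfg$alpha_amp * env * sin(omega * t_idx + phase[i])
    }
    data[, roi_idx] <- data[, roi_idx] + outer(wave, amp_jitter)
    stim_sample <- starts + pad + nw
    mask_sample <- stim_sample + gap
    events <- data.frame(
      sample = c(stim_sample, mask_sample, mask_sample + round(0.501 * fs)),
      type = rep(c("stimulus", "mask_on", "mask_off"), each = nrow(sched)),
      trial = rep(sched$trial_index, 3),
      block = rep(sched$block, 3),
      duration_ms = rep(dur, 3),
      stringsAsFactors = FALSE)
    events <- events[events$sample <= total, ]
    eeg_recording(data, fs, ch, events)
  })
}

#' Generate a display-timing deviation log
#'
#' Draws measured display-duration deviations per nominal duration whose
#' 0.1 ms-binned mode equals the configured offset, so that
#' [correct_durations()] reproduces the intended corrected durations.
#'
#' @param config a [cohort_config()] (uses its `timing_offsets`).
#' @param seed integer seed.
#' @param n_per_duration deviations per nominal duration.
#' @return named list of deviation vectors (a `TimingLog`).
#' @export
generate_timing_log <- function(config = cohort_config(), seed = 1,
                                n_per_duration = 60) {
  offsets <- config$timing_offsets
  with_local_seed(seed, {
    out <- lapply(offsets, function(off) {
      n_exact <- ceiling(0.4 * n_per_duration)
      dev <- c(off + stats::runif(n_exact, -0.04, 0.04),
               off + stats::rnorm(n_per_duration - n_exact, 0, 0.4))
      # ensure the binned mode is the configured offset
      while (binned_mode(dev) != round(off, 1)) {
        dev <- c(dev, off)
      }
      sample(dev)
    })
    names(out) <- names(offsets)
    out
  })
}

#' Alpha ratios for every subject of a synthetic cohort
#'
#' Convenience wrapper running [generate_eeg()], [preprocess_eeg()],
#' [segment_trials()] and [alpha_ratio_table()] per subject.
#'
#' @inheritParams generate_eeg
#' @param preprocess apply [preprocess_eeg()] (band-pass, notch, common
#'   average) before segmentation.
#' @param verbose print one line per subject.
#' @return data frame: `subject`, `block`, `duration_ms`, `band`,
#'   `log_ratio`, `n_trials`.
#' @export
generate_alpha_ratios <- function(cohort, schedule, seed = 1,
                                  trials_per_cell = NULL, preprocess = TRUE,
                                  verbose = FALSE) {
  out <- vector("list", nrow(cohort$subjects))
  for (i in seq_len(nrow(cohort$subjects))) {
    s <- cohort$subjects$subject[i]
    rec <- generate_eeg(cohort, schedule, s, seed = seed,
                        trials_per_cell = trials_per_cell)
    if (preprocess) rec <- preprocess_eeg(rec)
    tab <- alpha_ratio_table(segment_trials(rec))
    tab$subject <- s
    out[[i]] <- tab
    if (verbose) message(sprintf("alpha ratios: %s done", s))
  }
  do.call(rbind, out)
}
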