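#' Configuration for a full pipeline run
#'
#' Bundles stage toggles, the cohort configuration, and the master seed.
#' Every stage derives its own random stream from the master seed, so a
#' rerun with the same configuration reproduces all outputs.
#'
#' @param seed master seed.
#' @param out_dir output directory (`NULL` for no files, results only
#'   returned).
#' @param cohort a [cohort_config()].
#' @param stages character subset of
#'   `c("simulate", "fit_tva", "alpha", "stats")`.
#' @param eeg_trials_per_cell optionally subsample EEG trials per
#'   block-by-duration cell (`NULL` = all 35).
#' @param cooks_threshold Cook's-distance exclusion threshold for the
#'   difference regression (`NULL` = the default `4/n`).
#' @param verbose print progress messages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL,
                            cohort = cohort_config(),
                            stages = c("simulate", "fit_tva", "alpha", "stats"),
                            eeg_trials_per_cell = NULL,
                            cooks_threshold = NULL,
                            verbose = FALSE) {
  stopifnot(all(stages %in% c("simulate", "fit_tva", "alpha", "stats")))
  structure(list(seed = as.integer(as.numeric(seed) %% 2147483647),
                 out_dir = out_dir, cohort = cohort,
                 stages = stages, eeg_trials_per_cell = eeg_trials_per_cell,
                 cooks_threshold = cooks_threshold, verbose = verbose),
            class = "pipeline_config")
}

#' Run the full analysis chain on a synthetic cohort
#'
#' Executes the enabled stages in order: `simulate` (schedule, timing
#' log, cohort, behaviour), `fit_tva` (per-subject per-block ML fits),
#' `alpha` (EEG synthesis and the spectral ratio chain), and `stats`
#' (the four one-tailed correlations with Bonferroni adjustment, the two
#' three-way and two two-way mixed ANOVAs, and the Cook's-screened
#' dummy-coded difference regression). When `out_dir` is set, writes the
#' result tables as delimited text/JSON plus a manifest recording the
#' seed and a hash of the configuration.
#'
#' @param config a [pipeline_config()].
#' @return list with elements `schedule`, `corrected_durations`,
#'   `cohort`, `behavior`, `fits`, `alpha`, `stats` (as enabled), and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  res <- list()
  stages <- config$stages

  if ("simulate" %in% stages) {
    say("stage simulate")
    tlog <- generate_timing_log(config$cohort, seed = config$seed)
    corrected <- correct_durations(tlog)
    schedule <- apply_timing_correction(build_schedule(config$seed), corrected)
    cohort <- generate_cohort(config$cohort, seed = config$seed)
    behavior <- generate_behavior(cohort, schedule, seed = config$seed)
    res$timing_log <- tlog
    res$corrected_durations <- corrected
    res$schedule <- schedule
    res$cohort <- cohort
    res$behavior <- behavior
  }

  if ("fit_tva" %in% stages) {
    if (is.null(res$behavior)) {
      stop_tvalpha("fit_tva stage requires the simulate stage",
                   "tvalpha_missing_input")
    }
    say("stage fit_tva")
    subs <- unique(res$behavior$subject)
    fits <- lapply(stats::setNames(subs, subs), function(s) {
      fit_tva(res$behavior[res$behavior$subject == s, ], per_block = TRUE)
    })
    res$fits <- data.frame(
      subject = subs,
      C_block1 = vapply(fits, function(f) f$per_block$block1$params$C, 0),
      C_block2 = vapply(fits, function(f) f$per_block$block2$params$C, 0),
      K_block1 = vapply(fits, function(f) f$per_block$block1$params$K, 0),
      K_block2 = vapply(fits, function(f) f$per_block$block2$params$K, 0),
      C_overall = vapply(fits, function(f) f$params$C, 0),
      K_overall = vapply(fits, function(f) f$params$K, 0),
      stringsAsFactors = FALSE)
  }

  if ("alpha" %in% stages) {
    if (is.null(res$cohort)) {
      stop_tvalpha("alpha stage requires the simulate stage",
                   "tvalpha_missing_input")
    }
    say("stage alpha")
    res$alpha <- generate_alpha_ratios(
      res$cohort, res$schedule, seed = config$seed,
      trials_per_cell = config$eeg_trials_per_cell,
      verbose = config$verbose)
  }

  if ("stats" %in% stages) {
    if (is.null(res$fits) || is.null(res$alpha)) {
      stop_tvalpha("stats stage requires fit_tva and alpha outputs",
                   "tvalpha_missing_input")
    }
    say("stage stats")
    res$cohort_table <- build_cohort_table(res$cohort, res$fits, res$alpha)
    res$stats <- run_stats(res$cohort_table, res$alpha,
                           cooks_threshold = config$cooks_threshold)
  }

  res$manifest <- list(seed = config$seed,
                       stages = stages,
                       config_hash = config_hash(config),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(config$out_dir)) write_outputs(res, config)
  invisible(res)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- config
  cfg$verbose <- NULL
  writeLines(paste(deparse(cfg), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

#' Merge fits, alpha ratios, and group labels into the analysis table
#'
#' @param cohort a [generate_cohort()] result (group labels).
#' @param fits per-subject fit table (from the `fit_tva` stage).
#' @param alpha long alpha-ratio table (from the `alpha` stage).
#' @return subject-level data frame with group, per-block C and K,
#'   per-block mean medium alpha ratio (`alpha_block1/2`), and average
#'   medium/upper ratios.
#' @export
build_cohort_table <- function(cohort, fits, alpha) {
  tab <- merge(cohort$subjects[, c("subject", "group")], fits, by = "subject")
  med <- alpha[alpha$band == "medium", ]
  blk <- stats::aggregate(log_ratio ~ subject + block, med, mean)
  wide <- stats::reshape(blk, idvar = "subject", timevar = "block",
                         direction = "wide")
  names(wide) <- sub("log_ratio.", "alpha_", names(wide))
  tab <- merge(tab, wide, by = "subject")
  for (b in c("medium", "upper")) {
    avg <- stats::aggregate(log_ratio ~ subject, alpha[alpha$band == b, ], mean)
    names(avg)[2] <- paste0("avg_", b)
    tab <- merge(tab, avg, by = "subject")
  }
  tab[order(tab$subject), ]
}

run_stats <- function(cohort_table, alpha, cooks_threshold = NULL) {
  ct <- cohort_table
  ct$C_avg <- (ct$C_block1 + ct$C_block2) / 2
  ct$K_avg <- (ct$K_block1 + ct$K_block2) / 2
  correlations <- list(
    C_medium = correlate_tva_alpha(ct$avg_medium, ct$C_avg),
    C_upper = correlate_tva_alpha(ct$avg_upper, ct$C_avg),
    K_medium = correlate_tva_alpha(ct$avg_medium, ct$K_avg),
    K_upper = correlate_tva_alpha(ct$avg_upper, ct$K_avg))

  long <- merge(alpha, ct[, c("subject", "group")], by = "subject")
  anova_alpha <- lapply(stats::setNames(c("medium", "upper"),
                                        c("medium", "upper")), function(b) {
    mixed_anova(long[long$band == b, ], dv = "log_ratio", subject = "subject",
                between = "group", within = c("block", "duration_ms"))
  })

  param_long <- function(prefix) {
    do.call(rbind, lapply(c("block1", "block2"), function(b) {
      data.frame(subject = ct$subject, group = ct$group, block = b,
                 value = ct[[paste0(prefix, "_", b)]],
                 stringsAsFactors = FALSE)
    }))
  }
  anova_params <- list(
    C = mixed_anova(param_long("C"), dv = "value", subject = "subject",
                    between = "group", within = "block"),
    K = mixed_anova(param_long("K"), dv = "value", subject = "subject",
                    between = "group", within = "block"))

  diff <- difference_values(ct)
  screen <- cooks_screen(diff, threshold = cooks_threshold %||% (4 / nrow(diff)))
  regression <- dummy_regression(screen$retained)

  list(correlations = correlations, anova_alpha = anova_alpha,
       anova_params = anova_params, difference = diff, screen = screen,
       regression = regression,
       assumptions = assumption_checks(diff$d_param, diff$group))
}

write_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  if (!is.null(res$schedule)) write_schedule(res$schedule, p("schedule.tsv"))
  if (!is.null(res$behavior)) write_trials(res$behavior, p("trials.tsv"))
  if (!is.null(res$cohort)) {
    write_gaming_profiles(res$cohort$questionnaires, p("questionnaires.tsv"))
    utils::write.table(res$cohort$subjects, p("cohort_true.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(res$fits)) {
    utils::write.table(res$fits, p("tva_fits.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(res$alpha)) {
    utils::write.table(res$alpha, p("alpha_ratios.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(res$stats)) {
    utils::write.table(res$cohort_table, p("cohort_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    for (nm in names(res$stats$anova_alpha)) {
      utils::write.table(as.data.frame(res$stats$anova_alpha[[nm]]),
                         p(sprintf("anova_alpha_%s.tsv", nm)), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    for (nm in names(res$stats$anova_params)) {
      utils::write.table(as.data.frame(res$stats$anova_params[[nm]]),
                         p(sprintf("anova_%s.tsv", nm)), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    reg <- res$stats$regression
    jsonlite::write_json(
      list(correlations = res$stats$correlations,
           regression = list(coefficients = as.list(reg$coefficients),
                             r_squared = reg$r_squared, F = reg$F,
                             df = reg$df, p = reg$p,
                             group_lines = reg$group_lines,
                             excluded = res$stats$screen$excluded)),
      p("stats.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(config$out_dir)
}
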