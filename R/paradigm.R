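#' Stimulus alphabet, display geometry, and design constants
#'
#' The whole-report paradigm draws 6 of 10 white geometrical shapes per
#' trial and places them on an invisible circle at six polar angles around
#' fixation. Stimulus displays are flashed at one of six nominal exposure
#' durations and followed by a pattern mask.
#'
#' @return `shape_alphabet()`: character vector of the 10 shape names.
#'   `display_angles()`: the six polar angles in degrees.
#'   `nominal_durations()`: the six nominal exposure durations in ms.
#' @export
shape_alphabet <- function() {
  c("circle", "ellipse", "hexagon", "diamond", "pentagon",
    "rhombus", "square", "star", "trapezoid", "triangle")
}

#' @rdname shape_alphabet
#' @export
display_angles <- function() c(30, 90, 150, 210, 270, 330)

#' @rdname shape_alphabet
#' @export
nominal_durations <- function() c(16.7, 33.4, 50.1, 83.5, 150.3, 200.4)

#' Enumerate all distinct stimulus displays
#'
#' Lists every way of choosing `display_size` distinct shapes from an
#' alphabet of `alphabet_size`; with the default 6-of-10 design this yields
#' the 210 displays used in the experiment, each presented exactly once per
#' experimental block.
#'
#' @param alphabet_size number of available shapes (default 10).
#' @param display_size shapes per display (default 6).
#' @return integer matrix with `display_size` rows; each column is one
#'   display given as indices into [shape_alphabet()].
#' @examples
#' ncol(enumerate_displays()) # 210
#' @export
enumerate_displays <- function(alphabet_size = 10, display_size = 6) {
  if (!(display_size > 0 && display_size <= alphabet_size)) {
    stop_tvalpha("display_size must satisfy 0 < display_size <= alphabet_size",
                 "tvalpha_invalid_design")
  }
  utils::combn(alphabet_size, display_size)
}

#' Build a full experiment schedule
#'
#' Produces the ordered trial list for one session: a 24-trial training
#' block (4 trials per exposure duration, displays drawn at random from the
#' 210) followed by two experimental blocks in which every display occurs
#' exactly once and every nominal duration exactly 35 times, in random
#' order. The shape-to-angle assignment is a fresh random bijection per
#' trial. Everything is a deterministic function of `seed`.
#'
#' @param seed integer seed controlling all randomisation.
#' @return data frame (one row per trial) with columns `block`
#'   (`training`/`block1`/`block2`), `trial_index` (within block),
#'   `display_id` (column index into [enumerate_displays()]),
#'   `duration_nominal_ms`, `duration_ms` (corrected duration, `NA` until
#'   [apply_timing_correction()] is used), `shapes` and `angles`
#'   (semicolon-joined, position-aligned).
#' @export
build_schedule <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  displays <- enumerate_displays()
  n_disp <- ncol(displays)
  durs <- nominal_durations()
  alphabet <- shape_alphabet()
  angles <- display_angles()

  with_local_seed(seed, {
    blocks <- list(
      training = list(ids = sample(n_disp, 24),
                      durs = sample(rep(durs, each = 4))),
      block1 = list(ids = sample(n_disp),
                    durs = sample(rep(durs, each = 35))),
      block2 = list(ids = sample(n_disp),
                    durs = sample(rep(durs, each = 35)))
    )
    rows <- lapply(names(blocks), function(bl) {
      b <- blocks[[bl]]
      n <- length(b$ids)
      shp <- character(n)
      for (i in seq_len(n)) {
        idx <- displays[, b$ids[i]]
        shp[i] <- paste(alphabet[idx][sample(length(idx))], collapse = ";")
      }
      data.frame(
        block = bl,
        trial_index = seq_len(n),
        display_id = b$ids,
        duration_nominal_ms = b$durs,
        duration_ms = NA_real_,
        shapes = shp,
        angles = paste(angles, collapse = ";"),
        stringsAsFactors = FALSE
      )
    })
    sched <- do.call(rbind, rows)
    attr(sched, "seed") <- as.integer(seed)
    sched
  })
}

#' Correct nominal exposure durations from a timing log
#'
#' Display timing on a 60 Hz monitor under a non-real-time OS deviates from
#' the requested durations. Each nominal duration is corrected by adding
#' the mode of its measured deviation distribution, after binning the
#' deviations to one decimal place (0.1 ms). Ties between equally frequent
#' bins are broken toward the smallest absolute deviation.
#'
#' @param log named list: one numeric vector of measured deviations (ms,
#'   may be negative) per nominal duration; names are the nominal
#'   durations formatted with [format_duration()].
#' @param nominal numeric vector of nominal durations to correct.
#' @return named numeric vector of corrected durations (ms), rounded to
#'   one decimal.
#' @examples
#' correct_durations(list(`16.7` = c(1.11, 1.08, 1.32)), 16.7) # 17.8
#' @export
correct_durations <- function(log, nominal = nominal_durations()) {
  keys <- format_duration(nominal)
  missing <- setdiff(keys, names(log))
  if (length(missing) > 0) {
    stop_tvalpha(paste0("no timing deviations for duration(s): ",
                        paste(missing, collapse = ", ")),
                 "tvalpha_missing_timing")
  }
  out <- vapply(seq_along(nominal), function(i) {
    dev <- log[[keys[i]]]
    if (length(dev) == 0) {
      stop_tvalpha(paste0("empty deviation list for duration ", keys[i]),
                   "tvalpha_missing_timing")
    }
    round(nominal[i] + binned_mode(dev), 1)
  }, numeric(1))
  names(out) <- keys
  out
}

#' @rdname correct_durations
#' @param x numeric durations.
#' @export
format_duration <- function(x) {
  sprintf("%g", x)
}

#' Fill corrected durations into a schedule
#'
#' @param schedule a schedule from [build_schedule()].
#' @param corrected named vector from [correct_durations()].
#' @return the schedule with `duration_ms` filled.
#' @export
apply_timing_correction <- function(schedule, corrected) {
  key <- format_duration(schedule$duration_nominal_ms)
  if (!all(key %in% names(corrected))) {
    stop_tvalpha("corrected durations do not cover every nominal duration",
                 "tvalpha_missing_timing")
  }
  schedule$duration_ms <- unname(corrected[key])
  schedule
}

#' Gaming genre categories
#'
#' Genres from the questionnaire, grouped as in the classification rules:
#' the first four are the "action-style" categories capped at 1 h/week for
#' non-video gamers, the last four are capped at 3 h/week.
#' @return character vector of the eight genre labels.
#' @export
gaming_genres <- function() {
  c("fps_tps", "action_rpg_adventure", "sports_driving", "rts_moba",
    "turnbased_rpg_fantasy", "turnbased_strategy_puzzle", "music", "other")
}

#' Classify a participant's gaming group from weekly play hours
#'
#' Applies the questionnaire rules: a participant is an action video gamer
#' (`AVG`) when their first/third-person-shooter plus action-RPG/adventure
#' play time reaches at least 5 h/week; a non-video gamer (`NVG`) when each
#' action-style genre is at most 1 h/week, each remaining genre at most
#' 3 h/week, and the total at most 5 h/week; everyone else is a non-action
#' video gamer (`NAVG`). The AVG rule is evaluated first.
#'
#' @param profile named numeric vector of average hours/week per genre
#'   (names as in [gaming_genres()]).
#' @param action_rule `"combined"` (default) applies the 5 h AVG threshold
#'   to the sum of the two action genres; `"per_genre"` requires a single
#'   action genre to reach 5 h.
#' @return one of `"NVG"`, `"NAVG"`, `"AVG"`.
#' @examples
#' classify_gamer(c(fps_tps = 6, action_rpg_adventure = 0,
#'                  sports_driving = 0, rts_moba = 0,
#'                  turnbased_rpg_fantasy = 0, turnbased_strategy_puzzle = 0,
#'                  music = 0, other = 0)) # "AVG"
#' @export
classify_gamer <- function(profile, action_rule = c("combined", "per_genre")) {
  action_rule <- match.arg(action_rule)
  genres <- gaming_genres()
  if (!all(genres %in% names(profile))) {
    stop_tvalpha("profile must name all eight genre categories",
                 "tvalpha_invalid_profile")
  }
  h <- as.numeric(profile[genres])
  if (anyNA(h) || any(h < 0)) {
    stop_tvalpha("hours must be defined and non-negative",
                 "tvalpha_invalid_profile")
  }
  names(h) <- genres
  action <- h[c("fps_tps", "action_rpg_adventure")]
  avg <- if (action_rule == "combined") sum(action) >= 5 else any(action >= 5)
  if (avg) return("AVG")
  low_caps <- h[c("fps_tps", "action_rpg_adventure", "sports_driving", "rts_moba")]
  high_caps <- h[c("turnbased_rpg_fantasy", "turnbased_strategy_puzzle",
                   "music", "other")]
  if (all(low_caps <= 1) && all(high_caps <= 3) && sum(h) <= 5) return("NVG")
  "NAVG"
}

#' Classify every subject in a long questionnaire table
#'
#' @param table data frame with columns `subject`, `genre`,
#'   `hours_per_week`.
#' @inheritParams classify_gamer
#' @return data frame with columns `subject` and `group`.
#' @export
classify_gamers <- function(table, action_rule = "combined") {
  stopifnot(all(c("subject", "genre", "hours_per_week") %in% names(table)))
  subjects <- unique(table$subject)
  grp <- vapply(subjects, function(s) {
    rows <- table[table$subject == s, ]
    prof <- stats::setNames(rows$hours_per_week, rows$genre)
    classify_gamer(prof, action_rule = action_rule)
  }, character(1))
  data.frame(subject = subjects, group = grp, stringsAsFactors = FALSE)
}

#' Read/write schedules and questionnaire tables as delimited text
#'
#' @param schedule,table data frame to write.
#' @param path file path (tab-separated text).
#' @name paradigm_io
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname paradigm_io
#' @export
read_schedule <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname paradigm_io
#' @export
write_gaming_profiles <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname paradigm_io
#' @export
read_gaming_profiles <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
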