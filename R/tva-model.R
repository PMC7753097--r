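#' TVA whole-report observer parameters
#'
#' In the Theory of Visual Attention (TVA), all displayed items race in
#' parallel toward a limited short-term store. Item `x` is processed at
#' rate `v_x = C * w_x / sum(w_z)` (items/s), so the rates always sum to
#' the total processing capacity `C`. Encoding only begins once the
#' effective exposure exceeds the perceptual threshold `t0`. The store
#' holds at most `K` items; a non-integer `K` is realised per trial as a
#' two-point mixture over `floor(K)` and `ceiling(K)` with weight
#' `K - floor(K)` on the larger value, so the long-exposure asymptote of
#' the mean score equals `K` exactly.
#'
#' @param C processing capacity, items/second, `>= 0`.
#' @param K short-term memory capacity, items, real-valued `>= 0`.
#' @param t0 perceptual threshold in ms, `>= 0`.
#' @param w attentional weights per display position (non-negative, at
#'   least one positive); defaults to uniform weights over 6 positions.
#' @return an object of class `tva_params`.
#' @export
tva_params <- function(C, K, t0 = 0, w = rep(1, 6)) {
  stopifnot(is.numeric(C), length(C) == 1, C >= 0,
            is.numeric(K), length(K) == 1, K >= 0,
            is.numeric(t0), length(t0) == 1, t0 >= 0,
            is.numeric(w), all(w >= 0), any(w > 0))
  structure(list(C = C, K = K, t0 = t0, w = w), class = "tva_params")
}

#' @export
print.tva_params <- function(x, ...) {
  cat(sprintf("TVA parameters: C = %.2f items/s, K = %.2f items, t0 = %.1f ms\n",
              x$C, x$K, x$t0))
  if (length(unique(x$w)) > 1) {
    cat("  attentional weights:", paste(signif(x$w / sum(x$w), 3), collapse = " "), "\n")
  }
  invisible(x)
}

# per-item encoding probabilities for a display of n_items
item_encoding_probs <- function(params, duration, n_items) {
  if (n_items < 1) {
    stop_tvalpha("display must contain at least one item", "tvalpha_invalid_display")
  }
  w <- params$w
  w <- if (length(w) >= n_items) w[seq_len(n_items)] else rep(1, n_items)
  if (all(w == 0)) w <- rep(1, n_items)
  v <- params$C * w / sum(w)            # items/s, sums to C
  tau <- max(0, duration - params$t0) / 1000  # effective exposure in s
  1 - exp(-v * tau)
}

#' Probability that one item is encoded
#'
#' Under uniform attentional weights each of the `n_items` racers runs at
#' rate `C / n_items`, so the probability that a given item finishes within
#' the effective exposure is
#' `1 - exp(-(C / n_items) * max(0, duration - t0) / 1000)`.
#'
#' @param params a [tva_params()] object.
#' @param duration exposure duration in ms.
#' @param n_items number of items in the display.
#' @return scalar encoding probability (uniform weights); with non-uniform
#'   weights, the vector of per-item probabilities.
#' @export
encoding_probability <- function(params, duration, n_items) {
  p <- item_encoding_probs(params, duration, n_items)
  if (length(unique(p)) == 1) p[1] else p
}

#' Distribution of the whole-report score
#'
#' The score is `S = min(K_r, B)` where `B` counts items whose race
#' finishes within the exposure (Binomial under uniform weights,
#' Poisson-binomial otherwise) and `K_r` is the trial's realised integer
#' capacity drawn from the floor/ceiling mixture of `K`.
#'
#' @inheritParams encoding_probability
#' @return numeric vector of length `n_items + 1` with `P(S = s)` for
#'   `s = 0..n_items`; sums to 1.
#' @export
score_pmf <- function(params, duration, n_items) {
  p <- item_encoding_probs(params, duration, n_items)
  # Poisson-binomial pmf of B by sequential convolution (exact)
  b <- 1
  for (pi in p) b <- c(b * (1 - pi), 0) + c(0, b * pi)
  kf <- floor(params$K)
  kc <- ceiling(params$K)
  wc <- params$K - kf
  pmf <- numeric(n_items + 1)
  for (kk in unique(c(kf, kc))) {
    wk <- if (kk == kf && kk == kc) 1 else if (kk == kf) 1 - wc else wc
    if (wk == 0) next
    if (kk >= n_items) {
      pmf <- pmf + wk * b
    } else {
      contrib <- numeric(n_items + 1)
      if (kk > 0) contrib[seq_len(kk)] <- b[seq_len(kk)]
      contrib[kk + 1] <- sum(b[(kk + 1):(n_items + 1)])
      pmf <- pmf + wk * contrib
    }
  }
  pmf
}

#' Expected whole-report score as a function of exposure duration
#'
#' The mean-score curve rises from 0 at `t0` with initial slope `C/1000`
#' items per ms and saturates at `min(K, n_items)`; its shape is what the
#' maximum-likelihood fit exploits to separate `C`, `K`, and `t0`.
#'
#' @inheritParams encoding_probability
#' @param durations numeric vector of exposure durations (ms).
#' @return numeric vector of expected scores, one per duration.
#' @export
expected_score_curve <- function(params, durations, n_items = 6) {
  stopifnot(length(durations) >= 1)
  vapply(durations, function(d) {
    sum(score_pmf(params, d, n_items) * 0:n_items)
  }, numeric(1))
}

# collapse a trial table to counts per (duration, score) cell
trial_counts <- function(trials, n_items = 6) {
  stopifnot(nrow(trials) >= 1)
  if (any(trials$score < 0 | trials$score > n_items)) {
    stop_tvalpha("trial scores must lie in 0..n_items", "tvalpha_data_error")
  }
  tab <- table(duration = trials$duration_ms, score = factor(trials$score, levels = 0:n_items))
  list(durations = as.numeric(rownames(tab)), counts = unclass(tab))
}

#' Log-likelihood of whole-report trials under TVA parameters
#'
#' Sums `log P(score | duration)` over trials. Cells with zero model
#' probability contribute a configurable large-negative floor instead of
#' `-Inf` so that optimisation remains well-behaved.
#'
#' @param params a [tva_params()] object.
#' @param trials data frame with columns `duration_ms` and `score`.
#' @param n_items items per display (6 in this design).
#' @param log_floor floor applied to per-trial log-probabilities.
#' @return scalar log-likelihood (`<= 0`).
#' @export
tva_log_likelihood <- function(params, trials, n_items = 6, log_floor = -700) {
  tc <- trial_counts(trials, n_items)
  ll <- 0
  for (i in seq_along(tc$durations)) {
    pmf <- score_pmf(params, tc$durations[i], n_items)
    lp <- pmax(log(pmf), log_floor)
    ll <- ll + sum(tc$counts[i, ] * lp)
  }
  ll
}

#' Maximum-likelihood estimation of TVA parameters
#'
#' Fits `(C, K, t0)` to whole-report accuracy data by bounded multi-start
#' maximisation of [tva_log_likelihood()]. `C` is optimised on the log
#' scale; the starts form a fixed grid over plausible capacities and
#' thresholds, so the fit is deterministic. Around 192 trials covering all
#' six exposure durations are needed for stable estimates; a warning is
#' issued below that.
#'
#' @param trials data frame with columns `duration_ms`, `score`, and
#'   (when `per_block = TRUE`) `block`.
#' @param n_items items per display.
#' @param per_block also fit each experimental block separately (210
#'   trials per block in the full design).
#' @param estimate_t0 estimate the perceptual threshold (default) or fix
#'   it at 0.
#' @param n_starts number of optimiser starts (taken from the start grid).
#' @param bounds list with elements `C`, `K`, `t0`, each `c(lower, upper)`.
#' @param min_trials trial count below which a warning is issued.
#' @return object of class `tva_fit`: `params`, `log_likelihood`,
#'   `converged`, `n_starts`, and (if requested) `per_block`, a named list
#'   of `tva_fit` objects.
#' @export
fit_tva <- function(trials, n_items = 6, per_block = FALSE,
                    estimate_t0 = TRUE, n_starts = 8,
                    bounds = list(C = c(0.5, 500), K = c(0, 6), t0 = c(0, 40)),
                    min_trials = 192) {
  if (nrow(trials) < min_trials) {
    warning(sprintf("only %d trials; at least %d recommended for stable TVA estimates",
                    nrow(trials), min_trials))
  }
  fit <- fit_tva_once(trials, n_items, estimate_t0, n_starts, bounds)
  if (per_block) {
    stopifnot("block" %in% names(trials))
    blocks <- sort(unique(trials$block))
    fit$per_block <- lapply(stats::setNames(blocks, blocks), function(b) {
      fit_tva_once(trials[trials$block == b, , drop = FALSE],
                   n_items, estimate_t0, n_starts, bounds)
    })
  }
  fit
}

fit_tva_once <- function(trials, n_items, estimate_t0, n_starts, bounds) {
  tc <- trial_counts(trials, n_items)
  negll <- function(par) {
    prm <- list(C = exp(par[1]), K = par[2],
                t0 = if (estimate_t0) par[3] else 0, w = rep(1, n_items))
    ll <- 0
    for (i in seq_along(tc$durations)) {
      pmf <- score_pmf(prm, tc$durations[i], n_items)
      ll <- ll + sum(tc$counts[i, ] * pmax(log(pmf), -700))
    }
    -ll
  }
  # fixed, diverse start set spanning the bounds (incl. a low-K start so
  # that degenerate all-zero data can reach the K lower bound)
  grid <- data.frame(C = c(40, 15, 80, 150, 30, 60, 10, 100),
                     K = c(3, 2, 4, 4, 0.5, 6, 3, 1),
                     t0 = c(10, 5, 30, 10, 0, 15, 35, 25))
  grid <- grid[seq_len(min(n_starts, nrow(grid))), , drop = FALSE]
  lower <- c(log(bounds$C[1]), bounds$K[1], bounds$t0[1])
  upper <- c(log(bounds$C[2]), bounds$K[2], bounds$t0[2])
  if (!estimate_t0) { lower <- lower[1:2]; upper <- upper[1:2] }
  best <- NULL
  any_ok <- FALSE
  for (i in seq_len(nrow(grid))) {
    start <- c(log(grid$C[i]), grid$K[i], if (estimate_t0) grid$t0[i])
    res <- tryCatch(
      stats::optim(start, negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    any_ok <- any_ok || res$convergence == 0
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop_tvalpha("all optimiser starts failed", "tvalpha_fit_failure")
  }
  params <- tva_params(C = exp(best$par[1]), K = best$par[2],
                       t0 = if (estimate_t0) best$par[3] else 0,
                       w = rep(1, n_items))
  structure(list(params = params,
                 log_likelihood = -best$value,
                 converged = any_ok,
                 n_starts = nrow(grid),
                 n_trials = nrow(trials),
                 bounds = bounds),
            class = "tva_fit")
}

#' @export
print.tva_fit <- function(x, ...) {
  cat(sprintf("TVA ML fit (%d trials, %d starts, %s)\n", x$n_trials,
              x$n_starts, if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  cat(sprintf("  log-likelihood: %.2f\n", x$log_likelihood))
  if (!is.null(x$per_block)) {
    for (b in names(x$per_block)) {
      cat(sprintf("  [%s] C = %.2f, K = %.2f, t0 = %.1f\n", b,
                  x$per_block[[b]]$params$C, x$per_block[[b]]$params$K,
                  x$per_block[[b]]$params$t0))
    }
  }
  invisible(x)
}

#' Simulate whole-report trials from the exponential race model
#'
#' Forward model used by the synthetic-data generator and for parameter
#' recovery: per trial, an integer capacity `K_r` is drawn from the
#' floor/ceiling mixture, each displayed item draws an exponential
#' completion time at its rate `v_x`, and the first `K_r` items finishing
#' before the effective exposure ends are encoded and reported. Reports
#' contain no false alarms (participants were instructed not to guess).
#'
#' @param params a [tva_params()] object.
#' @param schedule schedule from [build_schedule()], with corrected
#'   durations filled in; only experimental blocks are simulated.
#' @param seed integer seed.
#' @return data frame: `block`, `trial_index`, `duration_ms`, `displayed`,
#'   `reported` (semicolon-joined shape names), `score`.
#' @export
simulate_trials <- function(params, schedule, seed) {
  sched <- schedule[schedule$block %in% c("block1", "block2"), , drop = FALSE]
  stopifnot(nrow(sched) > 0)
  dur <- sched$duration_ms
  if (anyNA(dur)) dur <- sched$duration_nominal_ms
  n <- nrow(sched)
  with_local_seed(seed, {
    n_items <- length(strsplit(sched$shapes[1], ";")[[1]])
    kf <- floor(params$K); frac <- params$K - kf
    k_r <- kf + (stats::runif(n) < frac)
    tau <- pmax(0, dur - params$t0) / 1000
    w <- params$w
    w <- if (length(w) >= n_items) w[seq_len(n_items)] else rep(1, n_items)
    v <- params$C * w / sum(w)
    times <- matrix(stats::rexp(n * n_items, rate = 1), nrow = n_items) / v
    finished <- sweep(times, 2, tau, `<=`)
    b_count <- colSums(finished)
    score <- pmin(k_r, b_count)
    reported <- character(n)
    shapes_list <- strsplit(sched$shapes, ";")
    for (i in seq_len(n)) {
      if (score[i] == 0) { reported[i] <- ""; next }
      fin <- which(finished[, i])
      enc <- fin[order(times[fin, i])][seq_len(score[i])]
      reported[i] <- paste(shapes_list[[i]][enc], collapse = ";")
    }
    data.frame(block = sched$block, trial_index = sched$trial_index,
               duration_ms = dur, displayed = sched$shapes,
               reported = reported, score = score,
               stringsAsFactors = FALSE)
  })
}

#' Read/write whole-report trial tables
#'
#' @param trials data frame of trials (optionally with a `subject` column).
#' @param path tab-separated text file.
#' @name trial_io
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_trials <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", colClasses = NA)
}
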