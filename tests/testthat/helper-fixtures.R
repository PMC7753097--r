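# shared fixtures, built in code at test time

uniform_profile <- function(...) {
  h <- stats::setNames(numeric(8), gaming_genres())
  over <- list(...)
  h[names(over)] <- unlist(over)
  h
}

# schedule with the printed corrected durations filled in
corrected_schedule <- function(seed = 1) {
  apply_timing_correction(
    build_schedule(seed),
    c(`16.7` = 17.8, `33.4` = 35.6, `50.1` = 53.4,
      `83.5` = 89, `150.3` = 144.6, `200.4` = 198))
}

# minimal trial table at a single duration for simulation checks
flat_schedule <- function(n, duration_ms = 100) {
  data.frame(block = "block1", trial_index = seq_len(n), display_id = 1L,
             duration_nominal_ms = duration_ms, duration_ms = duration_ms,
             shapes = "circle;ellipse;hexagon;diamond;pentagon;rhombus",
             angles = paste(display_angles(), collapse = ";"),
             stringsAsFactors = FALSE)
}

# subject-by-block long table for mixed-ANOVA checks
sim_cohort_frame <- function(seed = 1, n = c(NVG = 14, NAVG = 15, AVG = 9),
                             effect = 0) {
  set.seed(seed)
  g <- rep(names(n), n)
  N <- sum(n)
  b1 <- rnorm(N, 40, 6)
  b2 <- b1 + rnorm(N, 0, 3) + effect * (g == "AVG")
  data.frame(subject = sprintf("S%02d", 1:N), group = g,
             value = c(b1, b2),
             block = rep(c("block1", "block2"), each = N),
             stringsAsFactors = FALSE)
}

# independent oracle for the score distribution: direct enumeration over
# the realised capacity and the binomial encoding count
score_pmf_oracle <- function(C, K, t0, duration, n_items) {
  p <- 1 - exp(-(C / n_items) * max(0, duration - t0) / 1000)
  kf <- floor(K); kc <- ceiling(K); wc <- K - kf
  pmf <- numeric(n_items + 1)
  for (b in 0:n_items) {
    pb <- stats::dbinom(b, n_items, p)
    for (k in unique(c(kf, kc))) {
      wk <- if (kf == kc) 1 else if (k == kf) 1 - wc else wc
      s <- min(k, b)
      pmf[s + 1] <- pmf[s + 1] + wk * pb
    }
  }
  pmf
}

# recording holding pure sinusoids on every channel, with one trial epoch:
# [pre 512][gap][post 512]; pre/post amplitudes set per channel group
sinusoid_recording <- function(freq = 11, amp_pre = 10, amp_post = 10,
                               sfreq = 1024, n_trials = 4, gap = 100,
                               ch = montage_1010(), duration_ms = 89) {
  nw <- round(sfreq / 2)
  ep <- nw + gap + nw
  total <- ep * n_trials
  t_idx <- seq_len(total) - 1
  starts <- (seq_len(n_trials) - 1) * ep + 1
  env <- rep(c(rep(amp_pre, nw), rep(amp_post, gap + nw)), n_trials)
  base <- env * sin(2 * pi * freq * t_idx / sfreq)
  data <- matrix(rep(base, length(ch)), ncol = length(ch))
  stim <- starts + nw
  events <- data.frame(
    sample = c(stim, stim + gap, stim + gap + round(0.501 * sfreq)),
    type = rep(c("stimulus", "mask_on", "mask_off"), each = n_trials),
    trial = rep(seq_len(n_trials), 3),
    block = "block1", duration_ms = duration_ms, stringsAsFactors = FALSE)
  events <- events[events$sample + nw - 1 <= total | events$type != "mask_on", ]
  eeg_recording(data, sfreq, ch, events)
}

# spectral chain on raw segment arrays: trial-average -> ratio -> band ROI
band_chain <- function(pre, post, sfreq = 1024, ch = montage_1010(),
                       band = "medium") {
  sp_pre <- trial_average_spectrum(pre, sfreq, ch, min_trials = 0)
  sp_post <- trial_average_spectrum(post, sfreq, ch, min_trials = 0)
  band_roi_log_ratio(power_ratio(sp_pre, sp_post), band)
}

# alpha-plus-noise segment arrays with programmed attenuation d
make_segments <- function(n_trials, d, amp = 20, noise_sd = 4, freq = 11,
                          sfreq = 1024, ch = montage_1010(), seed = 1) {
  nw <- round(sfreq / 2)
  nch <- length(ch)
  roi <- ch %in% posterior_roi()
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    mk <- function(amp_scale) {
      seg <- array(rnorm(nw * nch * n_trials, sd = noise_sd), c(nw, nch, n_trials))
      for (i in seq_len(n_trials)) {
        wave <- amp_scale * amp * sin(2 * pi * freq * (seq_len(nw) - 1) / sfreq +
                                        runif(1, 0, 2 * pi))
        seg[, roi, i] <- seg[, roi, i] + wave
      }
      seg
    }
    list(pre = mk(1), post = mk(10^(-d / 2)))
  })
}
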