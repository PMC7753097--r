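test_that("500 ms windows at 1024 Hz give an exact 2 Hz frequency grid", {
  seg <- array(rnorm(512 * 3 * 4), c(512, 3, 4))
  sp <- trial_average_spectrum(seg, 1024, c("A", "B", "C"), min_trials = 0)
  expect_equal(unique(diff(sp$freq)), 2)
  expect_equal(sp$freq[1], 0)
  expect_equal(max(sp$freq), 512)
  expect_true(all(sp$power >= 0))
})

test_that("filtering notches line noise and leaves the alpha band intact", {
  ch <- montage_1010()
  n <- 8192; fs <- 1024
  t_idx <- (seq_len(n) - 1) / fs
  mk_rec <- function(freq) {
    x <- matrix(rep(sin(2 * pi * freq * t_idx), length(ch)), ncol = length(ch))
    eeg_recording(x, fs, ch, data.frame(sample = 2000, type = "stimulus",
                                        trial = 1, block = "block1",
                                        duration_ms = 89))
  }
  band_power <- function(rec, freq) {
    mid <- rec$data[2049:6144, 1]  # interior, away from filter edges
    sp <- Mod(fft(mid))^2
    f <- (seq_along(mid) - 1) * fs / length(mid)
    sum(sp[abs(f - freq) < 1])
  }
  r50 <- mk_rec(50)
  p_before <- band_power(r50, 50)
  p_after <- band_power(preprocess_eeg(r50, reref = FALSE), 50)
  expect_gt(10 * log10(p_before / p_after), 20)
  r11 <- mk_rec(11)
  p11_before <- band_power(r11, 11)
  p11_after <- band_power(preprocess_eeg(r11, reref = FALSE), 11)
  expect_lt(abs(10 * log10(p11_before / p11_after)), 1)
})

test_that("common-average re-referencing zeroes the channel mean", {
  ch <- montage_1010()
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(2048 * length(ch)), ncol = length(ch)),
                       1024, ch, data.frame(sample = 1024, type = "stimulus",
                                            trial = 1, block = "block1",
                                            duration_ms = 89))
  out <- preprocess_eeg(rec, bandpass = NULL, notch = NULL)
  expect_lt(max(abs(rowMeans(out$data))), 1e-10)
})

test_that("preprocessing validates input and resamples to 1024 Hz", {
  ch <- montage_1010()
  expect_error(
    preprocess_eeg(eeg_recording(matrix(0, 100, 3), 1024, c("A", "B", "C"),
                                 data.frame(sample = 50, type = "stimulus",
                                            trial = 1))),
    class = "tvalpha_channel_error")
  rec <- eeg_recording(matrix(rnorm(4000 * length(ch)), ncol = length(ch)),
                       100, ch, data.frame(sample = 2000, type = "stimulus",
                                           trial = 1, block = "block1",
                                           duration_ms = 89))
  expect_error(preprocess_eeg(rec), class = "tvalpha_sampling_error")
  rec1000 <- eeg_recording(matrix(rnorm(5000 * length(ch)), ncol = length(ch)),
                           1000, ch,
                           data.frame(sample = 2500, type = "stimulus",
                                      trial = 1, block = "block1",
                                      duration_ms = 89))
  out <- preprocess_eeg(rec1000, bandpass = NULL, notch = NULL, reref = FALSE)
  expect_equal(out$sfreq, 1024)
  expect_equal(nrow(out$data), 5120)
  expect_equal(out$events$sample, as.integer(round(2499 * 1.024)) + 1L)
})

test_that("segmentation cuts 512-sample windows around the markers", {
  ch <- c("P1", "P2", posterior_roi()[-(4:5)])
  n <- 5000
  data <- matrix(rep(seq_len(n), length(ch)), ncol = length(ch))
  events <- data.frame(sample = c(1000, 300, 1100, 400, 1613, 913),
                       type = rep(c("stimulus", "mask_on", "mask_off"), each = 2),
                       trial = rep(1:2, 3),
                       block = "block1", duration_ms = 89)
  rec <- eeg_recording(data, 1024, ch, events)
  segs <- segment_trials(rec)
  # trial 2's pre window would start at sample -212: dropped
  expect_equal(dim(segs$pre)[3], 1)
  expect_equal(segs$n_dropped, 1)
  expect_equal(segs$pre[, 1, 1], 488:999)
  expect_equal(segs$post[, 1, 1], 1100:1611)
  # mask-offset anchoring shifts the post window
  segs_off <- segment_trials(rec, post_anchor = "mask_offset")
  expect_equal(segs_off$post[, 1, 1], 1613:2124)
  # no valid trial at all
  bad <- rec
  bad$events$sample <- c(300, 310, 400, 410, 913, 923)
  expect_error(segment_trials(bad), class = "tvalpha_empty_data")
})

test_that("spectra peak at the stimulus frequency and average linearly", {
  nw <- 512; fs <- 1024
  wave <- sin(2 * pi * 12 * (seq_len(nw) - 1) / fs)
  seg1 <- array(wave, c(nw, 1, 1))
  sp1 <- trial_average_spectrum(seg1, fs, "O1", min_trials = 0)
  expect_equal(sp1$freq[which.max(sp1$power)], 12)
  # unit-amplitude sinusoid at a bin centre has mean power 1/2
  expect_equal(max(sp1$power), 0.5, tolerance = 0.01)
  # averaging identical segments equals the single-segment spectrum
  segN <- array(rep(wave, 8), c(nw, 1, 8))
  spN <- trial_average_spectrum(segN, fs, "O1", min_trials = 0)
  expect_equal(spN$power, sp1$power)
  expect_warning(trial_average_spectrum(segN, fs, "O1"), "stabilise")
  # white noise is flat across bins up to sampling error
  set.seed(2)
  segW <- array(rnorm(nw * 1 * 400), c(nw, 1, 400))
  spW <- trial_average_spectrum(segW, fs, "O1", min_trials = 0)
  inner <- spW$power[spW$freq > 10 & spW$freq < 500]
  expect_lt(stats::sd(inner) / mean(inner), 0.15)
})

test_that("power ratios follow the amplitude-squared law", {
  seg <- make_segments(10, d = 0, noise_sd = 0)
  sp_pre <- trial_average_spectrum(seg$pre, 1024, montage_1010(), min_trials = 0)
  # identical spectra: unit ratio wherever power is nonzero
  self <- power_ratio(sp_pre, sp_pre)
  nz <- sp_pre$power > 0
  expect_equal(unname(self[nz]), rep(1, sum(nz)))
  expect_equal(band_roi_log_ratio(self, "medium"), 0, tolerance = 1e-12)
  # halving the post amplitude quadruples the ratio in the band
  half <- make_segments(10, d = 2 * log10(2), noise_sd = 0)
  sp_post <- trial_average_spectrum(half$post, 1024, montage_1010(), min_trials = 0)
  ratio <- power_ratio(sp_pre, sp_post)
  roi <- montage_1010() %in% posterior_roi()
  band <- attr(ratio, "freq") %in% c(10, 12)
  expect_equal(mean(ratio[band, roi]), 4, tolerance = 1e-3)
  # grids must match
  short <- trial_average_spectrum(seg$pre[1:256, , , drop = FALSE], 512,
                                  montage_1010(), min_trials = 0)
  expect_error(power_ratio(sp_pre, short), class = "tvalpha_grid_mismatch")
})

test_that("band ROI log-ratios encode attenuation sign and magnitude", {
  freq <- seq(0, 512, by = 2)
  ch <- montage_1010()
  mk_ratio <- function(v) {
    m <- matrix(v, length(freq), length(ch))
    attr(m, "freq") <- freq; attr(m, "ch_names") <- ch
    m
  }
  expect_equal(band_roi_log_ratio(mk_ratio(1), "medium"), 0)
  expect_equal(band_roi_log_ratio(mk_ratio(4), "medium"), log10(4))
  expect_equal(band_roi_log_ratio(mk_ratio(0.5), "upper"), log10(0.5))
  bad <- mk_ratio(1); attr(bad, "ch_names") <- sub("O1", "XX", ch)
  expect_error(band_roi_log_ratio(bad, "medium"), class = "tvalpha_channel_error")
})

test_that("post-window amplitude scaling shifts the log-ratio analytically", {
  # scaling the post alpha amplitude by a changes the band log-ratio by
  # exactly -2*log10(a) in noise-free signals
  base <- make_segments(12, d = 0.1, noise_sd = 0)
  r0 <- band_chain(base$pre, base$post)
  for (a in c(0.5, 0.8, 1.6)) {
    scaled <- base
    roi <- montage_1010() %in% posterior_roi()
    scaled$post[, roi, ] <- scaled$post[, roi, ] * a
    expect_equal(band_chain(scaled$pre, scaled$post), r0 - 2 * log10(a),
                 tolerance = 1e-9)
  }
})

test_that("the spectral chain recovers programmed attenuation", {
  # noise-free: exact up to spectral leakage
  for (d in c(0, 0.05, 0.12)) {
    seg <- make_segments(20, d = d, noise_sd = 0, seed = 3)
    expect_equal(band_chain(seg$pre, seg$post), d, tolerance = 1e-3)
  }
  # with background noise: unbiased, error shrinking with trial count
  d <- 0.08
  err <- sapply(c(15, 60), function(nt) {
    est <- sapply(1:8, function(r) {
      seg <- make_segments(nt, d = d, seed = 100 * nt + r)
      band_chain(seg$pre, seg$post)
    })
    c(bias = mean(est) - d, sd = stats::sd(est))
  })
  expect_lt(abs(err["bias", 1]), 0.02)
  expect_lt(err["sd", 2], err["sd", 1])
})

test_that("subject averages pool the 12 cells symmetrically", {
  tab <- expand.grid(block = c("block1", "block2"),
                     duration_ms = c(17.8, 35.6, 53.4, 89, 144.6, 198),
                     band = c("medium", "upper"), stringsAsFactors = FALSE)
  tab$log_ratio <- ifelse(tab$band == "medium",
                          ifelse(tab$block == "block1", 0.1, 0.3), 0.05)
  avg <- subject_average_ratio(tab)
  expect_equal(unname(avg["medium"]), 0.2)
  expect_equal(unname(avg["upper"]), 0.05)
  expect_equal(subject_average_ratio(tab[sample(nrow(tab)), ]), avg)
  expect_error(subject_average_ratio(tab[-1, ]), class = "tvalpha_incomplete_data")
  expect_warning(got <- subject_average_ratio(tab[-1, ], require_complete = FALSE),
                 "available cells")
  expect_equal(unname(got["medium"]), mean(tab$log_ratio[tab$band == "medium"][-1]))
})
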