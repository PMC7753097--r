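# Zero-phase frequency-domain filtering. The combined response is a
# Butterworth-magnitude band-pass (order 2 high-pass, order 4 low-pass)
# times a Gaussian notch. Applied via FFT over the whole recording, two
# real channels packed per complex transform (valid because the response
# is real and even).
fft_filter_response <- function(freq, bandpass, notch, notch_sigma = 1.5) {
  f <- pmax(abs(freq), 1e-9)
  h <- rep(1, length(f))
  if (!is.null(bandpass)) {
    h <- h / sqrt(1 + (bandpass[1] / f)^4)      # high-pass, order 2
    h <- h / sqrt(1 + (f / bandpass[2])^8)      # low-pass, order 4
  }
  if (!is.null(notch)) {
    h <- h * (1 - exp(-((f - notch) / notch_sigma)^2))
  }
  h
}

fft_filter_matrix <- function(x, sfreq, bandpass, notch) {
  n <- nrow(x)
  nc <- ncol(x)
  N <- stats::nextn(n, c(2, 3, 5))
  k <- floor(N / 2)
  freq <- c(0:k, if (N %% 2 == 0) -((k - 1):1) else -(k:1)) * sfreq / N
  H <- fft_filter_response(freq, bandpass, notch)
  out <- x
  j <- 1
  while (j <= nc) {
    x1 <- c(x[, j], numeric(N - n))
    two <- j + 1 <= nc
    x2 <- if (two) c(x[, j + 1], numeric(N - n)) else numeric(N)
    y <- stats::fft(stats::fft(complex(real = x1, imaginary = x2)) * H,
                    inverse = TRUE) / N
    out[, j] <- Re(y)[seq_len(n)]
    if (two) out[, j + 1] <- Im(y)[seq_len(n)]
    j <- j + 2
  }
  out
}

#' Preprocess an EEG recording
#'
#' Applies, in order: a 0.1-120 Hz band-pass and 50 Hz notch filter
#' (zero-phase, frequency-domain), common-average re-referencing over the
#' scalp channels, and resampling to 1024 Hz (chosen so that 500 ms
#' windows hold exactly 512 samples and the FFT grid is 2 Hz). Channels
#' whose label starts with `"EOG"` are excluded from the common average.
#'
#' @param rec an [eeg_recording()]; sampling rate must be at least 256 Hz.
#' @param bandpass `c(low, high)` band edges in Hz, or `NULL` to skip.
#' @param notch notch centre frequency in Hz, or `NULL` to skip.
#' @param reref apply the common-average reference.
#' @param target_sfreq resampling target in Hz.
#' @param roi channels that must be present (error if missing).
#' @return the preprocessed [eeg_recording()].
#' @export
preprocess_eeg <- function(rec, bandpass = c(0.1, 120), notch = 50,
                           reref = TRUE, target_sfreq = 1024,
                           roi = posterior_roi()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$sfreq < 256) {
    stop_tvalpha("sampling rate must be >= 256 Hz", "tvalpha_sampling_error")
  }
  missing <- setdiff(roi, rec$ch_names)
  if (length(missing) > 0) {
    stop_tvalpha(paste0("missing ROI channel(s): ", paste(missing, collapse = ", ")),
                 "tvalpha_channel_error")
  }
  x <- rec$data
  if (!is.null(bandpass) || !is.null(notch)) {
    x <- fft_filter_matrix(x, rec$sfreq, bandpass, notch)
  }
  if (reref) {
    scalp <- !startsWith(rec$ch_names, "EOG")
    x <- x - rowMeans(x[, scalp, drop = FALSE])
  }
  events <- rec$events
  sfreq <- rec$sfreq
  if (!is.null(target_sfreq) && !isTRUE(all.equal(sfreq, target_sfreq))) {
    frac <- resample_fraction(target_sfreq, sfreq)
    x <- apply(x, 2, function(col) signal::resample(col, frac[1], frac[2]))
    events$sample <- pmax(1L, as.integer(round((events$sample - 1) *
                                                 target_sfreq / sfreq)) + 1L)
    sfreq <- target_sfreq
  }
  eeg_recording(x, sfreq, rec$ch_names, events)
}

# reduced p/q such that target = orig * p / q
resample_fraction <- function(target, orig) {
  p <- round(target * 1000)
  q <- round(orig * 1000)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Cut pre-stimulus and post-mask windows around each trial
#'
#' Extracts, per trial, a 500 ms window ending at stimulus onset and a
#' 500 ms window anchored to the mask (at mask onset by default; the mask
#' itself lasts 501 ms, so the onset-anchored window covers the period
#' directly following stimulus processing). Trials whose windows fall
#' outside the recording are dropped and counted.
#'
#' @param rec a preprocessed [eeg_recording()].
#' @param window_ms window length in ms.
#' @param post_anchor `"mask_onset"` (default) or `"mask_offset"`.
#' @return object of class `segment_pairs`: arrays `pre` and `post`
#'   (samples x channels x trials), a per-trial `info` data frame
#'   (`trial`, `block`, `duration_ms`), `sfreq`, `ch_names`, and
#'   `n_dropped`.
#' @export
segment_trials <- function(rec, window_ms = 500,
                           post_anchor = c("mask_onset", "mask_offset")) {
  post_anchor <- match.arg(post_anchor)
  nw <- round(window_ms / 1000 * rec$sfreq)
  ev <- rec$events
  stim <- ev[ev$type == "stimulus", ]
  anchor_type <- if (post_anchor == "mask_onset") "mask_on" else "mask_off"
  mask <- ev[ev$type == anchor_type, ]
  key <- function(d) paste(d$block, d$trial)
  mask <- mask[match(key(stim), key(mask)), ]
  ok <- !is.na(mask$sample) &
    (stim$sample - nw) >= 1 &
    (mask$sample + nw - 1) <= nrow(rec$data)
  n_dropped <- sum(!ok)
  if (!any(ok)) {
    stop_tvalpha("no trial has both windows inside the recording",
                 "tvalpha_empty_data")
  }
  stim <- stim[ok, ]; mask <- mask[ok, ]
  n_tr <- nrow(stim)
  nch <- ncol(rec$data)
  pre <- array(0, c(nw, nch, n_tr))
  post <- array(0, c(nw, nch, n_tr))
  for (i in seq_len(n_tr)) {
    pre[, , i] <- rec$data[(stim$sample[i] - nw):(stim$sample[i] - 1), ]
    post[, , i] <- rec$data[mask$sample[i]:(mask$sample[i] + nw - 1), ]
  }
  structure(list(pre = pre, post = post,
                 info = data.frame(trial = stim$trial, block = stim$block,
                                   duration_ms = stim$duration_ms,
                                   stringsAsFactors = FALSE),
                 sfreq = rec$sfreq, ch_names = rec$ch_names,
                 n_dropped = n_dropped),
            class = "segment_pairs")
}

#' Trial-averaged FFT power spectrum
#'
#' Computes per-trial windowed FFT power and averages across trials, per
#' channel and frequency bin. With 512-sample windows at 1024 Hz the bin
#' spacing is exactly 2 Hz. Power is normalised so that a unit-amplitude
#' sinusoid at a bin centre yields its mean power 0.5 (in microvolt^2);
#' the normalisation cancels in pre/post ratios. Fewer than 15 trials
#' triggers a warning (ratio estimates stabilise at about 15 trials).
#'
#' @param segments 3-dimensional array (samples x channels x trials), or
#'   one of the `pre`/`post` arrays of a `segment_pairs` object.
#' @param sfreq sampling rate in Hz.
#' @param ch_names channel labels.
#' @param taper `"hann"` (default) or `"none"`.
#' @param min_trials trial count below which a warning is issued.
#' @return object of class `power_spectrum`: `freq` (Hz), `power`
#'   (frequency x channel matrix), `n_trials`, `ch_names`.
#' @export
trial_average_spectrum <- function(segments, sfreq, ch_names,
                                   taper = c("hann", "none"),
                                   min_trials = 15) {
  taper <- match.arg(taper)
  stopifnot(length(dim(segments)) == 3)
  n <- dim(segments)[1]
  nch <- dim(segments)[2]
  n_tr <- dim(segments)[3]
  if (n_tr == 0) stop_tvalpha("no segments to average", "tvalpha_empty_data")
  if (n_tr < min_trials) {
    warning(sprintf("only %d trials; ratio estimates stabilise at about %d",
                    n_tr, min_trials))
  }
  w <- if (taper == "hann") 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1))) else rep(1, n)
  mat <- matrix(segments, nrow = n) * w
  sp <- Mod(stats::mvfft(mat))^2 * (2 / sum(w)^2)
  nbin <- n %/% 2 + 1
  sp <- array(sp[seq_len(nbin), , drop = FALSE], c(nbin, nch, n_tr))
  power <- if (n_tr > 1) rowMeans(sp, dims = 2) else
    matrix(sp[, , 1], nbin, nch)
  structure(list(freq = (seq_len(nbin) - 1) * sfreq / n,
                 power = power, n_trials = n_tr, ch_names = ch_names),
            class = "power_spectrum")
}

#' Pre/post spectral power ratio
#'
#' Elementwise ratio of the trial-averaged pre-stimulus spectrum to the
#' trial-averaged post-mask spectrum. Values above 1 in the alpha band
#' indicate post-mask power loss (event-related desynchronisation, ERD);
#' values below 1 indicate synchronisation (ERS). Zero-power denominator
#' bins are replaced by a small epsilon and counted in the
#' `n_regularised` attribute.
#'
#' @param pre,post `power_spectrum` objects on identical grids.
#' @param eps regularisation added to the denominator (microvolt^2).
#' @return frequency x channel matrix of ratios, with attributes `freq`,
#'   `ch_names`, and `n_regularised`.
#' @export
power_ratio <- function(pre, post, eps = 1e-12) {
  stopifnot(inherits(pre, "power_spectrum"), inherits(post, "power_spectrum"))
  if (!isTRUE(all.equal(pre$freq, post$freq)) ||
      !identical(pre$ch_names, post$ch_names)) {
    stop_tvalpha("pre and post spectra are on different grids",
                 "tvalpha_grid_mismatch")
  }
  n_zero <- sum(post$power <= 0)
  denom <- post$power
  denom[denom <= 0] <- eps
  ratio <- pre$power / denom
  attr(ratio, "freq") <- pre$freq
  attr(ratio, "ch_names") <- pre$ch_names
  attr(ratio, "n_regularised") <- n_zero
  ratio
}

# frequency bins per band on the 2 Hz grid; the shared 12 Hz bin mirrors
# the overlapping 10-12 / 12-14 Hz band edges
alpha_band_bins <- function(band) {
  switch(band,
         medium = c(10, 12),
         upper = c(12, 14),
         stop_tvalpha("band must be 'medium' or 'upper'", "tvalpha_bad_band"))
}

#' Posterior-ROI band-averaged log10 ratio
#'
#' Averages a pre/post ratio matrix over the posterior ROI channels and
#' the requested alpha band bins (medium: 10 and 12 Hz; upper: 12 and
#' 14 Hz on the 2 Hz grid), then takes log10. Positive values indicate
#' ERD, negative values ERS.
#'
#' @param ratio matrix from [power_ratio()].
#' @param band `"medium"` (10-12 Hz) or `"upper"` (12-14 Hz).
#' @param roi ROI channel labels.
#' @return scalar log10 ratio.
#' @export
band_roi_log_ratio <- function(ratio, band = c("medium", "upper"),
                               roi = posterior_roi()) {
  band <- match.arg(band)
  freq <- attr(ratio, "freq")
  ch <- attr(ratio, "ch_names")
  missing <- setdiff(roi, ch)
  if (length(missing) > 0) {
    stop_tvalpha(paste0("missing ROI channel(s): ", paste(missing, collapse = ", ")),
                 "tvalpha_channel_error")
  }
  bins <- freq %in% alpha_band_bins(band)
  log10(mean(ratio[bins, ch %in% roi]))
}

#' Alpha log-ratios per block, exposure duration and band
#'
#' Runs the spectral chain on a segmented recording: within every
#' block-by-duration cell, trial-average the pre and post windows,
#' form the pre/post ratio, average it over the posterior ROI and band,
#' and log10-transform.
#'
#' @param segs a `segment_pairs` object from [segment_trials()].
#' @param bands which bands to compute.
#' @param roi ROI channel labels.
#' @param taper FFT taper, see [trial_average_spectrum()].
#' @return data frame: `block`, `duration_ms`, `band`, `log_ratio`,
#'   `n_trials`.
#' @export
alpha_ratio_table <- function(segs, bands = c("medium", "upper"),
                              roi = posterior_roi(), taper = "hann") {
  stopifnot(inherits(segs, "segment_pairs"))
  cells <- unique(segs$info[, c("block", "duration_ms")])
  cells <- cells[order(cells$block, cells$duration_ms), ]
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- segs$info$block == cells$block[i] &
      segs$info$duration_ms == cells$duration_ms[i]
    pre <- trial_average_spectrum(segs$pre[, , sel, drop = FALSE], segs$sfreq,
                                  segs$ch_names, taper = taper, min_trials = 0)
    post <- trial_average_spectrum(segs$post[, , sel, drop = FALSE], segs$sfreq,
                                   segs$ch_names, taper = taper, min_trials = 0)
    ratio <- power_ratio(pre, post)
    for (b in bands) {
      out[[length(out) + 1]] <- data.frame(
        block = cells$block[i], duration_ms = cells$duration_ms[i],
        band = b, log_ratio = band_roi_log_ratio(ratio, b, roi),
        n_trials = sum(sel), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-subject average alpha ratio
#'
#' Unweighted mean of the 12 block-by-duration log-ratio cells per band
#' (6 exposure durations x 2 blocks), the quantity correlated with the
#' subject's TVA parameters.
#'
#' @param table data frame from [alpha_ratio_table()] (one subject).
#' @param require_complete error when any of the 12 cells is missing
#'   (default); otherwise average the available cells with a warning.
#' @return named numeric vector, one average log-ratio per band.
#' @export
subject_average_ratio <- function(table, require_complete = TRUE) {
  bands <- unique(table$band)
  vapply(stats::setNames(bands, bands), function(b) {
    rows <- table[table$band == b, ]
    n_cells <- length(unique(rows$block)) * length(unique(rows$duration_ms))
    if (nrow(rows) < 12) {
      if (require_complete) {
        stop_tvalpha(sprintf("band %s has %d of 12 cells", b, nrow(rows)),
                     "tvalpha_incomplete_data")
      }
      warning(sprintf("band %s: averaging %d available cells", b, nrow(rows)))
    }
    mean(rows$log_ratio)
  }, numeric(1))
}
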