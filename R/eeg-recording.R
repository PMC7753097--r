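#' The posterior region of interest and the 62-channel montage
#'
#' Alpha ratios are averaged over 17 occipital, parietal and
#' parieto-occipital channels. `montage_1010()` lists the 62 scalp
#' channels of the recording cap (10-10 system) used by the synthetic
#' generator; the ROI is a subset of it.
#'
#' @return character vector of channel labels.
#' @export
posterior_roi <- function() {
  c("O1", "O2", "Oz", "P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8",
    "PO3", "PO4", "PO7", "PO8", "POz", "Pz")
}

#' @rdname posterior_roi
#' @export
montage_1010 <- function() {
  c("Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "FT9", "FT10")
}

#' Multichannel EEG recording with event markers
#'
#' Lightweight in-memory container: a samples-by-channels matrix in
#' microvolts, the sampling rate, channel labels, and an event table
#' keying stimulus and mask markers to trials.
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param sfreq sampling rate in Hz.
#' @param ch_names character vector of channel labels (one per column).
#' @param events data frame with columns `sample` (1-based), `type` (one
#'   of `"stimulus"`, `"mask_on"`, `"mask_off"`), `trial`, `block`,
#'   `duration_ms`.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, ch_names, events) {
  data <- as.matrix(data)
  if (!identical(oldClass(data), NULL)) {
    data <- matrix(as.numeric(data), nrow(data), ncol(data))
  }
  stopifnot(is.numeric(data), ncol(data) == length(ch_names),
            is.numeric(sfreq), sfreq > 0)
  stopifnot(all(c("sample", "type", "trial") %in% names(events)))
  if (any(events$sample < 1 | events$sample > nrow(data))) {
    stop_tvalpha("event markers outside recording span", "tvalpha_marker_error")
  }
  structure(list(data = data, sfreq = sfreq, ch_names = ch_names,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels, %d samples @ %g Hz (%.1f s), %d events\n",
              ncol(x$data), nrow(x$data), x$sfreq, nrow(x$data) / x$sfreq,
              nrow(x$events)))
  invisible(x)
}

# --- BrainVision triplet I/O (IEEE float32, multiplexed) -------------------

#' Write / read a recording as a BrainVision triplet
#'
#' Writes `<basename>.vhdr` (text header), `<basename>.vmrk` (markers)
#' and `<basename>.eeg` (binary IEEE float32, multiplexed). Marker
#' descriptions encode the trial key as `type/block/trial/duration` so the
#' event table round-trips; generic BrainVision readers still see ordinary
#' stimulus markers.
#'
#' @param rec an [eeg_recording()].
#' @param basename path without extension.
#' @return `write_brainvision`: the basename, invisibly.
#'   `read_brainvision`: an [eeg_recording()].
#' @export
write_brainvision <- function(rec, basename) {
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  nm <- basename(basename)
  header <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", nm, ".eeg"),
    paste0("MarkerFile=", nm, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", ncol(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$sfreq, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(rec$ch_names), rec$ch_names)
  )
  writeLines(header, vhdr, useBytes = TRUE)
  ev <- rec$events
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", nm, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0",
    sprintf("Mk%d=Stimulus,%s/%s/%d/%s,%d,1,0",
            seq_len(nrow(ev)) + 1, ev$type, ev$block, ev$trial,
            format_duration(ev$duration_ms), ev$sample)
  )
  writeLines(mk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$data)), con, size = 4, endian = "little")
  invisible(basename)
}

#' @param vhdr_path path to the `.vhdr` header file.
#' @rdname write_brainvision
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, encoding = "UTF-8")
  getval <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)[1]
    sub(paste0("^", key, "="), "", ln)
  }
  n_ch <- as.integer(getval("NumberOfChannels"))
  sfreq <- 1e6 / as.numeric(getval("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[[`, character(1), 1)
  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, getval("DataFile"))
  vmrk_path <- file.path(dir, getval("MarkerFile"))
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  raw <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  close(con)
  data <- matrix(raw, ncol = n_ch, byrow = TRUE)
  mlines <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk_path, encoding = "UTF-8"),
                 value = TRUE)
  parts <- strsplit(sub("^Mk[0-9]+=Stimulus,", "", mlines), ",")
  desc <- strsplit(vapply(parts, `[[`, character(1), 1), "/")
  events <- data.frame(
    sample = as.integer(vapply(parts, `[[`, character(1), 2)),
    type = vapply(desc, `[[`, character(1), 1),
    block = vapply(desc, `[[`, character(1), 2),
    trial = as.integer(vapply(desc, `[[`, character(1), 3)),
    duration_ms = as.numeric(vapply(desc, `[[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
  eeg_recording(data, sfreq, ch_names, events)
}

# --- plain binary + JSON header fallback -----------------------------------

#' Plain-binary recording format (JSON header + float32 payload)
#'
#' Dependency-free fallback format: `<basename>.json` holds the sampling
#' rate, channel labels and event table; `<basename>.dat` holds the
#' samples-by-channels matrix as little-endian IEEE float32, multiplexed.
#'
#' @inheritParams write_brainvision
#' @export
write_eeg_binary <- function(rec, basename) {
  hdr <- list(sfreq = rec$sfreq, ch_names = rec$ch_names,
              n_samples = nrow(rec$data), events = rec$events,
              binary_format = "float32_le_multiplexed")
  jsonlite::write_json(hdr, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(basename, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$data)), con, size = 4, endian = "little")
  invisible(basename)
}

#' @rdname write_eeg_binary
#' @export
read_eeg_binary <- function(basename) {
  hdr <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  con <- file(paste0(basename, ".dat"), "rb")
  raw <- readBin(con, "numeric", n = hdr$n_samples * length(hdr$ch_names),
                 size = 4, endian = "little")
  close(con)
  eeg_recording(matrix(raw, ncol = length(hdr$ch_names), byrow = TRUE),
                hdr$sfreq, hdr$ch_names, as.data.frame(hdr$events))
}
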