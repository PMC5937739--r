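#' Construct a raw hybrid recording
#'
#' Container for synchronized EEG/EOG/NIRS-intensity streams with event
#' markers and montage metadata. Time is seconds from recording start;
#' sample 0 sits at t = 0; event onsets mark the start of the task period.
#'
#' @param eeg Channels x samples matrix (microvolts) with rownames giving
#'   channel names.
#' @param eog 4 x samples matrix (microvolts).
#' @param nirs_intensity 9 x 2 x samples array of positive intensities
#'   (arbitrary units), channels x wavelength x samples.
#' @param events Data frame with columns `onset_s` (numeric) and `label`
#'   (`"MA"` or `"BL"`).
#' @param eeg_rate_hz,nirs_rate_hz Sampling rates, Hz.
#' @param frontal Channel names flagged as frontal analysis channels.
#' @param optode_distance_mm NIRS source-detector separation, millimetres.
#' @param meta Optional named list of provenance fields (seed, generator
#'   settings, ...).
#'
#' @return A `bci_recording` object.
#' @export
bci_recording <- function(eeg, eog, nirs_intensity, events,
                          eeg_rate_hz = 1000, nirs_rate_hz = 12.5,
                          frontal = FRONTAL_CHANNELS,
                          optode_distance_mm = 30,
                          meta = list()) {
  eeg <- as.matrix(eeg)
  assert_that(nrow(eeg) == 0 || !is.null(rownames(eeg)),
              "eeg must carry channel rownames")
  eog <- if (is.null(eog)) matrix(0, 0, ncol(eeg)) else as.matrix(eog)
  events <- as.data.frame(events)
  assert_that(all(c("onset_s", "label") %in% names(events)),
              "events needs onset_s and label columns")
  bad <- setdiff(unique(as.character(events$label)), c("MA", "BL"))
  if (length(bad)) {
    abort(sprintf("unknown event label(s): %s (row %d)",
                  paste(bad, collapse = ", "),
                  which(as.character(events$label) %in% bad)[1]))
  }
  dur <- ncol(eeg) / eeg_rate_hz
  assert_that(all(events$onset_s >= 0 & events$onset_s <= dur),
              "event onsets must lie within the recording")
  if (!is.null(nirs_intensity)) {
    assert_that(length(dim(nirs_intensity)) == 3,
                "nirs_intensity must be channels x wavelength x samples")
    if (any(nirs_intensity <= 0)) {
      bad <- which(nirs_intensity <= 0, arr.ind = TRUE)[1, ]
      abort(sprintf("non-positive NIRS intensity (channel %d, sample %d)",
                    bad[1], bad[3]))
    }
  }
  structure(
    list(
      eeg = eeg, eog = eog, nirs_intensity = nirs_intensity,
      events = tibble::as_tibble(events),
      eeg_rate_hz = eeg_rate_hz, nirs_rate_hz = nirs_rate_hz,
      frontal = intersect(rownames(eeg), frontal),
      optode_distance_mm = optode_distance_mm,
      meta = meta
    ),
    class = "bci_recording"
  )
}

#' @export
print.bci_recording <- function(x, ...) {
  cat("<bci_recording>\n")
  cat(sprintf("  EEG : %d ch x %d samples @ %g Hz (%d frontal)\n",
              nrow(x$eeg), ncol(x$eeg), x$eeg_rate_hz, length(x$frontal)))
  if (!is.null(x$eog)) {
    cat(sprintf("  EOG : %d ch x %d samples\n", nrow(x$eog), ncol(x$eog)))
  }
  if (!is.null(x$nirs_intensity)) {
    d <- dim(x$nirs_intensity)
    cat(sprintf("  NIRS: %d ch x %d wavelengths x %d samples @ %g Hz\n",
                d[1], d[2], d[3], x$nirs_rate_hz))
  }
  cat(sprintf("  events: %d (%s)\n", nrow(x$events),
              paste(sprintf("%s=%d", names(table(x$events$label)),
                            table(x$events$label)), collapse = ", ")))
  invisible(x)
}

#' Epoched single-modality data
#'
#' @param data Trials x channels x samples array.
#' @param window_s `c(start, end)` seconds relative to task onset
#'   (half-open: samples with `start <= t < end`).
#' @param labels Per-trial factor with levels `MA`, `BL`.
#' @param rate_hz Sampling rate of the epoched stream.
#' @param modality One of `"EEG"`, `"HbO"`, `"HbR"`.
#' @param channels Channel names, length = `dim(data)[2]`.
#'
#' @return A `bci_epochs` object.
#' @export
bci_epochs <- function(data, window_s, labels, rate_hz, modality,
                       channels = NULL) {
  assert_that(length(dim(data)) == 3, "data must be trials x channels x samples")
  labels <- factor(as.character(labels), levels = c("MA", "BL"))
  assert_that(dim(data)[1] == length(labels),
              "labels length must match trial count")
  structure(
    list(data = data, window_s = as.numeric(window_s), labels = labels,
         rate_hz = rate_hz, modality = modality,
         channels = channels %||% sprintf("ch%d", seq_len(dim(data)[2]))),
    class = "bci_epochs"
  )
}

#' @export
print.bci_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bci_epochs %s> %d trials x %d ch x %d samples, [%g, %g) s @ %g Hz\n",
              x$modality, d[1], d[2], d[3], x$window_s[1], x$window_s[2],
              x$rate_hz))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

# subset trials of an epoch set
epochs_subset <- function(ep, idx) {
  bci_epochs(ep$data[idx, , , drop = FALSE], ep$window_s, ep$labels[idx],
             ep$rate_hz, ep$modality, ep$channels)
}
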