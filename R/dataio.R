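#' Write a recording to the native dataset layout
#'
#' One directory per recording: numeric payloads as little-endian float64
#' binary (`eeg.bin`, `eog.bin`, `nirs.bin`), a plain-text JSON metadata
#' descriptor (`meta.json`: version, rates, dimensions, channel names,
#' montage, units, provenance), a TSV events table (`onset_s`, `label`),
#' and a `manifest.json` listing every file with its MD5 checksum. The
#' layout round-trips bit-exactly through [read_dataset()].
#'
#' @param rec A [bci_recording].
#' @param path Target directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#'
#' @return Invisibly, the manifest as a named character vector of checksums.
#' @export
write_dataset <- function(rec, path, overwrite = FALSE) {
  if (dir.exists(path) && length(dir(path)) > 0 && !overwrite) {
    abort(sprintf("directory '%s' exists and is not empty (set overwrite = TRUE)",
                  path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  write_f64 <- function(x, file) {
    con <- file(file.path(path, file), "wb")
    on.exit(close(con))
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  }
  write_f64(rec$eeg, "eeg.bin")
  write_f64(rec$eog, "eog.bin")
  write_f64(rec$nirs_intensity, "nirs.bin")
  utils::write.table(rec$events, file.path(path, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(
    version = 1L,
    eeg_rate_hz = rec$eeg_rate_hz, nirs_rate_hz = rec$nirs_rate_hz,
    eeg_channels = rownames(rec$eeg),
    eog_channels = rownames(rec$eog) %||% EOG_CHANNELS,
    frontal = rec$frontal,
    eeg_dim = dim(rec$eeg), eog_dim = dim(rec$eog),
    nirs_dim = dim(rec$nirs_intensity),
    optode_distance_mm = rec$optode_distance_mm,
    units = list(eeg = "uV", eog = "uV", nirs = "a.u."),
    provenance = rec$meta
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  payload <- c("eeg.bin", "eog.bin", "nirs.bin", "events.tsv", "meta.json")
  sums <- tools::md5sum(file.path(path, payload))
  names(sums) <- payload
  jsonlite::write_json(as.list(sums), file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(sums)
}

#' Read a recording from the native dataset layout
#'
#' Loads and validates a directory written by [write_dataset()]: the
#' metadata descriptor must be present, sample counts must match the
#' declared dimensions and rates, intensities must be positive and event
#' labels known; violations raise structured errors naming the offending
#' file, channel or line.
#'
#' @param path Dataset directory.
#'
#' @return A [bci_recording].
#' @export
read_dataset <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    abort(sprintf("corrupt dataset: missing metadata descriptor '%s'",
                  meta_file))
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  assert_that(!is.null(meta$version), "corrupt dataset: no version field")

  read_f64 <- function(file, n) {
    f <- file.path(path, file)
    if (!file.exists(f)) abort(sprintf("corrupt dataset: missing '%s'", file))
    con <- file(f, "rb")
    on.exit(close(con))
    x <- readBin(con, "double", n = n + 1, size = 8, endian = "little")
    if (length(x) != n) {
      abort(sprintf("corrupt dataset: '%s' has %d values, expected %d",
                    file, length(x), n))
    }
    x
  }
  eeg <- matrix(read_f64("eeg.bin", prod(meta$eeg_dim)),
                meta$eeg_dim[1], meta$eeg_dim[2],
                dimnames = list(meta$eeg_channels, NULL))
  eog <- matrix(read_f64("eog.bin", prod(meta$eog_dim)),
                meta$eog_dim[1], meta$eog_dim[2],
                dimnames = list(meta$eog_channels, NULL))
  nirs <- array(read_f64("nirs.bin", prod(meta$nirs_dim)), meta$nirs_dim)

  # declared rates must agree with the sample counts (same duration)
  dur_e <- meta$eeg_dim[2] / meta$eeg_rate_hz
  dur_n <- meta$nirs_dim[3] / meta$nirs_rate_hz
  if (abs(dur_e - dur_n) > 2 / meta$nirs_rate_hz) {
    abort(sprintf(
      "rate mismatch: EEG implies %.2f s but NIRS implies %.2f s", dur_e, dur_n))
  }
  if (any(nirs <= 0)) {
    bad <- which(nirs <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("invalid dataset: non-positive intensity at channel %d, sample %d",
                  bad[1], bad[3]))
  }

  ev_file <- file.path(path, "events.tsv")
  events <- utils::read.delim(ev_file, sep = "\t", colClasses =
                                c(onset_s = "numeric", label = "character"))
  bad <- which(!events$label %in% c("MA", "BL"))
  if (length(bad)) {
    abort(sprintf("unknown event label '%s' in %s line %d",
                  events$label[bad[1]], ev_file, bad[1] + 1L))
  }

  bci_recording(
    eeg = eeg, eog = eog, nirs_intensity = nirs, events = events,
    eeg_rate_hz = meta$eeg_rate_hz, nirs_rate_hz = meta$nirs_rate_hz,
    frontal = meta$frontal,
    optode_distance_mm = meta$optode_distance_mm,
    meta = as.list(meta$provenance)
  )
}
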