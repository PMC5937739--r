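#' Import a standard-format recording
#'
#' Reads EEG from EDF or BrainVision files, or NIRS intensities from SNIRF,
#' into a [bci_recording]. Channel names are matched case-insensitively
#' onto the frontal montage; matched channels are flagged frontal, unmapped
#' channels are retained but unflagged, and a warning lists missing frontal
#' channels. SNIRF files must carry two wavelengths per source-detector
#' pair.
#'
#' @param path File path (`.edf`, `.vhdr`, or `.snirf`).
#' @param kind `"EDF"`, `"BrainVision"`, or `"SNIRF"` (default guessed from
#'   the extension).
#'
#' @return A [bci_recording]; EEG-only imports carry no NIRS block and vice
#'   versa.
#' @export
import_standard <- function(path, kind = NULL) {
  kind <- kind %||% switch(tolower(tools::file_ext(path)),
                           edf = "EDF", vhdr = "BrainVision",
                           snirf = "SNIRF",
                           abort("cannot guess format; pass `kind`"))
  switch(kind,
         EDF = import_edf(path),
         BrainVision = import_brainvision(path),
         SNIRF = import_snirf(path),
         abort(sprintf("unknown import kind '%s'", kind)))
}

# flag frontal channels by case-insensitive name match; warn about gaps
assemble_eeg_recording <- function(data, channels, rate_hz, events = NULL) {
  match_idx <- match(tolower(channels), tolower(FRONTAL_CHANNELS))
  mapped <- !is.na(match_idx)
  channels[mapped] <- FRONTAL_CHANNELS[match_idx[mapped]]
  if (!any(mapped)) abort("no frontal channels found in file")
  missing <- setdiff(FRONTAL_CHANNELS, channels[mapped])
  if (length(missing)) {
    warn(sprintf("frontal channels absent from file: %s",
                 paste(missing, collapse = ", ")))
  }
  rownames(data) <- channels
  events <- events %||% data.frame(onset_s = numeric(0), label = character(0))
  bci_recording(
    eeg = data, eog = matrix(0, 0, ncol(data)), nirs_intensity = NULL,
    events = events, eeg_rate_hz = rate_hz,
    meta = list(source = "import")
  )
}

# --- EDF ---------------------------------------------------------------------

import_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd_num <- function(n) as.numeric(rd_str(n))
  rd_str(8) # version
  rd_str(80); rd_str(80); rd_str(8); rd_str(8) # ids, date, time
  rd_num(8) # header bytes
  rd_str(44)
  n_rec <- rd_num(8)
  rec_dur <- rd_num(8)
  ns <- as.integer(rd_num(4))
  assert_that(!is.na(ns) && ns >= 1, "not a valid EDF header")
  field <- function(width) vapply(seq_len(ns), function(i) rd_str(width), "")
  labels <- field(16)
  field(80) # transducer
  field(8)  # physical dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80) # prefiltering
  spr <- as.integer(field(8))
  field(32)
  assert_that(length(unique(spr)) == 1,
              "mixed per-signal rates are not supported")
  n_samp <- n_rec * spr[1]
  data <- matrix(NA_real_, ns, n_samp)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2,
                     endian = "little", signed = TRUE)
      scale <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      data[s, (r - 1) * spr[s] + seq_len(spr[s])] <-
        (raw - dig_min[s]) * scale + phys_min[s]
    }
  }
  assemble_eeg_recording(data, labels, spr[1] / rec_dur)
}

# --- BrainVision -------------------------------------------------------------

import_brainvision <- function(path) {
  hdr <- readLines(path, warn = FALSE)
  get_key <- function(key) {
    ln <- grep(sprintf("^%s=", key), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(sprintf("^%s=", key), "", ln[1])
  }
  data_file <- file.path(dirname(path), get_key("DataFile"))
  if (!file.exists(data_file)) {
    abort(sprintf("BrainVision data file '%s' not found", data_file))
  }
  n_ch <- as.integer(get_key("NumberOfChannels"))
  samp_int_us <- as.numeric(get_key("SamplingInterval"))
  rate <- 1e6 / samp_int_us
  fmt <- get_key("BinaryFormat") %||% "IEEE_FLOAT_32"
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  ch_info <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_info, `[`, "", 1)
  res <- vapply(ch_info, function(x) {
    r <- suppressWarnings(as.numeric(x[3])); if (is.na(r)) 1 else r
  }, numeric(1))
  sz <- file.size(data_file)
  con <- file(data_file, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    n_val <- sz / 4
    vals <- readBin(con, "double", n = n_val, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    n_val <- sz / 2
    vals <- readBin(con, "integer", n = n_val, size = 2, endian = "little",
                    signed = TRUE)
  } else {
    abort(sprintf("unsupported BinaryFormat '%s'", fmt))
  }
  data <- matrix(vals, n_ch, length(vals) / n_ch) * res # multiplexed
  events <- NULL
  mk <- get_key("MarkerFile")
  if (!is.null(mk) && file.exists(file.path(dirname(path), mk))) {
    ml <- readLines(file.path(dirname(path), mk), warn = FALSE)
    ml <- grep("^Mk[0-9]+=", ml, value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
    desc <- trimws(vapply(parts, `[`, "", 2))
    pos <- as.numeric(vapply(parts, `[`, "", 3))
    keep <- desc %in% c("MA", "BL")
    if (any(keep)) {
      events <- data.frame(onset_s = (pos[keep] - 1) / rate,
                           label = desc[keep])
    }
  }
  assemble_eeg_recording(data, labels, rate, events)
}

# --- SNIRF (HDF5, via the bundled python bridge) -----------------------------

import_snirf <- function(path) {
  bridge <- system.file("python", "snirf_to_json.py", package = "hybridbci",
                        mustWork = TRUE)
  out <- suppressWarnings(
    system2("python", c(shQuote(bridge), shQuote(path)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0
  parsed <- tryCatch(jsonlite::fromJSON(paste(out, collapse = "\n"),
                                        simplifyVector = TRUE),
                     error = function(e) NULL)
  if (status != 0 || is.null(parsed)) {
    abort(sprintf("SNIRF import failed: %s", paste(out, collapse = " ")))
  }
  if (!is.null(parsed$error)) abort(sprintf("SNIRF import: %s", parsed$error))
  n_wl <- length(parsed$wavelengths)
  if (n_wl != 2) {
    abort(sprintf("SNIRF file carries %d wavelength(s); need exactly 2", n_wl))
  }
  # the bridge flattens channels x wavelengths x samples in Fortran order
  arr <- array(parsed$data_flat,
               dim = c(parsed$n_channels, n_wl, parsed$n_samples))
  rate <- 1 / parsed$time_step
  n_samp <- dim(arr)[3]
  bci_recording(
    eeg = matrix(0, 0, ceiling(n_samp / rate * 1000)),
    eog = NULL, nirs_intensity = arr,
    events = data.frame(onset_s = numeric(0), label = character(0)),
    eeg_rate_hz = 1000, nirs_rate_hz = rate,
    meta = list(source = "snirf", wavelengths = parsed$wavelengths)
  )
}
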