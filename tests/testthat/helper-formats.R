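# Minimal writers for the standard formats, used only to build import
# fixtures in code at test time.

pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")

write_minimal_edf <- function(path, channels, data, rate) {
  # one data record per second, int16 little-endian
  stopifnot(ncol(data) %% rate == 0)
  n_rec <- ncol(data) / rate
  ns <- length(channels)
  phys_min <- -200; phys_max <- 200
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeBin(charToRaw(pad(s, n)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(n_rec, 8); wr(1, 8); wr(ns, 4)
  for (ch in channels) wr(ch, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(phys_min, 8)
  for (i in seq_len(ns)) wr(phys_max, 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(rate, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- data[s, (r - 1) * rate + seq_len(rate)]
      dig <- as.integer(round((seg - phys_min) * scale + dig_min))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

write_brainvision <- function(prefix, channels, data, rate,
                              markers = NULL, data_file_exists = TRUE) {
  vhdr <- paste0(prefix, ".vhdr")
  eegf <- paste0(prefix, ".eeg")
  vmrk <- paste0(prefix, ".vmrk")
  lines <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s", basename(eegf)),
    sprintf("MarkerFile=%s", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", length(channels)),
    sprintf("SamplingInterval=%d", as.integer(1e6 / rate)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_along(channels), channels)
  )
  writeLines(lines, vhdr)
  if (data_file_exists) {
    con <- file(eegf, "wb")
    writeBin(as.numeric(data), con, size = 4, endian = "little")
    close(con)
  }
  mk <- c("[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (!is.null(markers)) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(markers)) + 1,
                        markers$label, markers$position))
  }
  writeLines(mk, vmrk)
  invisible(vhdr)
}

write_snirf <- function(path, n_channels = 9, n_wavelengths = 2,
                        n_samples = 50, rate = 12.5) {
  script <- sprintf('
import h5py, numpy as np
np.random.seed(0)
n_ch, n_wl, n_s = %d, %d, %d
with h5py.File(r"%s", "w") as f:
    nirs = f.create_group("nirs")
    probe = nirs.create_group("probe")
    probe["wavelengths"] = np.array([760.0, 850.0][:n_wl])
    data = nirs.create_group("data1")
    ts = np.abs(np.random.rand(n_s, n_ch * n_wl)) + 0.5
    data["dataTimeSeries"] = ts
    data["time"] = np.arange(n_s) / %f
    k = 1
    for ch in range(n_ch):
        for wl in range(n_wl):
            ml = data.create_group("measurementList%%d" %% k)
            ml["sourceIndex"] = ch + 1
            ml["detectorIndex"] = ch + 1
            ml["wavelengthIndex"] = wl + 1
            k += 1
', n_channels, n_wavelengths, n_samples, path, rate)
  tmp <- tempfile(fileext = ".py")
  writeLines(script, tmp)
  status <- system2("python", shQuote(tmp), stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0) {
    stop("failed to write SNIRF fixture: ", paste(status, collapse = " "))
  }
  invisible(path)
}
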