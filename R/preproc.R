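#' Downsample EEG with anti-alias filtering
#'
#' Decimates each channel by an integer factor after an 8th-order zero-phase
#' Butterworth low-pass at 80% of the new Nyquist frequency (so 1000 Hz
#' recordings decimated by 5 are low-passed at 80 Hz before keeping every
#' 5th sample).
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param rate_hz Input sampling rate.
#' @param factor Integer decimation factor (default 5: 1000 to 200 Hz).
#'
#' @return List with `data` (same shape, samples reduced to
#'   `ceiling(n/factor)`) and `rate_hz` (new rate).
#' @export
downsample_eeg <- function(x, rate_hz, factor = 5L) {
  assert_that(factor >= 1, "factor must be >= 1")
  x <- rbind(x)
  if (factor == 1L) return(list(data = x, rate_hz = rate_hz))
  new_rate <- rate_hz / factor
  b <- signal::butter(8, 0.8 * (new_rate / 2) / (rate_hz / 2), type = "low")
  keep <- seq(1, ncol(x), by = factor)
  out <- matrix(NA_real_, nrow(x), length(keep), dimnames = list(rownames(x), NULL))
  for (ch in seq_len(nrow(x))) {
    # demean to avoid edge transients from the zero-padded forward-backward
    # pass; the mean is in the passband and is restored unchanged
    m <- mean(x[ch, ])
    out[ch, ] <- signal::filtfilt(b, x[ch, ] - m)[keep] + m
  }
  list(data = out, rate_hz = new_rate)
}

#' Zero-phase Butterworth band-pass
#'
#' Applies the band-pass of a [filter_spec()] to each channel. The band-pass
#' is realized as a cascade of a high-pass at the low edge and a low-pass at
#' the high edge, each of the specified order; a single polynomial band-pass
#' of high order at very low normalized cutoffs (the 0.01--0.2 Hz
#' hemodynamic band at 12.5 Hz) is numerically unstable, the cascade is not.
#' With `zero_phase` the filter runs forward and backward (no group delay,
#' doubled effective order).
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param spec [filter_spec()].
#' @param rate_hz Sampling rate of `x`.
#'
#' @return Filtered data, same shape as `x`.
#' @export
bandpass <- function(x, spec, rate_hz) {
  nyq <- rate_hz / 2
  assert_that(spec$passband_hz[2] < nyq,
              "passband upper edge must be below Nyquist")
  hp <- signal::butter(spec$order, spec$passband_hz[1] / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$passband_hz[2] / nyq, type = "low")
  apply_1d <- function(v) {
    if (spec$zero_phase) {
      signal::filtfilt(lp, signal::filtfilt(hp, v))
    } else {
      as.numeric(signal::filter(lp, signal::filter(hp, v)))
    }
  }
  if (is.matrix(x)) {
    out <- x
    for (ch in seq_len(nrow(x))) out[ch, ] <- apply_1d(x[ch, ])
    out
  } else {
    apply_1d(x)
  }
}

#' Remove ocular artifacts from EEG
#'
#' Blind-source-separation based cleaning: a second-order statistics
#' decomposition (joint diagonalization of time-lagged covariances, SOBI
#' style) is computed on the EEG and EOG channels jointly; components whose
#' absolute correlation with any EOG channel exceeds `threshold` are zeroed
#' before back-projection. A multiple-regression-on-EOG fallback
#' (`method = "regression"`) is also provided.
#'
#' @param eeg Channels x samples matrix.
#' @param eog 4 x samples matrix, time-aligned with `eeg` at the same rate.
#' @param method `"sobi"` (default) or `"regression"`.
#' @param threshold Absolute component-EOG correlation above which a source
#'   is treated as ocular.
#' @param lags_s Covariance lags used by the joint diagonalization, seconds.
#' @param rate_hz Sampling rate (needed to realize `lags_s`).
#'
#' @return Cleaned EEG matrix, same shape as `eeg`.
#' @export
remove_eog <- function(eeg, eog, method = c("sobi", "regression"),
                       threshold = 0.7, lags_s = NULL, rate_hz = 200) {
  method <- match.arg(method)
  eeg <- rbind(eeg); eog <- rbind(eog)
  assert_that(ncol(eeg) == ncol(eog), "eeg and eog must be time-aligned")
  assert_that(ncol(eeg) > nrow(eeg) + nrow(eog),
              "need more samples than channels")
  if (all(abs(eog) < .Machine$double.eps)) return(eeg)

  if (method == "regression") {
    # project EOG (and unit offset) out of each EEG channel
    X <- t(rbind(1, eog))
    beta <- solve(crossprod(X), crossprod(X, t(eeg)))
    return(eeg - t(X %*% beta))
  }

  lags_s <- lags_s %||% c(seq(1, 10) / rate_hz, seq(0.075, 0.5, by = 0.025))
  lags <- unique(pmax(1L, round(lags_s * rate_hz)))
  joint <- rbind(eeg, eog)
  dec <- sobi_decompose(joint, lags)
  sources <- dec$unmixing %*% (joint - rowMeans(joint))
  # identify ocular components by correlation with the EOG channels
  cors <- abs(cor(t(sources), t(eog)))
  bad <- apply(cors, 1, max) > threshold
  mixing <- dec$mixing
  mixing[, bad] <- 0
  cleaned_joint <- mixing %*% sources
  cleaned <- cleaned_joint[seq_len(nrow(eeg)), , drop = FALSE] +
    rowMeans(eeg)
  dimnames(cleaned) <- dimnames(eeg)
  cleaned
}

# SOBI: whiten, then jointly diagonalize lagged covariance matrices.
# Returns unmixing (sources = unmixing %*% centered data) and mixing
# (its pseudo-inverse).
sobi_decompose <- function(x, lags) {
  xc <- x - rowMeans(x)
  n <- ncol(xc)
  C0 <- tcrossprod(xc) / n
  e0 <- eigen(C0, symmetric = TRUE)
  keep <- e0$values > max(e0$values) * 1e-10
  W <- diag(1 / sqrt(e0$values[keep]), sum(keep)) %*% t(e0$vectors[, keep])
  z <- W %*% xc
  mats <- lapply(lags, function(l) {
    M <- z[, 1:(n - l), drop = FALSE] %*% t(z[, (1 + l):n, drop = FALSE]) / (n - l)
    (M + t(M)) / 2
  })
  V <- joint_diagonalize(mats)
  unmix <- t(V) %*% W
  mixing <- pseudo_inverse(unmix)
  list(unmixing = unmix, mixing = mixing)
}

# Jacobi-rotation joint approximate diagonalization of symmetric matrices
# (Cardoso & Souloumiac). Returns orthogonal V maximizing the sum of
# squared diagonals of t(V) %*% M %*% V.
joint_diagonalize <- function(mats, tol = 1e-9, max_sweeps = 100) {
  d <- nrow(mats[[1]])
  V <- diag(d)
  A <- mats
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(d - 1)) {
      for (j in (i + 1):d) {
        g11 <- 0; g12 <- 0; g22 <- 0
        for (M in A) {
          h1 <- M[i, i] - M[j, j]
          h2 <- 2 * M[i, j]
          g11 <- g11 + h1 * h1
          g12 <- g12 + h1 * h2
          g22 <- g22 + h2 * h2
        }
        # rotation angle from the principal eigenvector of the 2x2 Gram
        # matrix of (h1, h2) pairs (reduces to the classical Jacobi angle
        # for a single matrix)
        theta <- 0.25 * atan2(2 * g12, g11 - g22)
        cs <- cos(theta); sn <- sin(theta)
        if (abs(sn) > tol) {
          changed <- TRUE
          for (k in seq_along(A)) {
            M <- A[[k]]
            rot_i <- cs * M[i, ] + sn * M[j, ]
            rot_j <- -sn * M[i, ] + cs * M[j, ]
            M[i, ] <- rot_i; M[j, ] <- rot_j
            col_i <- cs * M[, i] + sn * M[, j]
            col_j <- -sn * M[, i] + cs * M[, j]
            M[, i] <- col_i; M[, j] <- col_j
            A[[k]] <- M
          }
          vi <- cs * V[, i] + sn * V[, j]
          vj <- -sn * V[, i] + cs * V[, j]
          V[, i] <- vi; V[, j] <- vj
        }
      }
    }
    if (!changed) break
  }
  V
}

# Moore-Penrose pseudo-inverse via SVD
pseudo_inverse <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Cut trials around task onsets
#'
#' Extracts `window_s = c(start, end)` seconds relative to each event onset
#' using the half-open sample-time convention: samples whose time `t`
#' (0-based, `t = k / rate`) satisfies `onset + start <= t < onset + end`.
#' Trials are ordered by onset; labels ride along.
#'
#' @param x Channels x samples matrix (one modality).
#' @param events Data frame with `onset_s` and `label`.
#' @param window_s `c(start, end)` seconds relative to onset.
#' @param rate_hz Sampling rate of `x`.
#' @param modality Tag stored on the result (`"EEG"`, `"HbO"`, `"HbR"`).
#'
#' @return A [bci_epochs] object (possibly with zero trials).
#' @export
epoch <- function(x, events, window_s, rate_hz, modality = "EEG") {
  x <- rbind(x)
  events <- events[order(events$onset_s), , drop = FALSE]
  n_samp_rec <- ncol(x)
  # half-open window: first sample k with k/rate >= onset+start,
  # last with k/rate < onset+end
  first <- ceiling((events$onset_s + window_s[1]) * rate_hz - 1e-9)
  last <- ceiling((events$onset_s + window_s[2]) * rate_hz - 1e-9) - 1
  n_len <- 0L
  if (nrow(events) > 0) {
    if (any(first < 0) || any(last >= n_samp_rec)) {
      abort(sprintf("epoch window [%g, %g) exceeds recording bounds for trial %d",
                    window_s[1], window_s[2],
                    which(first < 0 | last >= n_samp_rec)[1]))
    }
    # when the window length is not an integer number of samples the
    # half-open count depends on onset phase; truncate to the common minimum
    n_len <- min(last - first + 1)
  }
  dat <- array(NA_real_, c(nrow(events), nrow(x), max(n_len, 0)))
  for (i in seq_len(nrow(events))) {
    dat[i, , ] <- x[, first[i] + seq_len(n_len), drop = FALSE]
  }
  bci_epochs(dat, window_s, events$label, rate_hz, modality,
             channels = rownames(x))
}

#' Preprocess a raw recording into analysis-ready epochs
#'
#' Applies the full preprocessing chain in the canonical order: EEG is
#' decimated (1000 to 200 Hz), band-pass filtered 0.5--50 Hz (3rd-order
#' zero-phase Butterworth), and cleaned of ocular artifacts by
#' blind source separation; NIRS intensities are converted by the modified
#' Beer-Lambert law and the concentration series band-pass filtered
#' 0.01--0.2 Hz (6th-order zero-phase Butterworth). EEG epochs cover the
#' task period (0--10 s), hemodynamic epochs its late phase (10--15 s).
#'
#' @param recording A [bci_recording].
#' @param eeg_downsample_factor Integer decimation factor.
#' @param eeg_band,nirs_band [filter_spec()] for the two streams.
#' @param eog_method Passed to [remove_eog()].
#' @param mbll [mbll_params()].
#' @param eeg_window_s,nirs_window_s Analysis windows, seconds from task
#'   onset.
#'
#' @return List of [bci_epochs]: `eeg`, `hbo`, `hbr`, plus `eeg_rate_hz`.
#' @export
preprocess_recording <- function(recording,
                                 eeg_downsample_factor = 5L,
                                 eeg_band = filter_spec(c(0.5, 50), order = 3),
                                 nirs_band = filter_spec(c(0.01, 0.2), order = 6),
                                 eog_method = "sobi",
                                 mbll = mbll_params(),
                                 eeg_window_s = c(0, 10),
                                 nirs_window_s = c(10, 15)) {
  frontal <- recording$frontal
  eeg <- recording$eeg[frontal, , drop = FALSE]
  ds <- downsample_eeg(eeg, recording$eeg_rate_hz, eeg_downsample_factor)
  eeg_f <- bandpass(ds$data, eeg_band, ds$rate_hz)
  eog_ds <- downsample_eeg(recording$eog, recording$eeg_rate_hz,
                           eeg_downsample_factor)$data
  eog_f <- bandpass(eog_ds, eeg_band, ds$rate_hz)
  eeg_clean <- remove_eog(eeg_f, eog_f, method = eog_method,
                          rate_hz = ds$rate_hz)

  conc <- mbll(recording$nirs_intensity, mbll, rate_hz = recording$nirs_rate_hz)
  hbo_f <- bandpass(conc$hbo, nirs_band, recording$nirs_rate_hz)
  hbr_f <- bandpass(conc$hbr, nirs_band, recording$nirs_rate_hz)
  rownames(hbo_f) <- rownames(hbr_f) <- sprintf("nirs%d", seq_len(nrow(hbo_f)))

  list(
    eeg = epoch(eeg_clean, recording$events, eeg_window_s, ds$rate_hz, "EEG"),
    hbo = epoch(hbo_f, recording$events, nirs_window_s,
                recording$nirs_rate_hz, "HbO"),
    hbr = epoch(hbr_f, recording$events, nirs_window_s,
                recording$nirs_rate_hz, "HbR"),
    eeg_rate_hz = ds$rate_hz
  )
}
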