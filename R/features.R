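#' Signed squared point-biserial correlation
#'
#' Discriminability of a per-trial scalar between the two classes:
#' `sign(r) * r^2` with `r` the point-biserial correlation between the
#' values and an MA = 1 / BL = 0 class coding. Positive values mean larger
#' in MA.
#'
#' @param values Per-trial numeric vector.
#' @param labels Per-trial labels (`MA`/`BL`), any coercible type.
#'
#' @return Scalar in \[-1, 1\].
#' @export
#' @examples
#' signed_r_squared(c(1, 1, 0, 0), c("MA", "MA", "BL", "BL")) # +1
signed_r_squared <- function(values, labels) {
  labels <- as.character(labels)
  assert_that(all(labels %in% c("MA", "BL")), "labels must be MA or BL")
  assert_that(length(unique(labels)) == 2, "both classes must be present")
  assert_that(sd(values) > 0, "values have zero variance")
  r <- cor(values, as.numeric(labels == "MA"))
  sign(r) * r^2
}

# Welch power spectral density, Hann window. Returns power on a grid with
# resolution_hz spacing (zero-padded FFT). x: vector.
welch_psd <- function(x, rate_hz, window_s = 1, overlap = 0.5,
                      resolution_hz = 0.5) {
  n_win <- round(window_s * rate_hz)
  n_fft <- max(n_win, round(rate_hz / resolution_hz))
  step <- max(1L, round(n_win * (1 - overlap)))
  starts <- seq(1, length(x) - n_win + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_win) / (n_win + 1))
  acc <- numeric(n_fft)
  for (s in starts) {
    seg <- x[s:(s + n_win - 1)] * w
    X <- fft(c(seg, numeric(n_fft - n_win)))
    acc <- acc + Mod(X)^2
  }
  p <- acc / (length(starts) * sum(w^2) * rate_hz)
  n_keep <- floor(n_fft / 2) + 1
  list(freq = (seq_len(n_keep) - 1) * rate_hz / n_fft,
       power = p[seq_len(n_keep)])
}

# per-trial, per-channel, per-bin log band power of an epoch set
# returns list(freq, power[trial, channel, bin])
epochs_psd <- function(epochs, resolution_hz = 0.5, window_s = 1) {
  d <- dim(epochs$data)
  ref <- welch_psd(epochs$data[1, 1, ], epochs$rate_hz,
                   window_s = window_s, resolution_hz = resolution_hz)
  p <- array(NA_real_, c(d[1], d[2], length(ref$freq)))
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      p[i, ch, ] <- welch_psd(epochs$data[i, ch, ], epochs$rate_hz,
                              window_s = window_s,
                              resolution_hz = resolution_hz)$power
    }
  }
  list(freq = ref$freq, power = p)
}

#' Heuristic participant-specific passband selection
#'
#' Selects the discriminative EEG passband from training epochs: per-bin log
#' band power (Welch, 1 s Hann windows, 50% overlap, 0.5 Hz grid) is scored
#' by signed r-squared averaged over channels; the band seeds at the bin of
#' extremal absolute score and grows outward while the adjacent bin keeps at
#' least `grow_frac` of the running (signed) score sum. Falls back to the
#' full `search_range_hz` when no bin reaches `min_score`. Deterministic.
#'
#' @param epochs Training [bci_epochs] (EEG, typically 200 Hz).
#' @param search_range_hz Band search limits, Hz.
#' @param resolution_hz Frequency grid step, Hz.
#' @param grow_frac Growth threshold as fraction of the running score sum.
#' @param min_score Minimum seed `|sgn r^2|` below which the fallback band
#'   is returned. The default `NULL` uses an approximate 5% family-wise
#'   null bound, `qnorm(1 - 0.025/n_bins) * sqrt(3) / ((n-1) * sqrt(c))`
#'   for `n` trials and `c` channels (the null sd of a signed r-squared is
#'   `sqrt(3)/(n-1)`), so chance-level data falls back to the full range.
#' @param psd Optional precomputed [epochs_psd()] result (internal reuse).
#'
#' @return List `band_spec` with `f_low`, `f_high` (snapped to the grid) and
#'   the per-bin `scores` tibble.
#' @export
select_band <- function(epochs, search_range_hz = c(4, 35),
                        resolution_hz = 0.5, grow_frac = 0.05,
                        min_score = NULL, psd = NULL) {
  assert_that(search_range_hz[1] < search_range_hz[2],
              "empty search range")
  labels <- epochs$labels
  assert_that(min(table(labels)) >= 4, "need at least 4 trials per class")
  psd <- psd %||% epochs_psd(epochs, resolution_hz = resolution_hz)
  bins <- which(psd$freq >= search_range_hz[1] &
                  psd$freq <= search_range_hz[2])
  freqs <- psd$freq[bins]
  n_ch <- dim(psd$power)[2]
  score <- vapply(seq_along(bins), function(b) {
    mean(vapply(seq_len(n_ch), function(ch) {
      signed_r_squared(log(psd$power[, ch, bins[b]] + 1e-30), labels)
    }, numeric(1)))
  }, numeric(1))

  n_tr <- length(labels)
  min_score <- min_score %||%
    (qnorm(1 - 0.025 / length(bins)) * sqrt(3) / ((n_tr - 1) * sqrt(n_ch)))
  seed <- which.max(abs(score))
  out <- if (abs(score[seed]) < min_score) {
    search_range_hz
  } else {
    s <- sign(score[seed])
    lo <- seed; hi <- seed
    running <- s * score[seed]
    repeat {
      cand_lo <- if (lo > 1) s * score[lo - 1] else -Inf
      cand_hi <- if (hi < length(score)) s * score[hi + 1] else -Inf
      thr <- grow_frac * running
      if (max(cand_lo, cand_hi) < thr || max(cand_lo, cand_hi) <= 0) break
      if (cand_lo >= cand_hi) {
        lo <- lo - 1; running <- running + cand_lo
      } else {
        hi <- hi + 1; running <- running + cand_hi
      }
    }
    c(freqs[lo], freqs[hi])
  }
  # a zero-width band cannot be filtered; widen to one grid step
  if (out[1] == out[2]) {
    out <- c(max(search_range_hz[1], out[1] - resolution_hz / 2),
             min(search_range_hz[2], out[2] + resolution_hz / 2))
  }
  list(f_low = out[1], f_high = out[2],
       scores = tibble::tibble(freq_hz = freqs, sgn_r2 = score))
}

#' Band-wise signed r-squared channel map
#'
#' Per channel and canonical frequency band, the signed r-squared of log
#' band power between MA and BL trials. Bands default to theta (4--8 Hz),
#' alpha (8--13), low beta (13--20), high beta (20--30) and gamma
#' (30--50 Hz).
#'
#' @param epochs EEG [bci_epochs].
#' @param bands Named list of `c(low, high)` band edges, Hz.
#'
#' @return Tibble `channel` x `band` x `sgn_r2` (class `bci_disc_map`), one
#'   row per channel-band pair.
#' @export
sgn_r2_band_map <- function(epochs,
                            bands = list(theta = c(4, 8), alpha = c(8, 13),
                                         low_beta = c(13, 20),
                                         high_beta = c(20, 30),
                                         gamma = c(30, 50))) {
  nyq <- epochs$rate_hz / 2
  assert_that(all(vapply(bands, max, numeric(1)) < nyq),
              "band outside Nyquist range")
  psd <- epochs_psd(epochs)
  d <- dim(psd$power)
  rows <- purrr::map_dfr(names(bands), function(bn) {
    bi <- which(psd$freq >= bands[[bn]][1] & psd$freq < bands[[bn]][2])
    tibble::tibble(
      channel = epochs$channels,
      band = bn,
      sgn_r2 = vapply(seq_len(d[2]), function(ch) {
        bp <- apply(psd$power[, ch, bi, drop = FALSE], 1, sum)
        signed_r_squared(log(bp + 1e-30), epochs$labels)
      }, numeric(1))
    )
  })
  rows$band <- factor(rows$band, levels = names(bands))
  class(rows) <- c("bci_disc_map", class(rows))
  rows
}

#' Hemodynamic mean and slope features
#'
#' Per channel of a concentration epoch set: the arithmetic mean over the
#' analysis window and the least-squares linear-fit slope (per second). For
#' the 9-channel montage this yields 18 features per chromophore.
#'
#' @param epochs [bci_epochs] of one chromophore cut on the hemodynamic
#'   window (10--15 s by default upstream).
#'
#' @return A feature tibble (class `bci_features`): one row per trial,
#'   columns `<channel>_<chromophore>_mean` / `_slope`, plus `label`.
#' @export
nirs_mean_slope <- function(epochs) {
  d <- dim(epochs$data)
  assert_that(d[3] >= 3, "need at least 3 samples in the window")
  t <- (seq_len(d[3]) - 1) / epochs$rate_hz
  tc <- t - mean(t)
  denom <- sum(tc^2)
  tag <- tolower(epochs$modality)
  vals <- matrix(NA_real_, d[1], 2 * d[2])
  nm <- character(2 * d[2])
  for (ch in seq_len(d[2])) {
    seg <- epochs$data[, ch, , drop = TRUE]
    seg <- matrix(seg, nrow = d[1])
    m <- rowMeans(seg)
    slope <- as.numeric((seg - m) %*% tc) / denom
    vals[, 2 * ch - 1] <- m
    vals[, 2 * ch] <- slope
    nm[2 * ch - 1] <- sprintf("%s_%s_mean", epochs$channels[ch], tag)
    nm[2 * ch] <- sprintf("%s_%s_slope", epochs$channels[ch], tag)
  }
  colnames(vals) <- nm
  out <- tibble::as_tibble(vals)
  out$label <- epochs$labels
  attr(out, "modality") <- epochs$modality
  class(out) <- c("bci_features", class(out))
  out
}
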