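#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes to dual-wavelength light
#' intensities: \eqn{I(\lambda, t) = I_0(\lambda) 10^{-\Delta OD(\lambda, t)}}
#' with \eqn{\Delta OD = \varepsilon d \, DPF \, \Delta c}. This is the
#' generative counterpart of [mbll()]; the two are exact algebraic inverses.
#'
#' @param delta_hbo,delta_hbr Channels x samples matrices of concentration
#'   changes, millimolar.
#' @param params [mbll_params()].
#' @param baseline_intensity Positive baseline intensities; scalar, per
#'   wavelength (length 2), or channels x 2 matrix.
#'
#' @return Array channels x 2 (wavelength) x samples of strictly positive
#'   intensities.
#' @export
forward_mbll <- function(delta_hbo, delta_hbr, params = mbll_params(),
                         baseline_intensity = 1) {
  delta_hbo <- rbind(delta_hbo); delta_hbr <- rbind(delta_hbr)
  assert_that(all(dim(delta_hbo) == dim(delta_hbr)),
              "delta_hbo and delta_hbr must have identical shape")
  n_ch <- nrow(delta_hbo); n_s <- ncol(delta_hbo)
  A <- mbll_coupling(params)
  i0 <- baseline_intensity
  if (length(i0) == 1) i0 <- matrix(i0, n_ch, 2)
  if (is.null(dim(i0)) && length(i0) == 2) i0 <- matrix(i0, n_ch, 2, byrow = TRUE)
  assert_that(all(i0 > 0), "baseline intensities must be positive")
  out <- array(NA_real_, c(n_ch, 2, n_s))
  for (ch in seq_len(n_ch)) {
    od <- A %*% rbind(delta_hbo[ch, ], delta_hbr[ch, ]) # 2 x samples
    out[ch, 1, ] <- i0[ch, 1] * 10^(-od[1, ])
    out[ch, 2, ] <- i0[ch, 2] * 10^(-od[2, ])
  }
  out
}

#' Modified Beer-Lambert conversion of raw intensities
#'
#' Converts dual-wavelength near-infrared light intensities to oxy- and
#' deoxyhemoglobin concentration changes. Per channel and sample,
#' \eqn{\Delta OD(\lambda) = -\log_{10}(I(\lambda)/I_0(\lambda))} and
#' \eqn{(\Delta HbO, \Delta HbR)^T = (\varepsilon d \, DPF)^{-1} \Delta OD},
#' where the reference intensity \eqn{I_0} is the per-channel mean over
#' `params$baseline_window_s` (whole recording if `NULL`).
#'
#' @param intensity Channels x 2 (wavelength) x samples array of positive
#'   intensities.
#' @param params [mbll_params()].
#' @param rate_hz Sampling rate, needed only when a baseline window is set.
#'
#' @return List with `hbo` and `hbr`, channels x samples matrices in
#'   millimolar.
#' @export
mbll <- function(intensity, params = mbll_params(), rate_hz = NULL) {
  assert_that(length(dim(intensity)) == 3 && dim(intensity)[2] == 2,
              "intensity must be channels x 2 wavelengths x samples")
  if (any(intensity <= 0)) {
    bad <- which(intensity <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-positive intensity at channel %d, wavelength %d, sample %d",
      bad[1], bad[2], bad[3]))
  }
  n_ch <- dim(intensity)[1]; n_s <- dim(intensity)[3]
  idx <- seq_len(n_s)
  if (!is.null(params$baseline_window_s)) {
    assert_that(!is.null(rate_hz), "rate_hz required with a baseline window")
    w <- params$baseline_window_s
    idx <- which((idx - 1) / rate_hz >= w[1] & (idx - 1) / rate_hz < w[2])
    assert_that(length(idx) > 0, "baseline window is outside the recording")
  }
  A_inv <- solve(mbll_coupling(params))
  hbo <- matrix(NA_real_, n_ch, n_s)
  hbr <- matrix(NA_real_, n_ch, n_s)
  for (ch in seq_len(n_ch)) {
    i0 <- c(mean(intensity[ch, 1, idx]), mean(intensity[ch, 2, idx]))
    od <- rbind(-log10(intensity[ch, 1, ] / i0[1]),
                -log10(intensity[ch, 2, ] / i0[2]))
    conc <- A_inv %*% od
    hbo[ch, ] <- conc[1, ]
    hbr[ch, ] <- conc[2, ]
  }
  list(hbo = hbo, hbr = hbr)
}
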