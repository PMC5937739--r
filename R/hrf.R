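#' Canonical double-gamma hemodynamic response
#'
#' Difference of two gamma densities, normalized to unit peak: a response
#' peaking at `peak_s` with a late undershoot around `undershoot_s` scaled
#' by `ratio`. Convolved with a 10 s task boxcar this places the peak
#' concentration change 10--15 s after task onset, the window the
#' hemodynamic features are read from.
#'
#' @param t Non-decreasing time grid, seconds, `t >= 0`.
#' @param peak_s Time-to-peak of the positive lobe, seconds.
#' @param undershoot_s Time-to-trough of the undershoot, seconds.
#' @param ratio Undershoot amplitude relative to the peak lobe (0 disables
#'   the undershoot).
#'
#' @return Numeric response sampled on `t`, max value 1.
#' @export
#' @examples
#' h <- canonical_hrf(seq(0, 30, by = 0.1))
#' which.max(h) # near t = 6 s
canonical_hrf <- function(t, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  assert_that(all(t >= 0), "time grid must be non-negative")
  assert_that(!is.unsorted(t, strictly = FALSE) && all(diff(t) > 0) || length(t) <= 1,
              "time grid must be strictly increasing")
  assert_that(peak_s > 0 && undershoot_s > peak_s,
              "need 0 < peak_s < undershoot_s")
  assert_that(ratio >= 0, "ratio must be non-negative")
  # gamma densities with rate 1 have mode (shape - 1); shape = mode + 1
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  # peak normalization on a dense internal grid so coarse t still scales right
  tg <- seq(0, max(undershoot_s * 2, max(t)), by = 0.01)
  hg <- stats::dgamma(tg, shape = peak_s + 1, rate = 1) -
    ratio * stats::dgamma(tg, shape = undershoot_s + 1, rate = 1)
  h / max(hg)
}
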