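#' Trial-paradigm configuration
#'
#' Timing and sampling parameters of one recording block: a pre-rest,
#' `n_trials_per_session` trials (visual instruction, 10 s task with eyes
#' closed, randomized inter-trial rest), and a post-rest. Event onsets mark
#' the start of the task period (the auditory go cue), so the analysis
#' windows 0--10 s (EEG) and 10--15 s (hemodynamics) are relative to task
#' start.
#'
#' @param pre_rest_s,post_rest_s Rest before/after the trial block, seconds.
#' @param instruction_s Visual instruction duration, seconds.
#' @param task_s Task duration, seconds.
#' @param rest_range_s Length-2 numeric; inter-trial rest is drawn uniformly
#'   from this interval, seconds.
#' @param n_trials_per_session Trials per session; even by default so the
#'   mental-arithmetic (MA) and baseline (BL) labels balance exactly.
#' @param n_sessions Number of sessions simulated per dataset.
#' @param eeg_rate_hz,nirs_rate_hz Sampling rates of the electrical and
#'   optical streams, Hz.
#' @param seed Integer seed making the generated dataset reproducible.
#'
#' @return A `paradigm_config` list.
#' @export
#' @examples
#' paradigm_config(n_sessions = 1)
paradigm_config <- function(pre_rest_s = 15,
                            instruction_s = 2,
                            task_s = 10,
                            rest_range_s = c(15, 17),
                            post_rest_s = 15,
                            n_trials_per_session = 20,
                            n_sessions = 3,
                            eeg_rate_hz = 1000,
                            nirs_rate_hz = 12.5,
                            seed = 1L) {
  assert_that(all(c(pre_rest_s, instruction_s, task_s, post_rest_s) > 0),
              "all paradigm durations must be positive")
  assert_that(length(rest_range_s) == 2 && rest_range_s[1] <= rest_range_s[2] &&
                rest_range_s[1] > 0,
              "rest_range_s must be a positive interval [lo, hi] with lo <= hi")
  assert_that(n_trials_per_session >= 2,
              "n_trials_per_session must be at least 2")
  assert_that(n_sessions >= 1, "n_sessions must be at least 1")
  assert_that(eeg_rate_hz > 0 && nirs_rate_hz > 0, "rates must be positive")
  structure(
    list(
      pre_rest_s = pre_rest_s, instruction_s = instruction_s,
      task_s = task_s, rest_range_s = as.numeric(rest_range_s),
      post_rest_s = post_rest_s,
      n_trials_per_session = as.integer(n_trials_per_session),
      n_sessions = as.integer(n_sessions),
      eeg_rate_hz = eeg_rate_hz, nirs_rate_hz = nirs_rate_hz,
      seed = as.integer(seed)
    ),
    class = "paradigm_config"
  )
}

#' Effect-size configuration for the synthetic generator
#'
#' Parameters controlling the class-discriminative structure and nuisance
#' components of simulated sessions. The two signals the decoder exploits
#' are (i) attenuation of the eyes-closed alpha rhythm during mental
#' arithmetic and (ii) a larger prefrontal hemodynamic response during
#' mental arithmetic than baseline.
#'
#' @param alpha_center_hz Center frequency of the alpha rhythm, Hz.
#' @param alpha_amplitude_uv Eyes-closed alpha amplitude (standard deviation
#'   of the narrowband component), microvolts.
#' @param alpha_attenuation_ma Fractional alpha-amplitude reduction during
#'   the mental-arithmetic task window, in \[0, 1\]. 0 removes the EEG effect.
#' @param hrf_amp_ma,hrf_amp_bl Peak oxyhemoglobin concentration change for
#'   MA and BL trials, millimolar (default 1.0 and 0.5 micromolar). The
#'   deoxyhemoglobin response is `hbr_ratio` times the oxy response.
#' @param hrf_amp_cv Trial-to-trial lognormal coefficient of variation of
#'   the response amplitude (mean-one jitter; 0 disables).
#' @param hbr_ratio Signed scale of the deoxy response relative to oxy
#'   (negative: HbR decreases while HbO increases).
#' @param noise_1f_scale Standard deviation of the 1/f EEG background,
#'   microvolts.
#' @param eog_amplitude_uv Amplitude of the ocular sources at the eyes,
#'   microvolts.
#' @param eog_mix_gain Gain of ocular contamination at the closest frontal
#'   electrode; gains decay toward posterior sites.
#' @param physio_freqs_hz Named frequencies (Hz) of cardiac, respiratory and
#'   Mayer-wave oscillations added to the hemodynamic channels.
#' @param physio_amp_mm Amplitude of each physiological oscillation,
#'   millimolar equivalent.
#' @param drift_scale Standard deviation of the slow random-walk drift in
#'   the hemodynamic channels, millimolar equivalent.
#' @param nirs_noise_mm White measurement noise on the hemodynamic channels,
#'   millimolar equivalent.
#'
#' @return An `effect_config` list.
#' @export
effect_config <- function(alpha_center_hz = 10,
                          alpha_amplitude_uv = 8,
                          alpha_attenuation_ma = 0.25,
                          hrf_amp_ma = 1.0e-3,
                          hrf_amp_bl = 0.5e-3,
                          hrf_amp_cv = 0.4,
                          hbr_ratio = -1 / 3,
                          noise_1f_scale = 6,
                          eog_amplitude_uv = 60,
                          eog_mix_gain = 0.4,
                          physio_freqs_hz = c(cardiac = 1.0, respiration = 0.3,
                                              mayer = 0.1),
                          physio_amp_mm = 0.35e-3,
                          drift_scale = 0.3e-3,
                          nirs_noise_mm = 0.08e-3) {
  assert_that(alpha_attenuation_ma >= 0 && alpha_attenuation_ma <= 1,
              "alpha_attenuation_ma must lie in [0, 1]")
  assert_that(all(c(alpha_amplitude_uv, noise_1f_scale, eog_amplitude_uv,
                    physio_amp_mm, drift_scale, nirs_noise_mm) >= 0),
              "amplitudes must be non-negative")
  assert_that(hrf_amp_ma >= 0 && hrf_amp_bl >= 0,
              "hemodynamic amplitudes must be non-negative")
  if (hrf_amp_ma < hrf_amp_bl) {
    warn("hrf_amp_ma < hrf_amp_bl: task response weaker than baseline response")
  }
  structure(
    list(
      alpha_center_hz = alpha_center_hz,
      alpha_amplitude_uv = alpha_amplitude_uv,
      alpha_attenuation_ma = alpha_attenuation_ma,
      hrf_amp_ma = hrf_amp_ma, hrf_amp_bl = hrf_amp_bl,
      hrf_amp_cv = hrf_amp_cv,
      hbr_ratio = hbr_ratio,
      noise_1f_scale = noise_1f_scale,
      eog_amplitude_uv = eog_amplitude_uv,
      eog_mix_gain = eog_mix_gain,
      physio_freqs_hz = physio_freqs_hz,
      physio_amp_mm = physio_amp_mm,
      drift_scale = drift_scale,
      nirs_noise_mm = nirs_noise_mm
    ),
    class = "effect_config"
  )
}

#' Modified Beer-Lambert law parameters
#'
#' Constants of the linear map between dual-wavelength optical-density
#' changes and hemoglobin concentration changes:
#' \deqn{\Delta OD(\lambda) = \varepsilon(\lambda) \, d \, DPF(\lambda) \, \Delta c.}
#'
#' Default extinction coefficients are standard values for 760 and 850 nm
#' in 1/(mM mm); rows are wavelengths, columns are (HbO, HbR).
#'
#' @param extinction 2 x 2 matrix of extinction coefficients, wavelengths x
#'   chromophores (HbO, HbR), 1/(mM mm).
#' @param dpf Differential pathlength factor per wavelength (dimensionless).
#' @param distance_mm Source-detector separation, millimetres.
#' @param wavelengths_nm Wavelength labels, nanometres.
#' @param baseline_window_s Optional `c(start, end)` in seconds defining the
#'   reference-intensity window; `NULL` uses the whole recording.
#'
#' @return An `mbll_params` list.
#' @export
mbll_params <- function(extinction = matrix(c(0.1486, 0.3843,
                                              0.2526, 0.1798),
                                            nrow = 2, byrow = TRUE,
                                            dimnames = list(c("760", "850"),
                                                            c("HbO", "HbR"))),
                        dpf = c(5.98, 5.07),
                        distance_mm = 30,
                        wavelengths_nm = c(760, 850),
                        baseline_window_s = NULL) {
  extinction <- as.matrix(extinction)
  assert_that(all(dim(extinction) == c(2, 2)), "extinction must be 2 x 2")
  assert_that(abs(det(extinction)) > 1e-12, "extinction matrix is singular")
  assert_that(all(dpf > 0) && length(dpf) == 2, "dpf must be two positive values")
  assert_that(distance_mm > 0, "distance_mm must be positive")
  structure(
    list(extinction = extinction, dpf = as.numeric(dpf),
         distance_mm = distance_mm,
         wavelengths_nm = as.numeric(wavelengths_nm),
         baseline_window_s = baseline_window_s),
    class = "mbll_params"
  )
}

# Pathlength-scaled system matrix: DeltaOD = coupling %*% c(dHbO, dHbR)
mbll_coupling <- function(params) {
  diag(params$dpf) %*% params$extinction * params$distance_mm
}

#' Band-pass filter specification
#'
#' @param passband_hz Length-2 numeric `c(low, high)`, Hz.
#' @param order Butterworth design order (the zero-phase forward-backward
#'   application doubles the effective order).
#' @param zero_phase Apply forward-backward (no group delay)?
#'
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(passband_hz, order = 3, zero_phase = TRUE) {
  assert_that(length(passband_hz) == 2 && passband_hz[1] > 0 &&
                passband_hz[1] < passband_hz[2],
              "passband must satisfy 0 < low < high")
  assert_that(order >= 1, "order must be >= 1")
  structure(
    list(passband_hz = as.numeric(passband_hz), order = as.integer(order),
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}
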