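#' Generate a synthetic hybrid EEG + NIRS dataset
#'
#' Simulates one participant's sessions of the eyes-closed mental-arithmetic
#' (MA) versus baseline (BL) paradigm with known ground truth. The EEG
#' carries an eyes-closed alpha rhythm over all channels whose amplitude is
#' attenuated during MA task windows, on top of 1/f background noise and
#' ocular (blink/saccade) contamination mixed with frontally dominant gains.
#' The NIRS intensities are produced by the forward Beer-Lambert model from
#' canonical hemodynamic responses with class-dependent amplitude, plus
#' slow drift, cardiac/respiratory/Mayer-wave oscillations, and white noise.
#' Sessions are concatenated on one time axis; labels are balanced within
#' each session and the inter-trial rest is drawn uniformly from the
#' configured range.
#'
#' @param paradigm [paradigm_config()].
#' @param effects [effect_config()].
#' @param mbll [mbll_params()] used by the optical forward model.
#'
#' @return List with `recording` ([bci_recording]) and `truth` (list with
#'   per-trial `labels`, `trial_onsets_s`, `session`, the noiseless
#'   `true_hbo`/`true_hbr` concentration series, the ocular `eog_sources`,
#'   and the ocular `mixing_matrix` into the EEG channels).
#' @export
#' @examples
#' sim <- generate_dataset(paradigm_config(n_sessions = 1, seed = 7))
#' sim$recording
generate_dataset <- function(paradigm = paradigm_config(),
                             effects = effect_config(),
                             mbll = mbll_params()) {
  set.seed(paradigm$seed)
  fs_e <- paradigm$eeg_rate_hz
  fs_n <- paradigm$nirs_rate_hz

  # ---- timeline and labels -------------------------------------------------
  onsets <- numeric(0); labels <- character(0); session <- integer(0)
  t_cursor <- 0
  session_dur <- numeric(paradigm$n_sessions)
  for (s in seq_len(paradigm$n_sessions)) {
    t0 <- t_cursor
    t_cursor <- t_cursor + paradigm$pre_rest_s
    n_tr <- paradigm$n_trials_per_session
    lab <- sample(rep(c("MA", "BL"), length.out = n_tr))
    for (i in seq_len(n_tr)) {
      t_cursor <- t_cursor + paradigm$instruction_s
      onsets <- c(onsets, t_cursor)
      labels <- c(labels, lab[i])
      session <- c(session, s)
      rest <- runif(1, paradigm$rest_range_s[1], paradigm$rest_range_s[2])
      t_cursor <- t_cursor + paradigm$task_s + rest
    }
    t_cursor <- t_cursor + paradigm$post_rest_s
    session_dur[s] <- t_cursor - t0
  }
  total_s <- t_cursor
  n_e <- floor(total_s * fs_e)
  n_n <- floor(total_s * fs_n)
  t_e <- (seq_len(n_e) - 1) / fs_e

  eeg_names <- c(FRONTAL_CHANNELS, POSTERIOR_CHANNELS)
  n_ch <- length(eeg_names)

  # ---- EEG: 1/f background + modulated alpha + ocular mixing ---------------
  eeg <- matrix(0, n_ch, n_e, dimnames = list(eeg_names, NULL))
  for (ch in seq_len(n_ch)) {
    eeg[ch, ] <- one_over_f_noise(n_e, fs_e) * effects$noise_1f_scale
  }

  # attenuation depth: 0 outside MA task windows, 1 inside (smoothed);
  # per-channel attenuation weights make the desynchronization spatially
  # non-uniform, as task-related alpha suppression is in practice -- a
  # perfectly uniform power change would be invisible to trace-normalized
  # spatial filtering
  depth <- rep(0, n_e)
  for (i in seq_along(onsets)) {
    if (labels[i] == "MA") {
      idx <- which(t_e >= onsets[i] & t_e < onsets[i] + paradigm$task_s)
      depth[idx] <- 1
    }
  }
  ramp <- max(1L, round(0.5 * fs_e))
  depth <- stats::filter(depth, rep(1 / ramp, ramp), sides = 2)
  depth[is.na(depth)] <- 0
  atten_weight <- runif(n_ch, 0.3, 1)

  if (effects$alpha_amplitude_uv > 0) {
    global_alpha <- narrowband_noise(n_e, fs_e, effects$alpha_center_hz)
    for (ch in seq_len(n_ch)) {
      own <- narrowband_noise(n_e, fs_e, effects$alpha_center_hz)
      carrier <- sqrt(0.5) * global_alpha + sqrt(0.5) * own
      gain <- effects$alpha_amplitude_uv * runif(1, 0.85, 1.15)
      env <- 1 - effects$alpha_attenuation_ma * atten_weight[ch] * depth
      eeg[ch, ] <- eeg[ch, ] + gain * env * carrier
    }
  }

  # ocular sources: blinks (sparse smooth pulses) and saccades (smoothed
  # telegraph), both < 4 Hz
  blink <- blink_source(n_e, fs_e)
  sacc <- saccade_source(n_e, fs_e)
  eog_src <- rbind(blink = blink, saccade = sacc) * effects$eog_amplitude_uv
  eog <- rbind(
    VEOGu = 1.0 * eog_src[1, ] + 0.10 * eog_src[2, ],
    VEOGl = -0.7 * eog_src[1, ] + 0.05 * eog_src[2, ],
    HEOGl = 0.15 * eog_src[1, ] + 0.9 * eog_src[2, ],
    HEOGr = 0.15 * eog_src[1, ] - 0.9 * eog_src[2, ]
  )
  eog <- eog + matrix(rnorm(4 * n_e, sd = 2), 4, n_e)
  # contamination gains decay from prefrontal to posterior sites
  decay <- c(1, 1, 0.85, 0.85, 0.8, 0.8, 0.6, 0.6, 0.55, 0.55, # frontal
             0.25, 0.2, 0.2, 0.15, 0.15, 0.12, 0.1, 0.1, 0.08, 0.08, 0.05, 0.05)
  mix <- cbind(blink = effects$eog_mix_gain * decay,
               saccade = 0.6 * effects$eog_mix_gain * decay)
  rownames(mix) <- eeg_names
  eeg <- eeg + mix %*% eog_src

  # ---- NIRS: HRF forward model + physiology + drift ------------------------
  n_opt <- 9
  t_hrf <- seq(0, 32, by = 1 / fs_n)
  hrf <- canonical_hrf(t_hrf)
  box <- numeric(n_n)
  t_n <- (seq_len(n_n) - 1) / fs_n
  cv <- effects$hrf_amp_cv
  for (i in seq_along(onsets)) {
    idx <- which(t_n >= onsets[i] & t_n < onsets[i] + paradigm$task_s)
    amp <- if (labels[i] == "MA") effects$hrf_amp_ma else effects$hrf_amp_bl
    # mean-one lognormal trial-to-trial amplitude jitter
    if (cv > 0) amp <- amp * stats::rlnorm(1, -log(1 + cv^2) / 2,
                                           sqrt(log(1 + cv^2)))
    box[idx] <- amp
  }
  resp <- convolve_causal(box, hrf)

  ch_gain <- runif(n_opt, 0.7, 1.3)
  true_hbo <- outer(ch_gain, resp)
  true_hbr <- effects$hbr_ratio * true_hbo

  # physiological oscillations are spatially coherent: one global phase per
  # component, channel-specific gain, plus a smaller independent part
  noise_conc <- function() {
    global <- lapply(effects$physio_freqs_hz, function(f) {
      sin(2 * pi * f * t_n + runif(1, 0, 2 * pi))
    })
    out <- matrix(0, n_opt, n_n)
    for (ch in seq_len(n_opt)) {
      phys <- rep(0, n_n)
      for (g in global) {
        phys <- phys + effects$physio_amp_mm *
          (runif(1, 0.6, 1.4) * g +
             0.3 * sin(2 * pi * runif(1, 0.05, 1.2) * t_n +
                         runif(1, 0, 2 * pi)))
      }
      drift <- cumsum(rnorm(n_n)) / sqrt(n_n) * effects$drift_scale
      out[ch, ] <- phys + drift + rnorm(n_n, sd = effects$nirs_noise_mm)
    }
    out
  }
  meas_hbo <- true_hbo + noise_conc()
  meas_hbr <- true_hbr + noise_conc()

  i0 <- matrix(runif(n_opt * 2, 0.8, 1.2), n_opt, 2)
  nirs_intensity <- forward_mbll(meas_hbo, meas_hbr, mbll,
                                 baseline_intensity = i0)

  events <- tibble::tibble(onset_s = onsets, label = labels)
  rec <- bci_recording(
    eeg = eeg, eog = eog, nirs_intensity = nirs_intensity, events = events,
    eeg_rate_hz = fs_e, nirs_rate_hz = fs_n,
    optode_distance_mm = mbll$distance_mm,
    meta = list(seed = paradigm$seed, generator = "hybridbci synthetic",
                n_sessions = paradigm$n_sessions)
  )
  truth <- list(
    labels = labels, trial_onsets_s = onsets, session = session,
    true_hbo = true_hbo, true_hbr = true_hbr,
    eog_sources = eog_src, mixing_matrix = mix,
    alpha_atten_weight = stats::setNames(atten_weight, eeg_names),
    nirs_channel_gain = ch_gain, baseline_intensity = i0
  )
  list(recording = rec, truth = truth)
}

# spectrally shaped Gaussian noise, unit variance; shape_fn maps frequency
# (Hz) to amplitude. FFT length padded to a highly composite size.
shaped_noise <- function(n, rate, shape_fn) {
  m <- stats::nextn(n)
  x <- rnorm(m)
  X <- fft(x)
  f <- c(0, seq_len(m - 1)) * rate / m
  f <- pmin(f, rate - f) # two-sided spectrum
  y <- Re(fft(X * shape_fn(f), inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y / sd(y)
}

# 1/f-amplitude Gaussian noise, unit variance
one_over_f_noise <- function(n, rate, f_floor = 0.5) {
  shaped_noise(n, rate, function(f) 1 / sqrt(pmax(f, f_floor)))
}

# unit-variance noise with a Gaussian spectral peak at f0
narrowband_noise <- function(n, rate, f0, half_bw = 1) {
  shaped_noise(n, rate, function(f) exp(-(f - f0)^2 / (2 * half_bw^2)))
}

blink_source <- function(n, rate, events_per_s = 0.15) {
  src <- numeric(n)
  n_ev <- stats::rpois(1, events_per_s * n / rate)
  if (n_ev > 0) {
    pos <- sort(sample.int(n, n_ev))
    width <- round(0.15 * rate)
    pulse <- exp(-((seq_len(4 * width) - 2 * width)^2) / (2 * width^2))
    for (p in pos) {
      idx <- p + seq_along(pulse) - 2 * width
      ok <- idx >= 1 & idx <= n
      src[idx[ok]] <- src[idx[ok]] + pulse[ok] * runif(1, 0.7, 1.3)
    }
  }
  src
}

saccade_source <- function(n, rate, switches_per_s = 0.3) {
  n_sw <- max(2, stats::rpois(1, switches_per_s * n / rate))
  pos <- sort(c(1, sample.int(n, n_sw), n + 1))
  lev <- runif(length(pos) - 1, -1, 1)
  src <- rep(lev, times = diff(pos))[seq_len(n)]
  b <- signal::butter(2, min(3 / (rate / 2), 0.99), type = "low")
  signal::filtfilt(b, src)
}

# causal linear convolution truncated to length(x)
convolve_causal <- function(x, kernel) {
  out <- stats::convolve(x, rev(kernel), type = "open")
  out[seq_along(x)]
}
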