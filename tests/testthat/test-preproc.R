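test_that("decimation preserves length arithmetic, constants and in-band tones", {
  x <- matrix(rnorm(10000), 1)
  out <- downsample_eeg(x, 1000, 5L)
  expect_equal(ncol(out$data), 2000)
  expect_equal(out$rate_hz, 200)

  const <- downsample_eeg(matrix(5, 1, 4000), 1000, 5L)
  expect_equal(const$data[1, ], rep(5, 800), tolerance = 1e-6)

  t <- (0:19999) / 1000
  tone <- downsample_eeg(matrix(sin(2 * pi * 10 * t), 1), 1000, 5L)
  sp <- Mod(fft(tone$data[1, ]))[1:2000]
  f <- (0:1999) * 200 / 4000
  expect_equal(f[which.max(sp)], 10)
  # amplitude preserved within 1% (spectral peak of a unit sine = n/2)
  expect_equal(max(sp) / (4000 / 2), 1, tolerance = 0.01)
})

test_that("band-pass filters match their analytic pass/stop behavior", {
  fs <- 200
  x <- 3 + rnorm(fs * 30, sd = 0.5)
  y <- bandpass(x, filter_spec(c(0.5, 50), order = 3), fs)
  trim <- (2 * fs):(length(y) - 2 * fs)
  expect_lt(abs(mean(y[trim])), 0.03) # DC (3 units) removed to < 1%

  # 0.05 Hz sine: inside the hemodynamic band, far below the EEG band
  fsn <- 12.5
  tn <- seq(0, 2000, by = 1 / fsn)
  slow <- sin(2 * pi * 0.05 * tn)
  yn <- bandpass(slow, filter_spec(c(0.01, 0.2), order = 6), fsn)
  mid <- yn[(length(yn) %/% 4):(3 * length(yn) %/% 4)]
  expect_equal(max(abs(mid)), 1, tolerance = 0.05)

  te <- seq(0, 400, by = 1 / fs)
  ye <- bandpass(sin(2 * pi * 0.05 * te), filter_spec(c(0.5, 50), 3), fs)
  mide <- ye[(length(ye) %/% 4):(3 * length(ye) %/% 4)]
  expect_lt(20 * log10(max(abs(mide))), -20)
})

test_that("filtering is linear to machine precision", {
  set.seed(4)
  x <- rnorm(1000); y <- rnorm(1000)
  spec <- filter_spec(c(1, 40), order = 3)
  lhs <- bandpass(2.5 * x - 1.3 * y, spec, 200)
  rhs <- 2.5 * bandpass(x, spec, 200) - 1.3 * bandpass(y, spec, 200)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("zero-phase filtering preserves impulse-feature latency", {
  fs <- 200
  x <- numeric(3000)
  x[1500:1520] <- exp(-((0:20) - 10)^2 / 18) # smooth bump
  y <- bandpass(x, filter_spec(c(0.5, 50), order = 3, zero_phase = TRUE), fs)
  expect_lt(abs(which.max(y) - which.max(x)), 3)
})

test_that("ocular cleaning removes EOG mixtures and keeps neural content", {
  set.seed(21)
  fs <- 200; n <- fs * 120
  # distinct narrowband neural sources per channel
  s <- rbind(
    hybridbci:::narrowband_noise(n, fs, 10),
    hybridbci:::narrowband_noise(n, fs, 22),
    hybridbci:::narrowband_noise(n, fs, 6),
    hybridbci:::narrowband_noise(n, fs, 17)
  )
  eog <- rbind(hybridbci:::blink_source(n, fs, events_per_s = 0.4) * 40,
               hybridbci:::saccade_source(n, fs) * 30,
               hybridbci:::blink_source(n, fs, events_per_s = 0.3) * 25,
               hybridbci:::saccade_source(n, fs, switches_per_s = 0.5) * 20)
  G <- matrix(runif(16, 0.2, 0.7), 4, 4)
  x <- s + G %*% eog
  for (method in c("sobi", "regression")) {
    cleaned <- remove_eog(x, eog, method = method, rate_hz = fs)
    expect_equal(dim(cleaned), dim(x))
    for (ch in 1:4) {
      expect_lt(max(abs(cor(cleaned[ch, ], t(eog)))), 0.1)
      expect_gt(cor(cleaned[ch, ], s[ch, ]), 0.9)
    }
  }
})

test_that("cleaning with silent EOG is a no-op", {
  set.seed(3)
  x <- matrix(rnorm(4 * 2000), 4)
  out <- remove_eog(x, matrix(0, 4, 2000), method = "sobi")
  expect_equal(out, x, tolerance = 1e-9)
})

test_that("epoching follows the half-open sample-time convention", {
  fs <- 200
  x <- matrix(rnorm(10 * fs * 60), 10)
  rownames(x) <- sprintf("ch%d", 1:10)
  ev <- data.frame(onset_s = seq(2, 40, by = 2)[1:20],
                   label = rep(c("MA", "BL"), 10))
  ep <- epoch(x, ev, c(0, 10), fs, "EEG")
  expect_equal(dim(ep$data), c(20, 10, 2000))

  # NIRS window [10, 15) with a sample exactly at onset + 10 s
  xn <- matrix(seq_len(13 * 375), 13)
  evn <- data.frame(onset_s = 2.0, label = "MA") # (2+10)*12.5 = 150 exact
  epn <- epoch(xn, evn, c(10, 15), 12.5, "HbO")
  expect_equal(dim(epn$data)[3], 63)

  # empty event list is fine
  ep0 <- epoch(x, ev[0, ], c(0, 10), fs, "EEG")
  expect_equal(dim(ep0$data)[1], 0)

  # windows beyond the recording are an error
  expect_error(epoch(x, data.frame(onset_s = 59, label = "MA"),
                     c(0, 10), fs, "EEG"), "exceeds recording")
})

test_that("epoching is label-agnostic: permuting events permutes trials", {
  fs <- 50
  x <- matrix(rnorm(2 * fs * 100), 2)
  ev <- data.frame(onset_s = c(5, 20, 35, 50), label = c("MA", "BL", "MA", "BL"))
  ep1 <- epoch(x, ev, c(0, 5), fs, "EEG")
  ep2 <- epoch(x, ev[c(3, 1, 4, 2), ], c(0, 5), fs, "EEG")
  expect_identical(ep1$data, ep2$data) # re-sorted by onset
  expect_identical(as.character(ep1$labels), as.character(ep2$labels))
})

test_that("preprocessing order yields analysis-ready epochs", {
  prep <- small_prep()
  expect_equal(prep$eeg$rate_hz, 200)
  expect_equal(dim(prep$eeg$data)[2], 10) # frontal channels only
  expect_equal(prep$eeg$window_s, c(0, 10))
  expect_equal(prep$hbo$window_s, c(10, 15))
  expect_equal(dim(prep$hbo$data)[2], 9)
  expect_identical(as.character(prep$eeg$labels),
                   as.character(prep$hbo$labels))
})
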