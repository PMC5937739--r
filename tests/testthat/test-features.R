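test_that("signed r-squared matches the point-biserial identity", {
  expect_equal(signed_r_squared(c(1, 1, 0, 0), c("MA", "MA", "BL", "BL")), 1)
  expect_equal(signed_r_squared(c(1, 0, 1, 0), c("MA", "BL", "BL", "MA")), 0,
               tolerance = 1e-12)
  # same values relabeled so class distributions coincide
  expect_equal(signed_r_squared(c(3, 7, 3, 7), c("MA", "MA", "BL", "BL")), 0,
               tolerance = 1e-12)

  # identity: sgn r2 = sign(m1-m2) * (m1-m2)^2 * n1 * n2 / (n^2 * var_total)
  set.seed(8)
  for (i in 1:20) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    v <- rnorm(n1 + n2)
    lab <- c(rep("MA", n1), rep("BL", n2))
    m1 <- mean(v[1:n1]); m2 <- mean(v[-(1:n1)])
    n <- n1 + n2
    direct <- sign(m1 - m2) * (m1 - m2)^2 * n1 * n2 /
      (n^2 * var(v) * (n - 1) / n)
    expect_equal(signed_r_squared(v, lab), direct, tolerance = 1e-10)
  }

  expect_error(signed_r_squared(1:4, rep("MA", 4)), "both classes")
  expect_error(signed_r_squared(rep(1, 4), c("MA", "MA", "BL", "BL")),
               "zero variance")
})

test_that("band selection finds a discriminative alpha band on a 0.5 Hz grid", {
  set.seed(31)
  fs <- 200; n_tr <- 16; n_s <- fs * 4
  dat <- array(NA_real_, c(n_tr, 4, n_s))
  labs <- rep(c("MA", "BL"), n_tr / 2)
  for (i in seq_len(n_tr)) {
    amp <- if (labs[i] == "MA") 0.6 else 2
    for (ch in 1:4) {
      dat[i, ch, ] <- rnorm(n_s) +
        amp * hybridbci:::narrowband_noise(n_s, fs, 10, half_bw = 0.7)
    }
  }
  ep <- bci_epochs(dat, c(0, 4), labs, fs, "EEG")
  band <- select_band(ep)
  expect_gte(10, band$f_low)
  expect_lte(10, band$f_high)
  expect_equal(band$f_low %% 0.5, 0)
  expect_equal(band$f_high %% 0.5, 0)

  # zero-effect data falls back to the full search range
  set.seed(32)
  null_dat <- array(rnorm(n_tr * 4 * n_s), c(n_tr, 4, n_s))
  ep0 <- bci_epochs(null_dat, c(0, 4), labs, fs, "EEG")
  band0 <- select_band(ep0)
  expect_equal(c(band0$f_low, band0$f_high), c(4, 35))
})

test_that("hemodynamic mean/slope features are exact for lines", {
  fs <- 12.5; n_s <- 63
  dat <- array(NA_real_, c(4, 2, n_s))
  t <- (0:(n_s - 1)) / fs
  dat[, 1, ] <- matrix(rep(c(2, -1, 0.5, 3), n_s), 4) # constants
  for (i in 1:4) dat[i, 2, ] <- i * t # lines through origin
  ep <- bci_epochs(dat, c(10, 15), c("MA", "BL", "MA", "BL"), fs, "HbO",
                   channels = c("c1", "c2"))
  f <- nirs_mean_slope(ep)
  expect_equal(f$c1_hbo_mean, c(2, -1, 0.5, 3))
  expect_equal(f$c1_hbo_slope, rep(0, 4), tolerance = 1e-10)
  expect_equal(f$c2_hbo_slope, 1:4, tolerance = 1e-10)

  # 9-channel montage gives 18 features per chromophore
  prep <- small_prep()
  fb <- nirs_mean_slope(prep$hbo)
  expect_equal(ncol(fb) - 1, 18)
  expect_true(all(is.finite(as.matrix(fb[setdiff(names(fb), "label")]))))
})

test_that("band map has channel x band structure and detects alpha suppression", {
  prep <- small_prep()
  m <- sgn_r2_band_map(prep$eeg)
  expect_equal(nrow(m), 10 * 5)
  expect_true(all(abs(m$sgn_r2) <= 1))
  alpha <- m$sgn_r2[m$band == "alpha"]
  expect_lt(mean(alpha), 0) # MA < BL in the alpha band

  # label-permuted data gives small scores
  set.seed(55)
  ep <- prep$eeg
  ep$labels <- sample(ep$labels)
  m0 <- sgn_r2_band_map(ep)
  expect_lt(mean(abs(m0$sgn_r2)), mean(abs(m$sgn_r2[m$band == "alpha"])))
})
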