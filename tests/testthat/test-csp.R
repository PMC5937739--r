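test_that("equal class covariances give eigenvalues near one half", {
  set.seed(12)
  C <- crossprod(matrix(rnorm(16), 4))
  ep <- epochs_with_cov(C, C, n_per_class = 8, n_samp = 200)
  model <- csp_fit(ep)
  expect_equal(model$eigenvalues, rep(0.5, 4), tolerance = 1e-8)
})

test_that("analytic two-channel case yields eigenvalues 0.8 and 0.2", {
  set.seed(13)
  ep <- epochs_with_cov(diag(c(4, 1)), diag(c(1, 4)),
                        n_per_class = 6, n_samp = 150)
  model <- csp_fit(ep, n_select = 1)
  expect_equal(model$eigenvalues, c(0.8, 0.2), tolerance = 1e-8)
})

test_that("whitening identity holds on training covariances", {
  set.seed(14)
  A <- crossprod(matrix(rnorm(25), 5)); B <- crossprod(matrix(rnorm(25), 5))
  ep <- epochs_with_cov(A, B, n_per_class = 5, n_samp = 120)
  model <- csp_fit(ep)
  oracle <- csp_oracle(ep)
  W <- model$filters
  expect_equal(t(W) %*% (oracle$S1 + oracle$S2) %*% W, diag(5),
               tolerance = 1e-8)
})

test_that("whiten-then-rotate equals the direct generalized eigenproblem", {
  set.seed(15)
  for (i in 1:100) {
    n_ch <- sample(2:6, 1)
    n_tr <- sample(4:20, 1) %/% 2 * 2
    dat <- array(rnorm(n_tr * n_ch * 80), c(n_tr, n_ch, 80))
    # inject class-dependent scaling so eigenvalues are distinct
    scales <- runif(n_ch, 0.5, 2)
    for (tr in which(rep(c(TRUE, FALSE), n_tr / 2))) {
      dat[tr, , ] <- diag(scales, n_ch) %*% matrix(dat[tr, , ], n_ch)
    }
    ep <- bci_epochs(dat, c(0, 1), rep(c("MA", "BL"), n_tr / 2), 80, "EEG")
    model <- csp_fit(ep)
    oracle <- csp_oracle(ep)
    expect_true(all(model$eigenvalues >= 0 & model$eigenvalues <= 1))
    expect_equal(model$eigenvalues, oracle$values, tolerance = 1e-7)
    # filters agree up to sign and scale when eigenvalues are distinct
    if (min(abs(diff(oracle$values))) > 1e-3) {
      for (k in seq_len(n_ch)) {
        a <- model$filters[, k] / sqrt(sum(model$filters[, k]^2))
        b <- oracle$vectors[, k] / sqrt(sum(oracle$vectors[, k]^2))
        expect_gt(abs(sum(a * b)), 1 - 1e-6)
      }
    }
  }
})

test_that("ratio-of-medians scores are robust where mean-based scores are not", {
  expect_equal(ratio_of_medians(c(4, 4, 1, 1), c("MA", "MA", "BL", "BL")), 0.8)
  expect_equal(ratio_of_medians(c(3, 3, 3, 3), c("MA", "MA", "BL", "BL")), 0.5)

  v <- c(1.9, 2, 2.1, 2.05, 1.95, 1, 1.1, 0.9) # median(MA) = 2, median(BL) = 1
  lab <- c(rep("MA", 5), rep("BL", 3))
  base <- ratio_of_medians(v, lab)
  v_out <- v; v_out[4] <- 1000 # extreme outlier above the median: unchanged
  expect_equal(ratio_of_medians(v_out, lab), base)
  mean_score <- function(v) mean(v[lab == "MA"]) /
    (mean(v[lab == "MA"]) + mean(v[lab == "BL"]))
  expect_false(isTRUE(all.equal(mean_score(v_out), mean_score(v))))
})

test_that("log-variance features scale and guard degenerate trials", {
  set.seed(16)
  ep <- epochs_with_cov(diag(c(4, 1, 2, 1, 1, 3)), diag(c(1, 4, 1, 2, 3, 1)),
                        n_per_class = 6, n_samp = 200)
  model <- csp_fit(ep)
  f <- csp_logvar(ep, model)
  expect_equal(ncol(f) - 1, 6)
  expect_true(all(is.finite(as.matrix(f[1:6]))))

  # scaling a trial by c shifts every unnormalized log variance by 2 log c
  f_raw <- csp_logvar(ep, model, normalize = FALSE)
  ep_scaled <- ep
  ep_scaled$data[1, , ] <- 3 * ep$data[1, , ]
  f_scaled <- csp_logvar(ep_scaled, model, normalize = FALSE)
  expect_equal(as.numeric(f_scaled[1, 1:6] - f_raw[1, 1:6]),
               rep(2 * log(3), 6), tolerance = 1e-9)

  ep_zero <- ep
  ep_zero$data[2, , ] <- 0
  expect_error(csp_logvar(ep_zero, model), "zero-variance")
})

test_that("few-channel data selects symmetrically fewer components", {
  set.seed(17)
  ep <- epochs_with_cov(diag(c(4, 1)), diag(c(1, 4)),
                        n_per_class = 6, n_samp = 100)
  model <- csp_fit(ep)
  expect_equal(length(model$selected_idx), 2)
})
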