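test_that("ITR closed form: chance gives zero, certainty gives m bits", {
  expect_equal(compute_itr(0.5), 0)
  expect_equal(compute_itr(1, m = 6), 6)
  expect_equal(compute_itr(50), 0)     # percent scale auto-detected
  expect_equal(compute_itr(100, m = 6), 6)
  expect_error(compute_itr(0), "accuracy")
  expect_warning(compute_itr(0.3), "below chance")
})

test_that("ITR is strictly increasing and convex above chance", {
  p <- seq(0.51, 1, by = 0.005)
  itr <- compute_itr(p)
  expect_true(all(diff(itr) > 0))
  expect_true(all(diff(diff(itr)) > -1e-10)) # convex
  # Jensen: mean of per-participant ITRs >= ITR of the mean accuracy
  tb <- reference_accuracy()
  expect_gte(mean(compute_itr(tb$hyb)), compute_itr(mean(tb$hyb)))
})

test_that("accuracy table summaries count hybrid improvements", {
  tb <- tibble::tibble(eeg = c(70, 80, 90), nirs = c(75, 70, 85),
                       hyb = c(80, 85, 88))
  s <- summarize_accuracy(tb)
  expect_equal(s$n_improved_eeg, 2)
  expect_equal(s$n_improved_nirs, 3)
  expect_equal(s$summary$mean[s$summary$modality == "EEG"], 80)

  same <- tibble::tibble(eeg = c(70, 80), nirs = c(70, 80), hyb = c(70, 80))
  expect_equal(summarize_accuracy(same)$n_improved_eeg, 0)
  expect_error(summarize_accuracy(tibble::tibble(eeg = 1, nirs = 1, hyb = 1)),
               "2 rows")
})

test_that("Friedman test matches the rank formula", {
  same <- matrix(rep(c(5, 5, 5), 4), 4, 3, byrow = TRUE) +
    matrix(rep(1:4, 3), 4, 3) # identical conditions per row
  ft0 <- friedman_test(same)
  expect_equal(ft0$statistic, 0)
  expect_equal(ft0$p.value, 1)

  ordered3 <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3, byrow = TRUE)
  ft <- friedman_test(ordered3)
  expect_equal(ft$statistic, 6)

  # statistic oracle: 12/(nk(k+1)) * sum_j (R_j - n(k+1)/2)^2 on random data
  set.seed(91)
  for (i in 1:10) {
    m <- matrix(rnorm(4 * 3), 4, 3)
    R <- colSums(t(apply(m, 1, rank)))
    stat <- 12 / (4 * 3 * 4) * sum((R - 4 * 4 / 2)^2)
    expect_equal(friedman_test(m)$statistic, stat, tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon signed-rank handles ties and matches enumeration", {
  # uniformly signed differences: the extreme tail of the exact null
  wt <- wilcoxon_signed_rank(rep(2, 12), rep(1, 12))
  expect_equal(wt$p.value, 2 / 2^12, tolerance = 1e-12)

  # symmetric alternating differences give p = 1
  a <- rep(0, 10); b <- rep(c(1, -1), 5)
  expect_equal(wilcoxon_signed_rank(a, b)$p.value, 1)

  # brute-force enumeration oracle at n = 6
  set.seed(92)
  for (i in 1:6) {
    d <- round(rnorm(6), 2)
    d[d == 0] <- 0.5
    rk <- rank(abs(d))
    w_obs <- sum(rk[d > 0])
    center <- sum(rk) / 2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
    w_all <- signs %*% rk
    p_exact <- mean(abs(w_all - center) >= abs(w_obs - center) - 1e-12)
    got <- wilcoxon_signed_rank(d, rep(0, 6)) # exact differences, ties kept

    expect_equal(got$statistic, w_obs)
    expect_equal(got$p.value, p_exact, tolerance = 1e-12)
  }

  expect_error(wilcoxon_signed_rank(1:3, 1:3), "zero")
})

test_that("BH adjustment follows the step-up construction", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(93)
  p <- runif(20)
  expect_true(all(fdr_adjust(p) >= p))
  expect_true(all(fdr_adjust(p) <= 1))
  # rejection-set nesting across thresholds
  adj <- fdr_adjust(p)
  expect_true(all(which(adj <= 0.1) %in% which(adj <= 0.2)))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("modality comparison report is coherent", {
  rep_out <- compare_modalities(reference_accuracy())
  expect_equal(nrow(rep_out$pairwise), 3)
  expect_true(all(rep_out$pairwise$p.adjusted >= rep_out$pairwise$p.value))
  expect_true(all(rep_out$pairwise$p.adjusted <= 1))
  expect_gt(rep_out$omnibus$statistic, 0)
})
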