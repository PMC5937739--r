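#' Information transfer rate
#'
#' Wolpaw-style ITR in bits per minute:
#' \deqn{ITR = m\left(\log_2 N + P\log_2 P + (1-P)\log_2\frac{1-P}{N-1}\right)}
#' where `m` is trials per minute, `N` the number of task types and `P` the
#' classification accuracy. `P = 1` uses the `0 log 0 := 0` convention; with
#' a 10 s trial and two classes the defaults give 6 bits/min at `P = 1` and
#' 0 at chance. Accuracies below `1/N` yield negative rates (returned as-is
#' with a warning).
#'
#' @param accuracy Accuracy as a proportion in (0, 1\], or percent in
#'   (1, 100\] (auto-detected per element: values > 1 are divided by 100).
#' @param m Trials per minute (default 6: a 10 s trial).
#' @param n_classes Number of task types, >= 2.
#'
#' @return Bits per minute, vectorized over `accuracy`.
#' @export
#' @examples
#' compute_itr(0.5) # 0 bits/min at chance
#' compute_itr(1)   # 6 bits/min
compute_itr <- function(accuracy, m = 6, n_classes = 2) {
  assert_that(n_classes >= 2, "n_classes must be >= 2")
  assert_that(m > 0, "m must be positive")
  p <- ifelse(accuracy > 1, accuracy / 100, accuracy)
  assert_that(all(p > 0 & p <= 1), "accuracy must lie in (0, 1] (or (1, 100])")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  qlogq <- ifelse(p < 1, (1 - p) * log2((1 - p) / (n_classes - 1)), 0)
  itr <- m * (log2(n_classes) + plogp + qlogq)
  if (any(p < 1 / n_classes)) {
    warn("accuracy below chance: negative ITR returned as-is")
  }
  itr
}

#' Published benchmark accuracy table
#'
#' Per-participant offline classification accuracies (percent) of a
#' 12-participant eyes-closed frontal hybrid EEG-fNIRS study: unimodal EEG,
#' unimodal NIRS (HbR+HbO fusion), the full hybrid (HYB), and the most
#' frequently selected participant-specific EEG passband. Shipped as a
#' plain-text fixture so the summary statistics and ITRs are reproducible
#' without any download.
#'
#' @return Tibble with columns `participant`, `eeg`, `f_low`, `f_high`,
#'   `nirs`, `hyb`.
#' @export
reference_accuracy <- function() {
  path <- system.file("extdata", "reference_accuracy.tsv",
                      package = "hybridbci", mustWork = TRUE)
  tb <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  tibble::as_tibble(tb)
}

#' Summarize an accuracy table
#'
#' Column means and standard deviations plus hybrid-improvement counts for
#' a per-participant accuracy table.
#'
#' @param table Data frame with numeric columns `eeg`, `nirs`, `hyb`
#'   (percent).
#'
#' @return List with `summary` (tibble modality/mean/sd), `n_improved_eeg`
#'   and `n_improved_nirs` (rows with `hyb` strictly greater), and
#'   `improvement_fraction` (fraction of rows improved over EEG, in
#'   percent).
#' @export
summarize_accuracy <- function(table) {
  assert_that(all(c("eeg", "nirs", "hyb") %in% names(table)),
              "table needs eeg, nirs, hyb columns")
  assert_that(nrow(table) >= 2, "need at least 2 rows")
  assert_that(!anyNA(table[c("eeg", "nirs", "hyb")]), "missing cells")
  cols <- c("eeg", "nirs", "hyb")
  smry <- tibble::tibble(
    modality = toupper(cols),
    mean = unname(vapply(cols, function(cl) mean(table[[cl]]), numeric(1))),
    sd = unname(vapply(cols, function(cl) sd(table[[cl]]), numeric(1)))
  )
  list(
    summary = smry,
    n_improved_eeg = sum(table$hyb > table$eeg),
    n_improved_nirs = sum(table$hyb > table$nirs),
    improvement_fraction = 100 * mean(table$hyb > table$eeg)
  )
}

#' Friedman rank test across conditions
#'
#' Nonparametric repeated-measures omnibus test (rows = participants,
#' columns = conditions) with average-rank tie handling; thin wrapper over
#' [stats::friedman.test()] returning a tidy row.
#'
#' @param mat Numeric matrix or data frame, participants x conditions.
#'
#' @return Tibble with `statistic`, `df`, `p.value`, `method`.
#' @export
friedman_test <- function(mat) {
  mat <- as.matrix(mat)
  assert_that(nrow(mat) >= 2 && ncol(mat) >= 2,
              "need >= 2 participants and >= 2 conditions")
  ft <- stats::friedman.test(mat)
  stat <- unname(ft$statistic); p <- ft$p.value
  # all conditions tied within every row: zero evidence, not undefined
  if (is.nan(stat)) {
    rank_var <- apply(mat, 1, function(r) var(rank(r)))
    if (all(rank_var == 0)) {
      stat <- 0; p <- 1
    }
  }
  tibble::tibble(statistic = stat,
                 df = unname(ft$parameter),
                 p.value = p,
                 method = "Friedman rank sum test")
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped; ties in
#' absolute differences get average ranks. For `n <= exact_max` non-zero
#' pairs the p-value is exact: the null distribution of the positive-rank
#' sum W+ over all 2^n sign assignments is built by convolution (ranks
#' doubled to integers), which is valid under ties, unlike the standard
#' exact routine. Larger samples use the normal approximation with
#' continuity and tie correction.
#'
#' @param a,b Paired numeric vectors.
#' @param exact_max Largest n for the exact enumeration (default 25).
#'
#' @return Tibble with `statistic` (W+), `n` (non-zero pairs), `p.value`,
#'   `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(rep(2, 12), rep(1, 12)) # p = 2 / 2^12
wilcoxon_signed_rank <- function(a, b, exact_max = 25) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("all differences are zero")
  if (n < 5) warn("fewer than 5 non-zero differences: test is very weak")
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  if (n <= exact_max) {
    # distribution of W+ over sign flips; double ranks so they are integers
    r2 <- as.integer(round(2 * rk))
    total <- sum(r2)
    dist <- c(1, numeric(total)) # dist[k+1] = #assignments with 2*W+ = k
    for (r in r2) {
      shifted <- c(numeric(r), dist[seq_len(total + 1 - r)])
      dist <- dist + shifted
    }
    probs <- dist / 2^n
    support <- (0:total) / 2
    center <- total / 4 # = n(n+1)/4 on the W+ scale since total = 2*sum(rk)
    dev <- abs(support - center)
    p <- sum(probs[dev >= abs(w - center) - 1e-12])
    method <- "exact Wilcoxon signed-rank (convolution)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation Wilcoxon signed-rank"
  }
  tibble::tibble(statistic = w, n = n, p.value = min(1, p), method = method)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment via [stats::p.adjust()]: sorted p-values are scaled by
#' m/rank, monotonicity is enforced from the largest down, values are capped
#' at 1, and the original order is restored.
#'
#' @param p Numeric p-values in \[0, 1\].
#'
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.04)) # 0.03 0.03 0.04
fdr_adjust <- function(p) {
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Omnibus and pairwise modality comparison
#'
#' The statistical report of a per-participant accuracy table: Friedman
#' omnibus over the three modalities, pairwise exact Wilcoxon signed-rank
#' post-hocs, and Benjamini-Hochberg correction of the pairwise p-values.
#'
#' @param table Data frame with columns `eeg`, `nirs`, `hyb`.
#'
#' @return List with `omnibus` (tibble) and `pairwise` (tibble with raw and
#'   FDR-adjusted p-values).
#' @export
compare_modalities <- function(table) {
  mat <- as.matrix(table[c("eeg", "nirs", "hyb")])
  omnibus <- friedman_test(mat)
  pairs <- list(c("eeg", "nirs"), c("eeg", "hyb"), c("nirs", "hyb"))
  pw <- purrr::map_dfr(pairs, function(pr) {
    wt <- wilcoxon_signed_rank(table[[pr[1]]], table[[pr[2]]])
    tibble::tibble(comparison = paste(toupper(pr), collapse = " vs "),
                   statistic = wt$statistic, p.value = wt$p.value)
  })
  pw$p.adjusted <- fdr_adjust(pw$p.value)
  list(omnibus = omnibus, pairwise = pw)
}

#' Analysis-window sweep
#'
#' Re-runs the cross-validated decoder over a grid of EEG and NIRS analysis
#' windows (one axis varied at a time is the usual reading: fix one window
#' and pass several for the other).
#'
#' @param recording A [bci_recording].
#' @param eeg_windows,nirs_windows Lists of `c(start, end)` windows, seconds
#'   from task onset.
#' @param repetitions,folds,seed Passed to [cross_validate()].
#' @param ... Passed to [preprocess_recording()].
#'
#' @return Tibble: one row per (eeg_window, nirs_window, modality) with the
#'   mean cross-validated accuracy.
#' @export
window_sweep <- function(recording, eeg_windows = list(c(0, 10)),
                         nirs_windows = list(c(10, 15)),
                         repetitions = 3, folds = 5, seed = 1, ...) {
  grid <- expand.grid(e = seq_along(eeg_windows),
                      n = seq_along(nirs_windows))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    ew <- eeg_windows[[grid$e[i]]]
    nw <- nirs_windows[[grid$n[i]]]
    prep <- preprocess_recording(recording, eeg_window_s = ew,
                                 nirs_window_s = nw, ...)
    cv <- cross_validate(prep, repetitions = repetitions, folds = folds,
                         seed = seed)
    g <- glance(cv)
    tibble::tibble(
      eeg_window = sprintf("[%g, %g)", ew[1], ew[2]),
      nirs_window = sprintf("[%g, %g)", nw[1], nw[2]),
      modality = g$modality, mean_accuracy = g$mean_accuracy
    )
  })
}
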