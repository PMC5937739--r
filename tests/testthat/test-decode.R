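test_that("meta-classifier fuses base scores with one dimension per member", {
  set.seed(61)
  n <- 100
  y <- rep(c("MA", "BL"), each = n / 2)
  scores <- tibble::tibble(
    EEG = ifelse(y == "MA", 1, -1) + rnorm(n, sd = 0.2), # near-perfect
    HbR = rnorm(n),                                      # chance
    HbO = rnorm(n)
  )
  meta <- fuse_meta(scores, y, c("EEG", "HbR", "HbO"))
  expect_equal(length(meta$w), 3)

  # fresh test data from the same generator
  y2 <- rep(c("MA", "BL"), each = n / 2)
  test_scores <- tibble::tibble(
    EEG = ifelse(y2 == "MA", 1, -1) + rnorm(n, sd = 0.2),
    HbR = rnorm(n), HbO = rnorm(n)
  )
  acc_meta <- mean(as.character(
    slda_score(meta, as.matrix(test_scores))$label) == y2) * 100
  acc_base <- mean((test_scores$EEG > 0) == (y2 == "MA")) * 100
  expect_gte(acc_meta, acc_base - 5)

  # duplicating a member's scores leaves accuracy essentially unchanged
  meta_dup <- fuse_meta(tibble::tibble(EEG = scores$EEG, HbR = scores$EEG,
                                       HbO = scores$HbO), y,
                        c("EEG", "HbR", "HbO"))
  test_dup <- tibble::tibble(EEG = test_scores$EEG, HbR = test_scores$EEG,
                             HbO = test_scores$HbO)
  acc_dup <- mean(as.character(
    slda_score(meta_dup, as.matrix(test_dup))$label) == y2) * 100
  expect_lt(abs(acc_dup - acc_meta), 6)

  expect_error(fuse_meta(scores, y, "EEG"), "at least 2")
})

test_that("cross-validation structure: 50 records, stratified, reproducible", {
  prep <- small_prep()
  cv <- cross_validate(prep, repetitions = 2, folds = 3, seed = 99)
  expect_equal(nrow(cv$folds), 2 * 3 * 7) # 7 modalities/fusions
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 100))

  # every trial appears exactly once per repetition in the test folds
  per_rep <- dplyr::filter(cv$predictions, modality == "EEG")
  counts <- table(per_rep$repetition, per_rep$trial)
  expect_true(all(counts == 1))

  cv2 <- cross_validate(prep, repetitions = 2, folds = 3, seed = 99)
  expect_identical(cv$folds, cv2$folds)
  cv3 <- cross_validate(prep, repetitions = 2, folds = 3, seed = 100)
  expect_false(identical(cv$folds, cv3$folds))

  g <- glance(cv)
  expect_setequal(
    g$modality,
    c("EEG", "HbR", "HbO", "HbR+HbO", "EEG+HbR", "EEG+HbO", "EEG+HbR+HbO"))
})

test_that("band selection and CSP are train-only (no test leakage)", {
  prep <- small_prep()
  cv_ref <- cross_validate(prep, repetitions = 1, folds = 3, seed = 5)

  # corrupt the *test* trials of the first fold; the selected band for that
  # fold must not change (it is fitted on training trials only)
  first_fold <- dplyr::filter(cv_ref$predictions, fold == 1,
                              modality == "EEG")
  test_idx <- unique(first_fold$trial)
  prep2 <- prep
  set.seed(1)
  prep2$eeg$data[test_idx, , ] <-
    prep2$eeg$data[test_idx, , ] +
    array(rnorm(length(test_idx) * prod(dim(prep2$eeg$data)[2:3]), sd = 50),
          c(length(test_idx), dim(prep2$eeg$data)[2:3]))
  cv_mod <- cross_validate(prep2, repetitions = 1, folds = 3, seed = 5)
  band_ref <- dplyr::filter(cv_ref$folds, fold == 1,
                            modality == "EEG")
  band_mod <- dplyr::filter(cv_mod$folds, fold == 1,
                            modality == "EEG")
  expect_equal(band_ref$f_low, band_mod$f_low)
  expect_equal(band_ref$f_high, band_mod$f_high)
})

test_that("stratification keeps per-fold class imbalance within one trial", {
  set.seed(77)
  labels <- factor(rep(c("MA", "BL"), 15), levels = c("MA", "BL"))
  for (k in c(3, 5)) {
    assignment <- hybridbci:::stratified_folds(labels, k)
    for (f in seq_len(k)) {
      tab <- table(labels[assignment == f])
      expect_lte(abs(tab[["MA"]] - tab[["BL"]]), 1)
    }
  }
})
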