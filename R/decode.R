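#' Train a meta-classifier over base classifier scores
#'
#' Stacking fusion: the continuous sLDA scores of the member modalities are
#' concatenated into a new feature vector (one dimension per member) and a
#' second-level sLDA is trained on it. For leakage-free stacking the
#' training scores must be produced out-of-sample (an inner split), which
#' [cross_validate()] enforces.
#'
#' @param base_scores Data frame / tibble of continuous base-classifier
#'   scores, one column per modality, one row per trial.
#' @param labels Per-trial labels.
#' @param members Character vector naming the score columns to fuse
#'   (>= 2), e.g. `c("EEG", "HbR", "HbO")`.
#'
#' @return A `bci_slda` meta-model expecting `length(members)` features.
#' @export
fuse_meta <- function(base_scores, labels, members) {
  assert_that(length(members) >= 2, "a fusion needs at least 2 members")
  assert_that(all(members %in% names(base_scores)),
              "members must name score columns")
  X <- as.matrix(base_scores[members])
  slda_fit(X, labels)
}

FUSION_SPECS <- list(
  "HbR+HbO" = c("HbR", "HbO"),
  "EEG+HbR" = c("EEG", "HbR"),
  "EEG+HbO" = c("EEG", "HbO"),
  "EEG+HbR+HbO" = c("EEG", "HbR", "HbO")
)

#' Nested cross-validated decoding of a preprocessed dataset
#'
#' Repeated stratified k-fold cross-validation (default 10 x 5) of the full
#' decoding pipeline. Within every outer training fold the participant-
#' specific passband is re-selected, the CSP filters are re-fit, and base
#' sLDA classifiers for EEG log-variance, HbR and HbO mean/slope features
#' are trained; an inner stratified split (default 8-fold) generates
#' out-of-sample base scores on which the meta-classifiers for the fusion
#' combinations HbR+HbO, EEG+HbR, EEG+HbO and EEG+HbR+HbO are trained, so
#' the meta level never sees resubstitution scores. Test trials are only
#' ever touched by fully fitted models.
#'
#' @param prep Output of [preprocess_recording()] (broadband EEG epochs plus
#'   HbO/HbR epochs).
#' @param repetitions,folds Outer CV structure (default 10 x 5).
#' @param inner_folds Inner folds for meta-score generation.
#' @param seed Integer; the master seed spawning per-repetition partitions.
#' @param band_args List of arguments forwarded to [select_band()].
#'
#' @return A `bci_cv_result`: `folds` tibble (repetition, fold, modality,
#'   accuracy in percent, selected band), `predictions` tibble, `seed`.
#' @export
cross_validate <- function(prep, repetitions = 10, folds = 5,
                           inner_folds = 8, seed = 1,
                           band_args = list()) {
  eeg <- prep$eeg; hbo <- prep$hbo; hbr <- prep$hbr
  labels <- eeg$labels
  n <- n_trials(eeg)
  assert_that(identical(as.character(labels), as.character(hbo$labels)) &&
                identical(as.character(labels), as.character(hbr$labels)),
              "mismatched trial alignment across modalities")
  assert_that(min(table(labels)) >= folds,
              "need at least `folds` trials per class")

  # trial-wise quantities that involve no cross-trial fitting can be
  # computed once: Welch spectra (band selection input) and the
  # hemodynamic mean/slope features
  psd <- epochs_psd(eeg)
  feat_hbo <- nirs_mean_slope(hbo)
  feat_hbr <- nirs_mean_slope(hbr)

  band_cache <- new.env(parent = emptyenv())
  filtered_for_band <- function(band) {
    key <- sprintf("%.3f_%.3f", band[1], band[2])
    if (!is.null(band_cache[[key]])) return(band_cache[[key]])
    spec <- filter_spec(band, order = 3)
    d <- dim(eeg$data)
    out <- eeg$data
    for (i in seq_len(d[1])) {
      out[i, , ] <- bandpass(matrix(eeg$data[i, , ], d[2], d[3]),
                             spec, eeg$rate_hz)
    }
    band_cache[[key]] <- out
    out
  }

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, repetitions)

  fold_rows <- list()
  pred_rows <- list()
  for (r in seq_len(repetitions)) {
    set.seed(rep_seeds[r])
    assignment <- stratified_folds(labels, folds)
    for (f in seq_len(folds)) {
      test_idx <- which(assignment == f)
      train_idx <- which(assignment != f)

      band_sel <- do.call(select_band, c(
        list(epochs = epochs_subset(eeg, train_idx),
             psd = list(freq = psd$freq,
                        power = psd$power[train_idx, , , drop = FALSE])),
        band_args))
      band <- c(band_sel$f_low, band_sel$f_high)

      filt <- filtered_for_band(band)
      eeg_band <- bci_epochs(filt, eeg$window_s, labels, eeg$rate_hz,
                             "EEG", eeg$channels)
      csp <- csp_fit(epochs_subset(eeg_band, train_idx), band = band)
      feat_eeg <- csp_logvar(eeg_band, csp)

      train_feats <- list(
        EEG = feat_eeg[train_idx, ],
        HbR = feat_hbr[train_idx, ],
        HbO = feat_hbo[train_idx, ]
      )
      test_feats <- list(
        EEG = feat_eeg[test_idx, ],
        HbR = feat_hbr[test_idx, ],
        HbO = feat_hbo[test_idx, ]
      )
      y_train <- labels[train_idx]
      y_test <- labels[test_idx]

      base <- lapply(train_feats, slda_fit)
      ts <- lapply(names(base), function(m) {
        slda_score(base[[m]], test_feats[[m]])$score
      })
      names(ts) <- names(base)
      test_scores <- tibble::as_tibble(ts)

      # inner out-of-fold stacking scores on the outer training fold
      inner_assign <- stratified_folds(y_train, inner_folds)
      oof <- matrix(NA_real_, length(train_idx), 3,
                    dimnames = list(NULL, names(base)))
      for (g in seq_len(inner_folds)) {
        g_test <- which(inner_assign == g)
        g_train <- which(inner_assign != g)
        for (m in names(base)) {
          mod <- slda_fit(train_feats[[m]][g_train, ])
          oof[g_test, m] <- slda_score(
            mod, train_feats[[m]][g_test, ])$score
        }
      }
      oof <- tibble::as_tibble(oof)

      preds <- lapply(ts, function(s) {
        factor(ifelse(s > 0, "MA", "BL"), levels = c("MA", "BL"))
      })
      acc <- vapply(preds, accuracy_pct, numeric(1), truth = y_test)
      for (spec_name in names(FUSION_SPECS)) {
        members <- FUSION_SPECS[[spec_name]]
        meta <- fuse_meta(oof, y_train, members)
        pred <- slda_score(meta, as.matrix(test_scores[members]))$label
        acc[spec_name] <- accuracy_pct(pred, y_test)
        preds[[spec_name]] <- pred
      }

      fold_rows[[length(fold_rows) + 1]] <- tibble::tibble(
        repetition = r, fold = f, modality = names(acc),
        accuracy = unname(acc),
        f_low = band[1], f_high = band[2], n_test = length(test_idx)
      )
      pred_rows[[length(pred_rows) + 1]] <- tibble::tibble(
        repetition = r, fold = f, trial = rep(test_idx, length(preds)),
        modality = rep(names(preds), each = length(test_idx)),
        predicted = unlist(lapply(preds, as.character), use.names = FALSE),
        truth = rep(as.character(y_test), length(preds))
      )
    }
  }

  structure(
    list(folds = dplyr::bind_rows(fold_rows),
         predictions = dplyr::bind_rows(pred_rows),
         repetitions = repetitions, n_folds = folds, seed = seed,
         n_trials = n),
    class = "bci_cv_result"
  )
}

accuracy_pct <- function(predicted, truth) {
  100 * mean(as.character(predicted) == as.character(truth))
}

# stratified fold assignment; per-fold class imbalance <= 1 trial
stratified_folds <- function(labels, k) {
  assignment <- integer(length(labels))
  for (cl in unique(as.character(labels))) {
    idx <- which(as.character(labels) == cl)
    idx <- sample(idx)
    assignment[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  assignment
}

#' @export
print.bci_cv_result <- function(x, ...) {
  cat(sprintf("<bci_cv_result> %d x %d-fold CV, %d trials, seed %d\n",
              x$repetitions, x$n_folds, x$n_trials, x$seed))
  print(glance(x))
  invisible(x)
}

#' @export
#' @rdname cross_validate
#' @param x A `bci_cv_result`.
#' @param ... Unused.
tidy.bci_cv_result <- function(x, ...) {
  x$folds
}

#' @export
#' @rdname cross_validate
glance.bci_cv_result <- function(x, ...) {
  out <- x$folds |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = sd(.data$accuracy),
                     n_folds = dplyr::n(), .groups = "drop")
  # conventional aliases: NIRS = HbR+HbO fusion, HYB = EEG+HbR+HbO
  out$alias <- dplyr::case_match(out$modality,
                                 "HbR+HbO" ~ "NIRS",
                                 "EEG+HbR+HbO" ~ "HYB",
                                 .default = NA_character_)
  out
}
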