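#' Fit common spatial patterns
#'
#' Computes CSP spatial filters for two-class epochs already band-passed to
#' the discriminative band. Per-trial channel covariances are normalized by
#' their trace and averaged within class (`Sigma1` = MA, `Sigma2` = BL); the
#' filters solve the generalized eigenproblem
#' \eqn{\Sigma_1 w = \lambda (\Sigma_1 + \Sigma_2) w}, realized by whitening
#' the composite covariance and rotating (numerically stable and exactly
#' equivalent). Eigenvalues lie in \[0, 1\] and are sorted descending; the
#' whitening identity \eqn{W^T(\Sigma_1+\Sigma_2)W = I} holds on the
#' training covariances. Components are then scored by the ratio-of-medians
#' of projected trial variances and the three most discriminative per side
#' are selected.
#'
#' @param epochs Training [bci_epochs], band-passed to `band`.
#' @param band Optional `c(f_low, f_high)` recorded on the model.
#' @param n_select Components per side (default 3; reduced symmetrically
#'   when fewer channels are available).
#' @param reg Identity regularization added to the composite covariance
#'   relative to its trace when near-singular.
#'
#' @return A `bci_csp` model: `filters` (channels x components), `patterns`,
#'   `eigenvalues`, `scores` (ratio-of-medians), `selected_idx`, `band`.
#' @export
csp_fit <- function(epochs, band = NULL, n_select = 3, reg = 1e-8) {
  labels <- epochs$labels
  assert_that(all(table(labels) >= 2), "need at least 2 trials per class")
  d <- dim(epochs$data)
  covs <- class_covariances(epochs)
  S1 <- covs$S1; S2 <- covs$S2
  C <- S1 + S2
  e_c <- eigen(C, symmetric = TRUE)
  # ridge only when the composite covariance is actually ill-conditioned,
  # so the whitening identity stays exact in the regular case
  if (min(e_c$values) < 1e-10 * max(e_c$values)) {
    C <- C + diag(reg * sum(diag(C)) / d[2], d[2])
    e_c <- eigen(C, symmetric = TRUE)
  }
  if (min(e_c$values) <= 0) {
    abort("composite covariance is rank-deficient after regularization")
  }
  # whiten-then-rotate: P C P^T = I, then eigendecompose P S1 P^T
  P <- diag(1 / sqrt(e_c$values)) %*% t(e_c$vectors)
  e_w <- eigen(P %*% S1 %*% t(P), symmetric = TRUE) # values in [0,1], desc
  W <- t(e_w$vectors) %*% P            # components x channels
  filters <- t(W)                      # channels x components
  lambda <- pmin(pmax(e_w$values, 0), 1)

  # ratio-of-medians component scoring on the training trials
  v <- project_variances(epochs$data, filters)
  scores <- ratio_of_medians(v, labels)
  k <- min(n_select, floor(d[2] / 2))
  ord <- order(abs(scores - 0.5), decreasing = TRUE)
  # pick k components with largest score (> 0.5 side) and k with smallest,
  # ties broken by eigenvalue order
  side_hi <- order(-scores, seq_along(scores))[seq_len(k)]
  side_lo <- order(scores, -seq_along(scores))[seq_len(k)]
  selected <- c(side_hi, side_lo)

  structure(
    list(filters = filters, patterns = pseudo_inverse(W),
         eigenvalues = lambda, scores = scores,
         selected_idx = selected, band = band,
         channels = epochs$channels, n_per_side = k, ord = ord),
    class = "bci_csp"
  )
}

# trials x components matrix of projected variances
project_variances <- function(data, filters) {
  d <- dim(data)
  out <- matrix(NA_real_, d[1], ncol(filters))
  for (i in seq_len(d[1])) {
    proj <- t(filters) %*% matrix(data[i, , ], d[2], d[3])
    out[i, ] <- apply(proj, 1, var)
  }
  out
}

# class-averaged, trace-normalized trial covariances
class_covariances <- function(epochs) {
  d <- dim(epochs$data)
  acc <- list(MA = matrix(0, d[2], d[2]), BL = matrix(0, d[2], d[2]))
  n <- c(MA = 0, BL = 0)
  for (i in seq_len(d[1])) {
    x <- matrix(epochs$data[i, , ], d[2], d[3])
    x <- x - rowMeans(x)
    S <- tcrossprod(x) / (d[3] - 1)
    S <- S / sum(diag(S))
    lab <- as.character(epochs$labels[i])
    acc[[lab]] <- acc[[lab]] + S
    n[lab] <- n[lab] + 1
  }
  list(S1 = acc$MA / n["MA"], S2 = acc$BL / n["BL"])
}

#' Ratio-of-medians component score
#'
#' Robust class-discriminability score of per-trial component variances:
#' `median(v | MA) / (median(v | MA) + median(v | BL))`, in (0, 1); 0.5
#' means no class difference. Using medians instead of means makes the score
#' insensitive to outlier trials.
#'
#' @param variances Per-trial variances: vector, or trials x components
#'   matrix.
#' @param labels Per-trial `MA`/`BL` labels.
#'
#' @return Score per component.
#' @export
#' @examples
#' ratio_of_medians(c(4, 4, 1, 1), c("MA", "MA", "BL", "BL")) # 0.8
ratio_of_medians <- function(variances, labels) {
  labels <- as.character(labels)
  assert_that(all(c("MA", "BL") %in% labels), "both classes must be present")
  v <- cbind(variances)
  vapply(seq_len(ncol(v)), function(j) {
    m1 <- median(v[labels == "MA", j])
    m2 <- median(v[labels == "BL", j])
    assert_that(m1 + m2 > 0, "zero median variance in both classes")
    m1 / (m1 + m2)
  }, numeric(1))
}

#' Log-variance CSP features
#'
#' Projects epochs through the selected CSP components and returns, per
#' trial and component, the log of the component-signal variance normalized
#' by the total variance across the selected components (normalization
#' switchable).
#'
#' @param epochs [bci_epochs] band-passed with the model's band.
#' @param model A `bci_csp` from [csp_fit()].
#' @param normalize Divide each component variance by the trial's total
#'   selected-component variance before the log (default TRUE).
#' @param floor Relative variance floor replacing zero-variance projections
#'   (flagged with a warning).
#'
#' @return Feature tibble (class `bci_features`): columns `csp<k>_logvar`
#'   plus `label`.
#' @export
csp_logvar <- function(epochs, model, normalize = TRUE, floor = 1e-12) {
  v <- project_variances(epochs$data, model$filters)
  v <- v[, model$selected_idx, drop = FALSE]
  tot <- rowSums(v)
  if (any(tot <= 0)) {
    abort(sprintf("zero-variance projected trial (trial %d)",
                  which(tot <= 0)[1]))
  }
  if (any(v <= 0)) {
    warn("zero-variance component projection floored")
    v <- pmax(v, floor * tot)
  }
  feats <- if (normalize) log(v / tot) else log(v)
  colnames(feats) <- sprintf("csp%d_logvar", model$selected_idx)
  out <- tibble::as_tibble(feats)
  out$label <- epochs$labels
  attr(out, "modality") <- "EEG"
  class(out) <- c("bci_features", class(out))
  out
}

#' @export
print.bci_csp <- function(x, ...) {
  cat(sprintf("<bci_csp> %d channels, %d components (%d selected)\n",
              nrow(x$filters), ncol(x$filters), length(x$selected_idx)))
  if (!is.null(x$band)) {
    cat(sprintf("  band: [%.1f, %.1f] Hz\n", x$band[1], x$band[2]))
  }
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
tidy.bci_csp <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    ratio_of_medians = x$scores,
    selected = seq_along(x$eigenvalues) %in% x$selected_idx
  )
}
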