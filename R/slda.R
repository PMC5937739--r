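#' Fit a shrinkage linear discriminant classifier
#'
#' Two-class LDA with the pooled covariance shrunk toward a scaled identity:
#' \eqn{\tilde\Sigma = (1-\gamma)\hat\Sigma + \gamma\nu I} with
#' \eqn{\nu = \mathrm{tr}(\hat\Sigma)/d} and the shrinkage intensity
#' \eqn{\gamma} chosen analytically (Ledoit-Wolf). The weight vector is
#' \eqn{w = \tilde\Sigma^{-1}(m_{MA} - m_{BL})} and the bias puts the
#' decision boundary through the class-mean midpoint, so the score
#' \eqn{w^T x + b} is positive for MA.
#'
#' @param features Feature tibble/data frame with a `label` column, or a
#'   numeric matrix plus `labels`.
#' @param labels Per-trial labels when `features` is a matrix.
#' @param gamma Shrinkage intensity in \[0, 1\], or `"auto"` (analytic).
#'
#' @return A `bci_slda` model with `w`, `b`, `gamma`, `nu`, class means.
#' @export
slda_fit <- function(features, labels = NULL, gamma = "auto") {
  xy <- as_feature_matrix(features, labels)
  X <- xy$x; y <- xy$labels
  assert_that(all(table(y) >= 2), "need at least 2 trials per class")
  assert_that(all(is.finite(X)), "features must be finite")
  d <- ncol(X)
  m1 <- colMeans(X[y == "MA", , drop = FALSE])
  m2 <- colMeans(X[y == "BL", , drop = FALSE])
  # pool class-centered data
  Xc <- X
  Xc[y == "MA", ] <- sweep(X[y == "MA", , drop = FALSE], 2, m1)
  Xc[y == "BL", ] <- sweep(X[y == "BL", , drop = FALSE], 2, m2)
  n <- nrow(Xc)
  S <- crossprod(Xc) / n
  nu <- sum(diag(S)) / d
  if (identical(gamma, "auto")) {
    gamma <- ledoit_wolf_gamma(Xc, S, nu)
  }
  assert_that(gamma >= 0 && gamma <= 1, "gamma must lie in [0, 1]")
  S_shrunk <- (1 - gamma) * S + gamma * nu * diag(d)
  w <- solve(S_shrunk, m1 - m2)
  b <- -sum(w * (m1 + m2) / 2)
  structure(
    list(w = as.numeric(w), b = b, gamma = gamma, nu = nu,
         mean_ma = m1, mean_bl = m2, features = colnames(X)),
    class = "bci_slda"
  )
}

# analytic Ledoit-Wolf shrinkage intensity toward nu * I, from
# class-centered rows Xc (n x d) with S = Xc'Xc / n
ledoit_wolf_gamma <- function(Xc, S, nu) {
  n <- nrow(Xc); d <- ncol(S)
  delta2 <- sum((S - nu * diag(d))^2)
  if (delta2 < .Machine$double.eps) return(0)
  beta2 <- 0
  for (i in seq_len(n)) {
    beta2 <- beta2 + sum((tcrossprod(Xc[i, ]) - S)^2)
  }
  beta2 <- beta2 / n^2
  max(0, min(1, beta2 / delta2))
}

#' Score feature rows with a fitted sLDA
#'
#' @param model A `bci_slda`.
#' @param features Feature tibble (a `label` column is ignored) or numeric
#'   matrix/vector.
#'
#' @return Tibble with `score` (\eqn{w^T x + b}) and `label` (`MA` iff
#'   score > 0).
#' @export
slda_score <- function(model, features) {
  X <- as_feature_matrix(features, labels = NULL, require_labels = FALSE)$x
  assert_that(ncol(X) == length(model$w),
              sprintf("feature dimension %d does not match model (%d)",
                      ncol(X), length(model$w)))
  s <- as.numeric(X %*% model$w + model$b)
  tibble::tibble(score = s,
                 label = factor(ifelse(s > 0, "MA", "BL"),
                                levels = c("MA", "BL")))
}

#' @export
predict.bci_slda <- function(object, newdata, ...) {
  slda_score(object, newdata)
}

#' @export
print.bci_slda <- function(x, ...) {
  cat(sprintf("<bci_slda> %d features, gamma = %.3f, nu = %.3g\n",
              length(x$w), x$gamma, x$nu))
  invisible(x)
}

#' @export
tidy.bci_slda <- function(x, ...) {
  tibble::tibble(term = x$features %||% sprintf("x%d", seq_along(x$w)),
                 weight = x$w)
}

#' @export
glance.bci_slda <- function(x, ...) {
  tibble::tibble(n_features = length(x$w), gamma = x$gamma, nu = x$nu,
                 bias = x$b)
}

# features -> list(x = matrix, labels = factor or NULL)
as_feature_matrix <- function(features, labels = NULL, require_labels = TRUE) {
  if (is.data.frame(features)) {
    lab <- if ("label" %in% names(features)) features$label else labels
    x <- as.matrix(features[setdiff(names(features), "label")])
  } else {
    lab <- labels
    x <- rbind(features)
    if (!is.matrix(features) && is.null(dim(features))) x <- matrix(features, nrow = 1)
  }
  storage.mode(x) <- "double"
  if (require_labels) {
    assert_that(!is.null(lab), "labels are required")
    lab <- factor(as.character(lab), levels = c("MA", "BL"))
  }
  list(x = x, labels = lab)
}
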