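#' Linear discriminant analysis with canonical variates
#'
#' Classical LDA on a low-dimensional feature space (here: concatenated
#' PLS scores): equal priors, pooled within-class covariance, prediction by
#' minimum Mahalanobis distance to the class means. A small ridge
#' (`lambda * trace(S)/d` on the diagonal) keeps the pooled covariance
#' positive definite when cross-validation folds make it near-singular.
#'
#' Canonical variates — the directions maximizing the between- to
#' within-class variance ratio — are obtained from the symmetric
#' generalized eigenproblem of (within, between) via the Cholesky factor of
#' the regularized pooled covariance, and are scaled to unit pooled
#' within-class variance.
#'
#' @param T_ numeric n x d feature matrix.
#' @param labels class label per row; every class needs >= 2 rows.
#' @param lambda ridge coefficient for the pooled covariance
#'   regularization (default `1e-8`; `0` disables it).
#' @return An object of class `lda_model`: `class_names`, `class_means`
#'   (c x d), `pooled_cov` (regularized, d x d), `canonical_directions`
#'   (d x min(c-1, d), ordered by decreasing separation ratio),
#'   `canonical_ratios`, `grand_mean`.
#' @export
lda_fit <- function(T_, labels, lambda = 1e-8) {
  T_ <- as.matrix(T_)
  labels <- as.character(labels)
  n <- nrow(T_)
  d <- ncol(T_)
  if (length(labels) != n) stop("'labels' must have one entry per row")
  cls <- sort(unique(labels))
  cnt <- table(factor(labels, levels = cls))
  if (length(cls) < 2) stop("need at least 2 classes")
  if (any(cnt < 2)) {
    stop("class with fewer than 2 rows: ", names(cnt)[which(cnt < 2)[1L]])
  }
  M <- t(matrix(vapply(cls, function(cl) {
    colMeans(T_[labels == cl, , drop = FALSE])
  }, numeric(d)), nrow = d))
  Sw <- matrix(0, d, d)
  for (i in seq_along(cls)) {
    Xc <- T_[labels == cls[i], , drop = FALSE] -
      rep(M[i, ], each = cnt[i])
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (n - length(cls))
  if (lambda > 0) Sw <- Sw + diag(lambda * sum(diag(Sw)) / d, d)
  ch <- tryCatch(chol(Sw), error = function(e) {
    stop("pooled within-class covariance is singular; ",
         "increase the ridge 'lambda'")
  })
  gm <- colMeans(T_)
  # between-class scatter of the (equally weighted) class means
  Mc <- M - rep(colMeans(M), each = length(cls))
  Sb <- crossprod(Mc) / max(length(cls) - 1L, 1L)
  # chol gives upper R with Sw = R'R; whiten with inv(R)': A = inv(R)' Sb inv(R)
  Rinv <- backsolve(ch, diag(d))
  Aw <- t(Rinv) %*% Sb %*% Rinv
  Aw <- (Aw + t(Aw)) / 2
  eg <- eigen(Aw, symmetric = TRUE)
  ncv <- min(length(cls) - 1L, d)
  dirs <- Rinv %*% eg$vectors[, seq_len(ncv), drop = FALSE]
  structure(
    list(class_names = cls, class_means = M, pooled_cov = Sw,
         canonical_directions = dirs,
         canonical_ratios = eg$values[seq_len(ncv)],
         grand_mean = gm, chol_cov = ch, lambda = lambda),
    class = "lda_model")
}

#' @rdname lda_fit
#' @param model a fitted `lda_model`.
#' @param T_new feature rows to classify.
#' @return `lda_predict`: character vector of predicted class labels
#'   (minimum Mahalanobis distance under the pooled covariance, equal
#'   priors).
#' @export
lda_predict <- function(model, T_new) {
  stopifnot(inherits(model, "lda_model"))
  T_new <- as.matrix(T_new)
  if (ncol(T_new) != ncol(model$class_means)) {
    stop("feature dimension does not match the fitted model")
  }
  d2 <- mahalanobis_to_means(model, T_new)
  model$class_names[max.col(-d2, ties.method = "first")]
}

# squared Mahalanobis distances to every class mean (n x c)
mahalanobis_to_means <- function(model, T_new) {
  ch <- model$chol_cov
  d2 <- vapply(seq_along(model$class_names), function(i) {
    D <- T_new - rep(model$class_means[i, ], each = nrow(T_new))
    Z <- t(backsolve(ch, t(D), transpose = TRUE))
    rowSums(Z^2)
  }, numeric(nrow(T_new)))
  matrix(d2, nrow = nrow(T_new))
}

#' @rdname lda_fit
#' @return `canonical_scores`: n x min(c-1, d) matrix of projections onto
#'   the canonical variates (centered at the training grand mean).
#' @export
canonical_scores <- function(model, T_new) {
  stopifnot(inherits(model, "lda_model"))
  T_new <- as.matrix(T_new)
  if (ncol(T_new) != ncol(model$class_means)) {
    stop("feature dimension does not match the fitted model")
  }
  (T_new - rep(model$grand_mean, each = nrow(T_new))) %*%
    model$canonical_directions
}
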