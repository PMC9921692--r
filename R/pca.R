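#' Principal component analysis
#'
#' Bilinear decomposition `X = T P' + E` of the column-centered data:
#' loadings are the top-k right singular vectors, scores the projections of
#' the centered rows. Used both for exploratory analysis (score/loading
#' plots, T2 vs Q diagnostics) and as the backbone of SIMCA class models.
#'
#' @param X numeric matrix, n x p.
#' @param k number of components, `1 <= k <= min(n-1, p)`.
#' @param center logical; subtract column means (default) — set `FALSE`
#'   when `X` is already centered.
#' @return An object of class `pca_model`: `mean` (p-vector), `loadings`
#'   (p x k, orthonormal), `scores` (n x k), `component_variances`
#'   (score variances, non-increasing), `k`.
#' @examples
#' m <- pca_fit(matrix(rnorm(50), 10, 5), k = 2)
#' crossprod(m$loadings)  # identity
#' @export
pca_fit <- function(X, k, center = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (k < 1 || k > kmax) {
    stop("'k' must be between 1 and min(n-1, p) = ", kmax)
  }
  mu <- if (center) colMeans(X) else rep(0, p)
  Xc <- X - rep(mu, each = n)
  sv <- svd(Xc, nu = k, nv = k)
  scores <- sv$u * rep(sv$d[seq_len(k)], each = n)
  structure(
    list(mean = mu, loadings = sv$v, scores = scores,
         component_variances = sv$d[seq_len(k)]^2 / (n - 1), k = k),
    class = "pca_model")
}

#' Exploratory PCA of a spectral dataset
#'
#' Mean-centered PCA of the intensities with T2/Q outlier diagnostics and
#' per-component explained variance — the standard first look at a
#' spectral data matrix before any classification.
#'
#' @param ds a [spectra_dataset()].
#' @param k number of components.
#' @return List: `model` ([pca_fit()] result), `scores` (data frame with
#'   sample ids, labels if present, score columns `PC1..PCk`, `t2`, `q`),
#'   `loadings` (data frame with wavenumbers and loading columns),
#'   `explained` (% variance per component, non-increasing).
#' @export
explore_pca <- function(ds, k = 10) {
  stopifnot(inherits(ds, "spectra_dataset"))
  X <- ds$intensities
  k <- min(k, nrow(X) - 1L, ncol(X))
  model <- pca_fit(X, k = k)
  dg <- pca_t2_q(model, X)
  total_var <- sum(scale(X, scale = FALSE)^2) / (nrow(X) - 1L)
  sc <- data.frame(sample_id = ds$sample_ids, dg$scores, t2 = dg$t2,
                   q = dg$q)
  names(sc)[1L + seq_len(k)] <- paste0("PC", seq_len(k))
  if (!is.null(ds$labels)) sc$label <- ds$labels
  ld <- data.frame(wavenumber = ds$wavenumbers, model$loadings)
  names(ld)[1L + seq_len(k)] <- paste0("PC", seq_len(k))
  list(model = model, scores = sc, loadings = ld,
       explained = 100 * model$component_variances / total_var)
}

#' Hotelling T2 and Q residual diagnostics
#'
#' Per-row leverage within the model plane (`T2_i = sum_a t_ia^2 / var_a`)
#' and squared orthogonal distance from it
#' (`Q_i = ||x_centered - t_i P'||^2`). Together they flag outliers: large
#' T2 means extreme but model-conforming, large Q means off-model.
#'
#' @param model a [pca_fit()] result.
#' @param X rows on the same variable axis (centered internally with the
#'   model mean).
#' @return List with numeric vectors `t2` and `q` (both >= 0), plus the
#'   score matrix `scores`.
#' @export
pca_t2_q <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean)) {
    stop("column dimension does not match the fitted model")
  }
  if (any(model$component_variances <= .Machine$double.eps^0.5 *
          model$component_variances[1L])) {
    stop("degenerate PCA model: zero component variance")
  }
  Xc <- X - rep(model$mean, each = nrow(X))
  T_ <- Xc %*% model$loadings
  t2 <- drop((T_^2) %*% (1 / model$component_variances))
  resid <- Xc - tcrossprod(T_, model$loadings)
  q <- rowSums(resid^2)
  list(t2 = t2, q = q, scores = T_)
}
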