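#' Two-block partial least squares (PLS2) by NIPALS
#'
#' Sequential extraction of latent variables maximizing covariance between
#' `X` and a (dummy-coded, centered) response matrix `Y`. Each component's
#' weight vector is the NIPALS fixed point — the dominant left singular
#' vector of the current `X'Y` — computed exactly through the symmetric
#' eigendecomposition of the small `c x c` cross-product, after which `X`
#' is deflated by the extracted score/loading pair. Components are nested:
#' the first `a` components of an `A`-component model equal an
#' `a`-component model.
#'
#' @param X numeric n x p predictor matrix.
#' @param Y numeric n x c response matrix (for classification: one-hot
#'   dummy coding; see [dummy_code()]).
#' @param A number of latent variables, `1 <= A <= min(n-1, p)`.
#' @param center logical; column-center `X` and `Y` (default). Use
#'   `FALSE` for inputs centered upstream (the means are then zero).
#' @return An object of class `pls2_model`: `x_mean`, `y_mean`, `weights`
#'   (W, p x A), `x_loadings` (P, p x A), `y_loadings` (Q, c x A), `scores`
#'   (T, n x A, mutually orthogonal), `ssy` (response sum of squares
#'   captured per LV, overall and per response column), `coef` (p x c
#'   regression coefficients), `A`.
#' @export
pls2_fit <- function(X, Y, A, center = TRUE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("'X' and 'Y' must be row-aligned")
  p <- ncol(X)
  cc <- ncol(Y)
  if (A < 1 || A > min(n - 1L, p)) {
    stop("'A' must be between 1 and min(n-1, p) = ", min(n - 1L, p))
  }
  x_mean <- if (center) colMeans(X) else rep(0, p)
  y_mean <- if (center) colMeans(Y) else rep(0, cc)
  Xd <- X - rep(x_mean, each = n)
  Yc <- Y - rep(y_mean, each = n)

  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  Q <- matrix(0, cc, A)
  T_ <- matrix(0, n, A)
  ssy_total <- numeric(A)
  ssy_col <- matrix(0, cc, A)
  for (a in seq_len(A)) {
    Z <- crossprod(Xd, Yc)                      # p x c covariance
    znorm <- sqrt(sum(Z^2))
    if (znorm < 1e-12) {
      stop("no residual X-Y covariance left at component ", a,
           "; reduce 'A'")
    }
    if (cc == 1L) {
      w <- Z[, 1L]
    } else {
      # dominant eigenvector of Z'Z: the fixed point the NIPALS u/w/t/q
      # loop iterates towards, collapsed onto the c-dimensional response
      # space and solved exactly
      M <- crossprod(Z)
      v <- eigen(M, symmetric = TRUE)$vectors[, 1L]
      w <- drop(Z %*% v)
    }
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w       # deterministic sign
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(Xd, t_)) / tt
    q_ <- drop(crossprod(Yc, t_)) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    W[, a] <- w
    P[, a] <- p_
    Q[, a] <- q_
    T_[, a] <- t_
    ssy_col[, a] <- q_^2 * tt
    ssy_total[a] <- sum(ssy_col[, a])
  }
  # B = W (P'W)^-1 Q'
  coef <- W %*% solve(crossprod(P, W), t(Q))
  structure(
    list(x_mean = x_mean, y_mean = y_mean, weights = W, x_loadings = P,
         y_loadings = Q, scores = T_, ssy = ssy_total, ssy_col = ssy_col,
         coef = coef, A = A),
    class = "pls2_model")
}

#' Project new rows onto a fitted PLS2 model
#'
#' Applies the stored weight/loading deflation recursion; on the training
#' matrix this reproduces the stored scores.
#'
#' @param model a [pls2_fit()] result.
#' @param X_new numeric matrix with the model's column dimension.
#' @return n_new x A score matrix.
#' @export
pls2_scores <- function(model, X_new) {
  stopifnot(inherits(model, "pls2_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != nrow(model$weights)) {
    stop("column dimension does not match the fitted model")
  }
  Xd <- X_new - rep(model$x_mean, each = nrow(X_new))
  T_ <- matrix(0, nrow(X_new), model$A)
  for (a in seq_len(model$A)) {
    t_ <- drop(Xd %*% model$weights[, a])
    T_[, a] <- t_
    Xd <- Xd - tcrossprod(t_, model$x_loadings[, a])
  }
  T_
}

#' Predicted responses from a PLS2 model
#'
#' @param model a [pls2_fit()] result.
#' @param X_new numeric matrix with the model's column dimension.
#' @return n_new x c matrix of fitted responses.
#' @export
pls2_predict <- function(model, X_new) {
  stopifnot(inherits(model, "pls2_model"))
  X_new <- as.matrix(X_new)
  Xc <- X_new - rep(model$x_mean, each = nrow(X_new))
  Xc %*% model$coef + rep(model$y_mean, each = nrow(X_new))
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a(SSY_a * (w_ja / ||w_a||)^2) / sum_a SSY_a)`,
#' where `SSY_a` is the response sum of squares captured by component `a`.
#' The squared indices average to 1 (`sum_j VIP_j^2 = p`), so `VIP > 1`
#' conventionally marks variables carrying more than average discriminant
#' information. With `y_column` set, `SSY_a` is computed from that response
#' column only — the class-wise variant used to color variables by the
#' class they characterize.
#'
#' @param model a [pls2_fit()] result.
#' @param y_column optional response-column index for class-wise VIP.
#' @return Numeric p-vector of VIP scores.
#' @export
vip_scores <- function(model, y_column = NULL) {
  stopifnot(inherits(model, "pls2_model"))
  ssy <- if (is.null(y_column)) model$ssy else model$ssy_col[y_column, ]
  tot <- sum(ssy)
  if (tot <= 0) stop("zero captured response sum of squares; VIP undefined")
  W <- model$weights
  Wn2 <- W^2 / rep(colSums(W^2), each = nrow(W))
  sqrt(nrow(W) * drop(Wn2 %*% ssy) / tot)
}

#' One-hot dummy coding of class labels
#'
#' Standard PLS-DA response coding: a 0/1 indicator column per class,
#' ordered by sorted unique label.
#'
#' @param labels character vector of class labels.
#' @param class_names optional fixed class ordering.
#' @return n x c 0/1 matrix with class names as columns.
#' @export
dummy_code <- function(labels, class_names = sort(unique(labels))) {
  if (!all(labels %in% class_names)) {
    stop("label outside the class set: ",
         setdiff(labels, class_names)[1L])
  }
  Y <- matrix(0, length(labels), length(class_names),
              dimnames = list(NULL, class_names))
  Y[cbind(seq_along(labels), match(labels, class_names))] <- 1
  Y
}
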