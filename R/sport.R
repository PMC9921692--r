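#' Orthogonalize a block against previously extracted scores
#'
#' Removes from `X_block` everything already explained by the accumulated
#' score matrix: `X_perp = X - T (T'T)^-1 T' X`, computed through an SVD
#' basis of `T_prior` so rank-deficient score matrices are handled by basis
#' truncation (with a message) rather than failure. With an empty `T_prior`
#' (`q = 0`) the block is returned unchanged.
#'
#' @param X_block numeric n x p matrix.
#' @param T_prior numeric n x q score matrix (`q >= 0`).
#' @return n x p matrix with `T_prior' X_perp = 0`.
#' @export
orthogonalize <- function(X_block, T_prior) {
  X_block <- as.matrix(X_block)
  if (is.null(T_prior) || NCOL(T_prior) == 0) return(X_block)
  T_prior <- as.matrix(T_prior)
  if (nrow(T_prior) != nrow(X_block)) stop("row counts must match")
  Q <- orthonormal_basis(T_prior)
  X_block - Q %*% crossprod(Q, X_block)
}

# Orthonormal basis of the column space, truncating numerically null
# directions (relative tolerance on singular values).
orthonormal_basis <- function(T_prior, tol = 1e-10) {
  sv <- svd(T_prior)
  keep <- sv$d > tol * sv$d[1L]
  if (!all(keep)) {
    message("rank-deficient prior scores: basis truncated from ",
            length(keep), " to ", sum(keep), " directions")
  }
  sv$u[, keep, drop = FALSE]
}

# Deflation map A = (T'T)^+ T' X (q x p) so that new rows can be
# orthogonalized as x - t_new A; pseudo-inverse via SVD with truncation.
deflation_map <- function(T_prior, X_block, tol = 1e-10) {
  sv <- svd(T_prior)
  keep <- sv$d > tol * sv$d[1L]
  V <- sv$v[, keep, drop = FALSE]
  U <- sv$u[, keep, drop = FALSE]
  (V * rep(1 / sv$d[keep], each = nrow(V))) %*% crossprod(U, X_block)
}

#' Fit a SPORT-LDA model
#'
#' Sequential preprocessing through orthogonalization: blocks (the same
#' spectra under different pretreatments) are visited in order; each
#' retained block is first orthogonalized against all scores already
#' extracted, then contributes its own PLS2 latent variables against the
#' centered dummy response. An LV count of 0 discards the block. LDA on
#' the concatenated scores yields the classifier.
#'
#' @param blockset a [build_blocks()] result fitted on the calibration set.
#' @param labels class label per calibration row.
#' @param lv_combo integer vector, one LV count per block (0-10 typical;
#'   0 = discard); at least one entry must be positive.
#' @param lambda ridge passed to [lda_fit()].
#' @return An object of class `sport_model`: `blockset` (preprocessing
#'   parameters), `lv_combo`, `submodels` (PLS2 per retained block),
#'   `deflation_maps`, `scores` (concatenated training scores), `lda`,
#'   `class_names`, `y_mean`.
#' @export
sport_fit <- function(blockset, labels, lv_combo, lambda = 1e-8) {
  stopifnot(inherits(blockset, "block_set"))
  B <- length(blockset$blocks)
  if (length(lv_combo) != B) {
    stop("'lv_combo' must have one entry per block (", B, ")")
  }
  if (any(lv_combo < 0)) stop("LV counts must be >= 0")
  if (all(lv_combo == 0)) stop("at least one block must retain LVs")
  labels <- as.character(labels)
  n <- nrow(blockset$blocks[[1L]])
  if (length(labels) != n) stop("'labels' must have one entry per row")
  cls <- sort(unique(labels))
  if (any(table(labels) < 2)) {
    stop("every class needs at least 2 training rows")
  }
  Y <- dummy_code(labels, cls)
  y_mean <- colMeans(Y)
  Yc <- Y - rep(y_mean, each = n)

  submodels <- vector("list", B)
  defl <- vector("list", B)
  T_acc <- matrix(0, n, 0)
  for (i in seq_len(B)) {
    if (lv_combo[i] == 0) next
    if (ncol(T_acc) > 0) {
      defl[[i]] <- deflation_map(T_acc, blockset$blocks[[i]])
      Xo <- blockset$blocks[[i]] - T_acc %*% defl[[i]]
    } else {
      Xo <- blockset$blocks[[i]]
    }
    submodels[[i]] <- pls2_fit(Xo, Yc, A = lv_combo[i], center = FALSE)
    T_acc <- cbind(T_acc, submodels[[i]]$scores)
  }
  lda <- lda_fit(T_acc, labels, lambda = lambda)
  structure(
    list(blockset = blockset, lv_combo = as.integer(lv_combo),
         submodels = submodels, deflation_maps = defl, scores = T_acc,
         lda = lda, class_names = cls, y_mean = y_mean),
    class = "sport_model")
}

#' @export
print.sport_model <- function(x, ...) {
  meth <- vapply(x$blockset$specs, `[[`, "", "method")
  cat("<sport_model> blocks:",
      paste(sprintf("%s(%d)", meth, x$lv_combo), collapse = " + "),
      "| classes:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

#' Predict classes for new spectra with a SPORT-LDA model
#'
#' New spectra are preprocessed with the stored training parameters,
#' carried through the stored sequential orthogonalization (a pure matrix
#' product with the fit-time deflation maps), projected onto each retained
#' block's PLS weights, and classified by the LDA on the concatenated
#' scores.
#'
#' @param model a [sport_fit()] result.
#' @param new a [spectra_dataset()] on the training axis.
#' @return List: `labels` (predicted classes), `canonical` (scores on the
#'   canonical variates, for class-separation plots), `scores`
#'   (concatenated block scores).
#' @export
sport_predict <- function(model, new) {
  stopifnot(inherits(model, "sport_model"))
  Xs <- transform_blocks(model$blockset, new)
  T_acc <- matrix(0, nrow(Xs[[1L]]), 0)
  for (i in seq_along(Xs)) {
    if (model$lv_combo[i] == 0) next
    Xo <- if (!is.null(model$deflation_maps[[i]])) {
      Xs[[i]] - T_acc %*% model$deflation_maps[[i]]
    } else {
      Xs[[i]]
    }
    T_acc <- cbind(T_acc, pls2_scores(model$submodels[[i]], Xo))
  }
  list(labels = lda_predict(model$lda, T_acc),
       canonical = canonical_scores(model$lda, T_acc),
       scores = T_acc)
}

#' Latent-variable grid for SPORT model selection
#'
#' All per-block LV combinations to be scored in cross-validation,
#' excluding the all-zero combination. The full grid uses every level
#' `0..max_lv`; the coarse grid thins each block's levels to
#' `0, 1, 3, 5, 7, 10` (intersected with `0..max_lv`) for desk-scale runs.
#'
#' @param n_blocks number of blocks B.
#' @param max_lv largest LV count per block.
#' @param coarse logical; use the thinned level set.
#' @return Integer matrix, one row per candidate combination, in
#'   lexicographic order.
#' @examples
#' nrow(lv_grid(4, 10))  # 11^4 - 1 = 14640
#' @export
lv_grid <- function(n_blocks, max_lv = 10, coarse = FALSE) {
  levels <- if (coarse) {
    intersect(c(0L, 1L, 3L, 5L, 7L, 10L), 0:max_lv)
  } else {
    0:max_lv
  }
  g <- as.matrix(expand.grid(rep(list(levels), n_blocks),
                             KEEP.OUT.ATTRS = FALSE)[, n_blocks:1, drop = FALSE])
  g <- g[rowSums(g) > 0, , drop = FALSE]
  dimnames(g) <- list(NULL, paste0("lv", seq_len(n_blocks)))
  # lexicographic order
  g[do.call(order, as.data.frame(g)), , drop = FALSE]
}

#' Cross-validated SPORT for one LV combination
#'
#' Stratified k-fold cross-validation with full refitting inside every
#' fold: preprocessing means, orthogonalization, PLS and LDA are all
#' re-estimated on the fold's training rows only, so no statistic from a
#' held-out row influences the model that predicts it.
#'
#' @param train a labeled [spectra_dataset()].
#' @param specs list of [preprocess_spec()] per block.
#' @param lv_combo LV count per block.
#' @param folds number of folds (default 7).
#' @param return_models logical; also return the per-fold `sport_model`s.
#' @return List: `ce` (classification error %, pooled over folds),
#'   `predicted` (held-out prediction per row), `fold` (fold id per row),
#'   and optionally `models`.
#' @export
sport_cv <- function(train, specs, lv_combo, folds = 7,
                     return_models = FALSE) {
  stopifnot(inherits(train, "spectra_dataset"), !is.null(train$labels))
  fold <- kfold_indices(train$labels, folds = folds, ids = train$sample_ids)
  pred <- character(length(fold))
  models <- if (return_models) vector("list", folds)
  for (k in seq_len(folds)) {
    tr <- spectra_subset(train, fold != k)
    te <- spectra_subset(train, fold == k)
    bs <- build_blocks(tr, specs)
    m <- sport_fit(bs, tr$labels, lv_combo)
    pred[fold == k] <- sport_predict(m, te)$labels
    if (return_models) models[[k]] <- m
  }
  out <- list(ce = 100 * mean(pred != train$labels), predicted = pred,
              fold = fold)
  if (return_models) out$models <- models
  out
}

#' Grid search over LV combinations by cross-validated classification error
#'
#' The SPORT model-selection protocol: every candidate combination in
#' [lv_grid()] is scored by stratified k-fold cross-validation (default 7
#' folds), refitting preprocessing, orthogonalization, PLS and LDA inside
#' each fold. The winner minimizes the pooled classification error; ties
#' are broken by the smallest total LV count, then lexicographically.
#'
#' Internally the nested structure of NIPALS components is exploited: per
#' fold, each distinct orthogonalization state is fitted once with the
#' largest LV count requested, and shallower combinations reuse truncated
#' score matrices, which keeps the full `11^B` grid tractable.
#'
#' @param train a labeled [spectra_dataset()] (the calibration set).
#' @param specs list of [preprocess_spec()] per block.
#' @param max_lv largest LV count per block (default 10).
#' @param folds number of CV folds (default 7).
#' @param coarse logical; use the thinned [lv_grid()] levels.
#' @param lambda LDA ridge.
#' @return List: `best_combo` (integer vector), `ce_cv` (its CV
#'   classification error %), `grid` (data frame of every combination and
#'   its CE).
#' @export
grid_search_lv <- function(train, specs, max_lv = 10, folds = 7,
                           coarse = FALSE, lambda = 1e-8) {
  stopifnot(inherits(train, "spectra_dataset"), !is.null(train$labels))
  if (folds < 2) stop("'folds' must be >= 2")
  if (max_lv < 1) stop("'max_lv' must be >= 1")
  specs <- lapply(specs, function(s) {
    if (is.character(s)) preprocess_spec(s) else s
  })
  B <- length(specs)
  grid <- lv_grid(B, max_lv = max_lv, coarse = coarse)
  levels <- sort(unique(c(0L, grid)))
  pos_levels <- levels[levels > 0]
  max_level <- max(pos_levels)

  fold <- kfold_indices(train$labels, folds = folds, ids = train$sample_ids)
  labels <- train$labels
  cls <- sort(unique(labels))
  n_all <- length(labels)
  # misclassification counts per combo, pooled over folds; combos are
  # addressed by their mixed-radix index over the level set
  nl <- length(levels)
  radix <- nl^((B - 1L):0L)
  digits <- matrix(match(grid, levels) - 1L, nrow = nrow(grid))
  idx_map <- integer(nl^B)
  idx_map[drop(digits %*% radix) + 1L] <- seq_len(nrow(grid))
  errors <- numeric(nrow(grid))
  visits <- integer(nrow(grid))

  for (k in seq_len(folds)) {
    tr <- spectra_subset(train, fold != k)
    te <- spectra_subset(train, fold == k)
    bs <- build_blocks(tr, specs)
    te_blocks <- transform_blocks(bs, te)
    Y <- dummy_code(tr$labels, cls)
    Yc <- Y - rep(colMeans(Y), each = nrow(Y))
    y_tr <- match(tr$labels, cls)
    y_te <- match(te$labels, cls)
    # Gram matrices: with p >> n all block-level algebra (orthogonalization,
    # NIPALS score extraction) runs in the n-dimensional sample space; the
    # scores are algebraically identical to the wide-matrix computation
    G_tr <- lapply(bs$blocks, tcrossprod)
    G_te <- lapply(seq_len(B),
                   function(i) tcrossprod(te_blocks[[i]], bs$blocks[[i]]))

    # depth-first over blocks; state carries accumulated train/test scores
    # and the mixed-radix combo index
    recurse <- function(i, T_tr, T_te, idx, any_pos) {
      if (i > B) {
        if (!any_pos) return()
        err <- lda_fold_errors(T_tr, y_tr, T_te, y_te, lambda)
        row <- idx_map[idx + 1L]
        errors[row] <<- errors[row] + err
        visits[row] <<- visits[row] + 1L
        return()
      }
      # lv = 0: skip the block entirely
      recurse(i + 1L, T_tr, T_te, idx * nl, any_pos)
      amax <- min(max_level, nrow(T_tr) - 1L, ncol(bs$blocks[[i]]))
      if (amax < 1) return()
      if (ncol(T_tr) > 0) {
        og <- kernel_orthogonalize(G_tr[[i]], G_te[[i]], T_tr, T_te)
      } else {
        og <- list(G = G_tr[[i]], G_te = G_te[[i]])
      }
      ks <- kernel_pls_scores(og$G, og$G_te, Yc, amax)
      for (li in seq_along(pos_levels)) {
        lv <- pos_levels[li]
        if (lv > ks$A) next
        recurse(i + 1L,
                cbind(T_tr, ks$scores[, seq_len(lv), drop = FALSE]),
                cbind(T_te, ks$scores_te[, seq_len(lv), drop = FALSE]),
                idx * nl + match(lv, levels) - 1L, TRUE)
      }
    }
    recurse(1L, matrix(0, nrow(bs$blocks[[1L]]), 0),
            matrix(0, nrow(te_blocks[[1L]]), 0), 0L, FALSE)
  }

  ce <- 100 * errors / n_all
  ce[visits < folds] <- NA_real_   # combos infeasible in some fold
  tab <- data.frame(grid, ce = ce)
  ord <- order(tab$ce, rowSums(grid), na.last = TRUE)
  # lexicographic final tie-break is inherited from grid row order
  best <- ord[1L]
  list(best_combo = as.integer(grid[best, ]), ce_cv = tab$ce[best],
       grid = tab)
}

# --- kernel-space machinery for the CV grid search ------------------------
# With p >> n it is wasteful to carry the wide blocks through the LV tree.
# All quantities the tree needs (orthogonalized-block PLS scores for
# training and held-out rows) are expressible through the Gram matrices
# G = X X' (n x n) and G_te = X_te X' (n_te x n); the recursions below are
# the exact sample-space images of the wide-matrix operations, so the
# scores agree with pls2_fit/pls2_scores up to floating-point error (a
# property the test suite checks against the wide-matrix path).

# (I - P_T) G (I - P_T) and (G_te - T_te T^+ G)(I - P_T), where P_T is the
# projector onto the accumulated score columns.
kernel_orthogonalize <- function(G, G_te, T_tr, T_te, tol = 1e-10) {
  sv <- svd(T_tr)
  keep <- sv$d > tol * sv$d[1L]
  U <- sv$u[, keep, drop = FALSE]
  # T^+ = V D^-1 U'
  TV <- T_te %*% (sv$v[, keep, drop = FALSE] *
                    rep(1 / sv$d[keep], each = ncol(T_te)))
  A1 <- G - U %*% crossprod(U, G)
  Go <- A1 - tcrossprod(A1 %*% U, U)
  C1 <- G_te - TV %*% crossprod(U, G)
  Gte_o <- C1 - tcrossprod(C1 %*% U, U)
  list(G = Go, G_te = Gte_o)
}

# Sequential NIPALS component extraction in kernel form. Per component the
# response-space eigenproblem gives v; the score is t = G Yc v / ||X'Yc v||
# with ||X'Yc v||^2 = (Yc v)' G (Yc v); both Gram matrices are then
# deflated by the extracted score/loading pair.
kernel_pls_scores <- function(G, G_te, Yc, A) {
  n <- nrow(G)
  T_tr <- matrix(0, n, A)
  T_te <- matrix(0, nrow(G_te), A)
  zv0 <- NA_real_
  a_eff <- 0L
  for (a in seq_len(A)) {
    GY <- G %*% Yc
    M <- crossprod(Yc, GY)
    M <- (M + t(M)) / 2
    v <- eigen(M, symmetric = TRUE)$vectors[, 1L]
    yv <- drop(Yc %*% v)
    gy <- drop(G %*% yv)
    zv2 <- sum(yv * gy)
    if (is.na(zv0)) zv0 <- zv2
    if (zv2 <= 1e-24 * max(zv0, 1)) break
    t_ <- gy / sqrt(zv2)
    t_te <- drop(G_te %*% yv) / sqrt(zv2)
    tt <- sum(t_^2)
    T_tr[, a] <- t_
    T_te[, a] <- t_te
    a_eff <- a
    if (a < A) {
      g1 <- drop(G %*% t_) / tt          # X p
      g2 <- drop(G_te %*% t_) / tt       # X_te p
      ptp <- sum(t_ * g1) / tt           # p'p
      G <- G - tcrossprod(t_, g1) - tcrossprod(g1, t_) +
        ptp * tcrossprod(t_, t_)
      G_te <- G_te - tcrossprod(t_te, g1) - tcrossprod(g2, t_) +
        ptp * tcrossprod(t_te, t_)
    }
  }
  list(scores = T_tr[, seq_len(a_eff), drop = FALSE],
       scores_te = T_te[, seq_len(a_eff), drop = FALSE], A = a_eff)
}

# Lean pooled-covariance Mahalanobis classifier for grid leaves: returns
# the held-out misclassification count. Same decision rule as
# lda_fit/lda_predict without the canonical-variate eigendecomposition.
lda_fold_errors <- function(T_tr, y_tr, T_te, y_te, lambda) {
  d <- ncol(T_tr)
  cnt <- tabulate(y_tr)
  M <- rowsum(T_tr, y_tr) / cnt
  Xc <- T_tr - M[y_tr, , drop = FALSE]
  Sw <- crossprod(Xc) / (length(y_tr) - length(cnt))
  if (lambda > 0) Sw <- Sw + diag(lambda * sum(diag(Sw)) / d, d)
  ch <- chol(Sw)
  Rinv <- backsolve(ch, diag(d))
  Wte <- T_te %*% Rinv
  Wm <- M %*% Rinv
  d2 <- outer(rowSums(Wte^2), rowSums(Wm^2), "+") - 2 * tcrossprod(Wte, Wm)
  sum(max.col(-d2, ties.method = "first") != y_te)
}

#' Per-block, class-wise VIP report for a SPORT model
#'
#' VIP scores are computed within each retained block's PLS submodel:
#' overall and per class (class-wise response sum of squares). The mask
#' marks variables whose class-wise VIP exceeds 1 — conventionally the
#' variables characterizing that class.
#'
#' @param model a [sport_fit()] result.
#' @return List with one entry per retained block: `spec` (method name),
#'   `wavenumbers`, `overall` (VIP vector), `by_class` (p x c matrix),
#'   `mask` (p x c logical, VIP > 1).
#' @export
sport_vip <- function(model) {
  stopifnot(inherits(model, "sport_model"))
  wn <- model$blockset$wavenumbers
  out <- list()
  for (i in seq_along(model$submodels)) {
    sm <- model$submodels[[i]]
    if (is.null(sm)) next
    byc <- vapply(seq_along(model$class_names),
                  function(ci) vip_scores(sm, y_column = ci),
                  numeric(length(wn)))
    colnames(byc) <- model$class_names
    out[[length(out) + 1L]] <- list(
      spec = model$blockset$specs[[i]]$method,
      wavenumbers = wn,
      overall = vip_scores(sm),
      by_class = byc,
      mask = byc > 1)
  }
  out
}
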