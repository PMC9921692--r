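#' Fit a SIMCA class model
#'
#' Soft independent modeling of class analogy: a PCA model of the target
#' class only. Spectra are pretreated (`MC`, `SNV`, `D1` or `D2`) and
#' centered on the class's own training mean; a K-component PCA is fitted;
#' the Q residual and Hotelling T2 of each training row are summarized by
#' their means (`Q0`, `T2_0`), which normalize the combined reduced
#' distance `d = sqrt((Q/Q0)^2 + (T2/T2_0)^2)`.
#'
#' The acceptance threshold is the empirical `quantile` (default 95th
#' percentile) of *cross-validated* training distances: within `folds`-fold
#' CV, each training row's distance is computed from a model it did not
#' influence, so the threshold is not biased low by resubstitution.
#'
#' @param X_class matrix of target-class training spectra (rows), or a
#'   [spectra_dataset()] (all of whose rows are used).
#' @param K number of principal components (`>= 1`, below the class rank).
#' @param spec a [preprocess_spec()] or method name (default `"MC"`).
#' @param folds CV folds for threshold calibration (default 7).
#' @param quantile acceptance quantile of the CV distance distribution.
#' @return An object of class `simca_model`: `spec`, `center` (class
#'   training mean after pretreatment), `pca`, `q0`, `t2_0`, `threshold`,
#'   `K`, `cv_distances`.
#' @export
simca_fit <- function(X_class, K, spec = preprocess_spec("MC"), folds = 7,
                      quantile = 0.95) {
  if (inherits(X_class, "spectra_dataset")) X_class <- X_class$intensities
  X_class <- as.matrix(X_class)
  if (is.character(spec)) spec <- preprocess_spec(spec)
  n <- nrow(X_class)
  if (K < 1) stop("'K' must be >= 1")
  if (n < K + 2) stop("need at least K + 2 = ", K + 2, " training rows")
  core <- simca_core(X_class, K, spec)

  # cross-validated distances for threshold calibration
  fold <- rep_len(seq_len(folds), n)
  cv_d <- numeric(n)
  for (k in seq_len(folds)) {
    tr <- X_class[fold != k, , drop = FALSE]
    if (nrow(tr) < K + 2) {
      stop("too few rows per CV fold for K = ", K,
           "; reduce 'K' or 'folds'")
    }
    sub <- simca_core(tr, K, spec)
    cv_d[fold == k] <- simca_core_distance(sub, X_class[fold == k, ,
                                                        drop = FALSE])
  }
  threshold <- stats::quantile(cv_d, quantile, names = FALSE)
  structure(c(core, list(threshold = threshold, cv_distances = cv_d,
                         quantile = quantile)),
            class = "simca_model")
}

# PCA + distance normalization on pretreated, class-centered rows.
simca_core <- function(X, K, spec) {
  P <- apply_pretreatment(X, spec)
  center <- colMeans(P)
  pca <- pca_fit(P, k = K, center = TRUE)
  if (pca$component_variances[K] <= 1e-12 * pca$component_variances[1L] ||
      !any(abs(P - rep(center, each = nrow(P))) > 1e-12)) {
    stop("class rank too low for K = ", K,
         " components (degenerate residual space)")
  }
  dg <- pca_t2_q(pca, P)
  if (all(dg$q < 1e-24)) {
    stop("zero residual space: K = ", K, " equals the class rank")
  }
  list(spec = spec, center = center, pca = pca,
       q0 = mean(dg$q), t2_0 = mean(dg$t2), K = K)
}

simca_core_distance <- function(core, X_raw) {
  P <- apply_pretreatment(X_raw, core$spec)
  dg <- pca_t2_q(core$pca, P)
  sqrt((dg$q / core$q0)^2 + (dg$t2 / core$t2_0)^2)
}

#' Reduced SIMCA distance of spectra from a class model
#'
#' `d_i = sqrt((Q_i/Q0)^2 + (T2_i/T2_0)^2)` after applying the model's
#' pretreatment and centering with the training parameters. Training rows
#' average to 1 on each normalized axis.
#'
#' @param model a [simca_fit()] result.
#' @param X matrix of spectra (rows) or a [spectra_dataset()] on the same
#'   axis.
#' @return Numeric vector of distances (>= 0).
#' @export
simca_distance <- function(model, X) {
  stopifnot(inherits(model, "simca_model"))
  if (inherits(X, "spectra_dataset")) X <- X$intensities
  X <- as.matrix(X)
  if (ncol(X) != length(model$center)) {
    stop("column dimension does not match the fitted model")
  }
  simca_core_distance(model, X)
}

#' SIMCA acceptance decision
#'
#' A spectrum is accepted by the class model iff its reduced distance does
#' not exceed the threshold (boundary inclusive).
#'
#' @param model a [simca_fit()] result.
#' @param X spectra to score.
#' @return Logical vector.
#' @export
simca_accept <- function(model, X) {
  simca_distance(model, X) <= model$threshold
}

#' Sensitivity, specificity and efficiency of a class model
#'
#' Sensitivity: % of target-class samples accepted. Specificity: % of
#' other-class samples rejected. Efficiency: their geometric mean — the
#' figure of merit used to select among SIMCA models.
#'
#' @param accepted_target logical acceptance on true-class rows.
#' @param accepted_other logical acceptance on other-class rows.
#' @return List with `sensitivity`, `specificity`, `efficiency` (all %).
#' @examples
#' class_metrics(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, TRUE, FALSE))
#' @export
class_metrics <- function(accepted_target, accepted_other) {
  if (length(accepted_target) == 0 || length(accepted_other) == 0) {
    stop("both the target and other-class sets must be nonempty")
  }
  sens <- 100 * mean(accepted_target)
  spec <- 100 * mean(!accepted_other)
  list(sensitivity = sens, specificity = spec,
       efficiency = sqrt(sens * spec))
}

# Selection rule shared by simca_cv_select and its tests: maximum
# efficiency; ties broken by the minimum number of PCs, then by
# pretreatment order as listed.
choose_simca_row <- function(table, tol = 1e-9) {
  best_eff <- max(table$efficiency)
  cand <- which(table$efficiency >= best_eff - tol)
  cand[order(table$K[cand], cand)][1L]
}

#' Cross-validated SIMCA model selection
#'
#' For every pretreatment and every component count `K <= K_max`, the
#' target class's training rows are scored in stratified `folds`-fold CV:
#' held-out target rows give the sensitivity, and all other-class rows —
#' scored against each fold model and averaged — give the specificity.
#' Fold models use the `quantile` of their own training distances as
#' acceptance threshold. The model maximizing CV efficiency wins; with
#' (near-)equal efficiencies the minimum number of PCs is preferred. The
#' chosen configuration is then refitted on all target rows with
#' [simca_fit()] (CV-calibrated threshold).
#'
#' @param train a labeled [spectra_dataset()] (the calibration set).
#' @param target_class the class to model.
#' @param specs pretreatments to scan (default `MC, SNV, D1, D2`).
#' @param K_max largest component count to scan (default 15).
#' @param folds CV folds (default 7).
#' @param quantile acceptance quantile (default 0.95).
#' @return List: `table` (data frame with columns `pretreatment`, `K`,
#'   `sensitivity`, `specificity`, `efficiency`, `chosen`), `model` (the
#'   refitted [simca_fit()] model), `target_class`.
#' @export
simca_cv_select <- function(train, target_class,
                            specs = c("MC", "SNV", "D1", "D2"),
                            K_max = 15, folds = 7, quantile = 0.95) {
  stopifnot(inherits(train, "spectra_dataset"))
  if (is.null(train$labels)) stop("'train' must be labeled")
  if (!target_class %in% train$labels) {
    stop("target class ", target_class, " not present in the training set")
  }
  if (K_max < 1) stop("'K_max' must be >= 1")
  specs <- lapply(specs, function(s) {
    if (is.character(s)) preprocess_spec(s) else s
  })
  tgt_rows <- which(train$labels == target_class)
  oth_rows <- which(train$labels != target_class)
  n_t <- length(tgt_rows)
  if (n_t < folds) stop("too few target rows (", n_t, ") for ", folds,
                        " folds")
  fold <- rep_len(seq_len(folds), n_t)
  K_max <- min(K_max, n_t - max(table(fold)) - 2L,
               ncol(train$intensities) - 1L)
  if (K_max < 1) stop("too few target rows for any component count")
  X_t <- train$intensities[tgt_rows, , drop = FALSE]
  X_o <- train$intensities[oth_rows, , drop = FALSE]

  rows <- list()
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    acc_t <- matrix(NA, n_t, K_max)              # held-out target acceptance
    rej_o <- matrix(0, folds, K_max)             # per-fold other rejection %
    for (k in seq_len(folds)) {
      tr <- X_t[fold != k, , drop = FALSE]
      te <- X_t[fold == k, , drop = FALSE]
      # one SVD at K_max serves every K: components are nested
      P_tr <- apply_pretreatment(tr, sp)
      ctr <- colMeans(P_tr)
      Ptr_c <- P_tr - rep(ctr, each = nrow(P_tr))
      sv <- svd(Ptr_c, nu = 0, nv = K_max)
      d2 <- sv$d^2
      scores_of <- function(Xraw) {
        Pp <- apply_pretreatment(Xraw, sp)
        Pc <- Pp - rep(ctr, each = nrow(Pp))
        list(T = Pc %*% sv$v, tot = rowSums(Pc^2))
      }
      s_tr <- scores_of(tr)
      s_te <- scores_of(te)
      s_ot <- scores_of(X_o)
      vars <- d2[seq_len(K_max)] / (nrow(tr) - 1)
      for (K in seq_len(K_max)) {
        if (vars[K] <= 1e-12 * vars[1L]) break
        idx <- seq_len(K)
        q_tr <- s_tr$tot - rowSums(s_tr$T[, idx, drop = FALSE]^2)
        t2_tr <- drop(s_tr$T[, idx, drop = FALSE]^2 %*% (1 / vars[idx]))
        q0 <- mean(q_tr)
        t20 <- mean(t2_tr)
        if (q0 <= 1e-24) break
        d_tr <- sqrt((q_tr / q0)^2 + (t2_tr / t20)^2)
        thr <- stats::quantile(d_tr, quantile, names = FALSE)
        dist_of <- function(s) {
          q <- pmax(s$tot - rowSums(s$T[, idx, drop = FALSE]^2), 0)
          t2 <- drop(s$T[, idx, drop = FALSE]^2 %*% (1 / vars[idx]))
          sqrt((q / q0)^2 + (t2 / t20)^2)
        }
        acc_t[fold == k, K] <- dist_of(s_te) <= thr
        rej_o[k, K] <- 100 * mean(dist_of(s_ot) > thr)
      }
    }
    for (K in seq_len(K_max)) {
      if (anyNA(acc_t[, K])) next
      sens <- 100 * mean(acc_t[, K])
      spec_ <- mean(rej_o[, K])
      rows[[length(rows) + 1L]] <- data.frame(
        pretreatment = sp$method, K = K, sensitivity = sens,
        specificity = spec_, efficiency = sqrt(sens * spec_))
    }
  }
  tab <- do.call(rbind, rows)
  pick <- choose_simca_row(tab)
  tab$chosen <- seq_len(nrow(tab)) == pick
  model <- simca_fit(X_t, K = tab$K[pick],
                     spec = preprocess_spec(tab$pretreatment[pick]),
                     folds = folds, quantile = quantile)
  list(table = tab, model = model, target_class = target_class)
}
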