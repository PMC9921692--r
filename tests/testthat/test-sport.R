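test_that("orthogonalization satisfies its defining identities", {
  set.seed(51)
  X <- matrix(rnorm(20 * 15), 20, 15)
  T_ <- matrix(rnorm(20 * 4), 20, 4)
  # empty projector
  expect_identical(orthogonalize(X, NULL), X)
  expect_identical(orthogonalize(X, matrix(0, 20, 0)), X)
  Xo <- orthogonalize(X, T_)
  expect_lt(max(abs(crossprod(T_, Xo))), 1e-8)
  # idempotence
  expect_equal(orthogonalize(Xo, T_), Xo, tolerance = 1e-10)
  # rank-deficient prior scores: truncation message, still exact
  T_def <- cbind(T_, T_[, 1] + T_[, 2])
  expect_message(Xo2 <- orthogonalize(X, T_def), "rank-deficient")
  expect_lt(max(abs(crossprod(T_def, Xo2))), 1e-8)
  expect_error(orthogonalize(X, matrix(rnorm(10), 5, 2)), "row counts")
})

test_that("a (3,9,3,0) combination concatenates 15 scores and drops block 4", {
  ds <- easy_dataset(n_per_class = 20, n_axis = 101)
  bs <- build_blocks(ds, default_specs())
  m <- sport_fit(bs, ds$labels, c(3, 9, 3, 0))
  expect_identical(ncol(m$scores), 15L)
  expect_null(m$submodels[[4]])
  expect_identical(m$lv_combo, c(3L, 9L, 3L, 0L))
  # inter-block score orthogonality
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[1:3, 4:15])), 1e-8)
  expect_lt(max(abs(G[4:12, 13:15])), 1e-8)
  expect_error(sport_fit(bs, ds$labels, c(0, 0, 0, 0)), "at least one")
  expect_error(sport_fit(bs, ds$labels, c(1, 1)), "one entry per block")
})

test_that("single-block SPORT equals the plain PLS-DA + LDA pipeline exactly", {
  ds <- easy_dataset(n_per_class = 15, n_axis = 61)
  tr <- spectra_subset(ds, which(seq_len(60) %% 3 != 0))
  te <- spectra_subset(ds, which(seq_len(60) %% 3 == 0))
  for (method in c("MC", "SNV")) {
    bs <- build_blocks(tr, list(preprocess_spec(method)))
    m <- sport_fit(bs, tr$labels, 4)
    got <- sport_predict(m, te)$labels
    # direct pipeline from the core primitives
    P_tr <- sportsimca:::apply_pretreatment(tr$intensities,
                                            preprocess_spec(method))
    mu <- colMeans(P_tr)
    Y <- dummy_code(tr$labels)
    pls <- pls2_fit(P_tr - rep(mu, each = nrow(P_tr)),
                    scale(Y, scale = FALSE), 4, center = FALSE)
    lda <- lda_fit(pls$scores, tr$labels)
    P_te <- sportsimca:::apply_pretreatment(te$intensities,
                                            preprocess_spec(method))
    want <- lda_predict(lda, pls2_scores(pls, P_te - rep(mu, each = nrow(P_te))))
    expect_identical(got, want)
  }
})

test_that("training predictions are self-consistent and permutation-equivariant", {
  ds <- easy_dataset(n_per_class = 14, n_axis = 61)
  bs <- build_blocks(ds, default_specs())
  m <- sport_fit(bs, ds$labels, c(2, 2, 2, 2))
  pr_tr <- sport_predict(m, ds)
  expect_identical(pr_tr$labels, lda_predict(m$lda, m$scores))
  # easy data: zero training errors at (2,2,2,2)
  expect_identical(sum(pr_tr$labels != ds$labels), 0L)
  perm <- sample(nrow(ds$intensities))
  pr_perm <- sport_predict(m, spectra_subset(ds, perm))
  expect_identical(pr_perm$labels, pr_tr$labels[perm])
  expect_equal(pr_perm$canonical, pr_tr$canonical[perm, ], tolerance = 1e-10)
})

test_that("held-out predictions match a step-through recomputation of the fit-time algebra", {
  ds <- easy_dataset(n_per_class = 16, n_axis = 61)
  tr <- spectra_subset(ds, 1:48)
  te <- spectra_subset(ds, 49:64)
  bs <- build_blocks(tr, default_specs())
  combo <- c(2, 3, 0, 1)
  m <- sport_fit(bs, tr$labels, combo)
  got <- sport_predict(m, te)

  # independent walk: preprocess, orthogonalize against accumulated train
  # scores via explicit least squares, project, classify
  Xs <- transform_blocks(bs, te)
  T_tr <- matrix(0, 48, 0)
  T_te <- matrix(0, 16, 0)
  for (i in seq_along(combo)) {
    if (combo[i] == 0) next
    if (ncol(T_tr) > 0) {
      A_ls <- qr.solve(T_tr, bs$blocks[[i]])
      Xo_tr <- bs$blocks[[i]] - T_tr %*% A_ls
      Xo_te <- Xs[[i]] - T_te %*% A_ls
    } else {
      Xo_tr <- bs$blocks[[i]]
      Xo_te <- Xs[[i]]
    }
    Y <- dummy_code(tr$labels)
    pls <- pls2_fit(Xo_tr, scale(Y, scale = FALSE), combo[i], center = FALSE)
    T_tr <- cbind(T_tr, pls$scores)
    T_te <- cbind(T_te, pls2_scores(pls, Xo_te))
  }
  lda <- lda_fit(T_tr, tr$labels)
  expect_identical(got$labels, lda_predict(lda, T_te))
  expect_equal(got$scores, T_te, tolerance = 1e-8)
  wrong <- spectra_dataset(te$intensities, rev(te$wavenumbers))
  expect_error(sport_predict(m, wrong), "axis")
})

test_that("the LV grid has the prescribed combinatorics", {
  expect_identical(nrow(lv_grid(4, 10)), 14640L)   # 11^4 - 1
  expect_identical(nrow(lv_grid(2, 10)), 120L)     # 11^2 - 1
  expect_identical(nrow(lv_grid(1, 10)), 10L)      # 11^1 - 1
  expect_identical(nrow(lv_grid(1, 1)), 1L)
  g <- lv_grid(3, 5)
  expect_false(any(rowSums(g) == 0))
  expect_identical(nrow(unique(g)), nrow(g))
  gc <- lv_grid(4, 10, coarse = TRUE)
  expect_identical(nrow(gc), 1295L)                # 6^4 - 1
  expect_setequal(unique(as.vector(gc)), c(0L, 1L, 3L, 5L, 7L, 10L))
})

test_that("the kernel grid path agrees with the reference CV on whole combos", {
  ds <- easy_dataset(n_per_class = 14, n_axis = 41)
  specs <- list(preprocess_spec("MC"), preprocess_spec("SNV"))
  gs <- grid_search_lv(ds, specs, max_lv = 3, folds = 4)
  expect_identical(nrow(gs$grid), 15L)
  for (row in c(2, 7, 11, 15)) {
    combo <- as.integer(gs$grid[row, 1:2])
    ref <- sport_cv(ds, specs, combo, folds = 4)
    expect_equal(gs$grid$ce[row], ref$ce, tolerance = 1e-9)
  }
  # the winner is optimal over its own grid and beats single-block combos
  expect_equal(gs$ce_cv, min(gs$grid$ce), tolerance = 1e-12)
  single <- rowSums(gs$grid[, 1:2] > 0) == 1
  expect_lte(gs$ce_cv, min(gs$grid$ce[single]))
})

test_that("grid search ties break towards parsimony, then lexicographic order", {
  # easy data: many combos reach CE 0; the reported winner must be the
  # lexicographically first among the smallest-total ones
  ds <- easy_dataset(n_per_class = 14, n_axis = 41)
  gs <- grid_search_lv(ds, list(preprocess_spec("MC"), preprocess_spec("SNV")),
                       max_lv = 4, folds = 4)
  zero <- gs$grid[gs$grid$ce <= gs$ce_cv, , drop = FALSE]
  tot <- rowSums(zero[, 1:2])
  cand <- zero[tot == min(tot), , drop = FALSE]
  expect_identical(gs$best_combo, as.integer(cand[1, 1:2]))
})

test_that("corrupting held-out rows never changes a fold's fitted parameters", {
  ds <- easy_dataset(n_per_class = 14, n_axis = 41)
  specs <- list(preprocess_spec("MC"), preprocess_spec("D1"))
  combo <- c(2, 1)
  cv1 <- sport_cv(ds, specs, combo, folds = 4, return_models = TRUE)
  ds2 <- ds
  bad <- cv1$fold == 1
  ds2$intensities[bad, ] <- ds2$intensities[bad, ] * 50 + 7
  cv2 <- sport_cv(ds2, specs, combo, folds = 4, return_models = TRUE)
  m1 <- cv1$models[[1]]
  m2 <- cv2$models[[1]]
  expect_identical(m1$blockset$train_means, m2$blockset$train_means)
  expect_identical(m1$submodels[[1]]$weights, m2$submodels[[1]]$weights)
  expect_identical(m1$lda$class_means, m2$lda$class_means)
  # and the held-out predictions for fold 1 change only through the
  # corrupted features, i.e. folds 2..4 models did change
  expect_false(identical(cv1$models[[2]]$lda$class_means,
                         cv2$models[[2]]$lda$class_means))
})

test_that("VIP report maps constructed contrasts onto the right wavenumbers", {
  # class B carries an extra band at 2400 cm^-1; VIP for class B should
  # exceed 1 there and stay low in a flat region
  ax <- seq(4000, 400, length.out = 181)
  profiles <- lapply(c(A = 0, B = 1), function(extra) {
    class_profile(if (extra) "B" else "A",
      data.frame(center = c(3200, 2400, 1600),
                 width = c(80, 40, 50),
                 amplitude = c(0.4, 0.15 + 0.25 * extra, 0.3),
                 amplitude_cv = 0.05),
      scatter_sd = 0.05, noise_sd = 0.003)
  })
  ds <- simulate_dataset(profiles, 30, ax, seed = 53)
  bs <- build_blocks(ds, list(preprocess_spec("MC"), preprocess_spec("SNV")))
  m <- sport_fit(bs, ds$labels, c(3, 3))
  vip <- sport_vip(m)
  expect_length(vip, 2)
  for (v in vip) {
    expect_equal(colSums(v$by_class^2),
                 c(A = length(ax), B = length(ax)), tolerance = 1e-6)
    expect_identical(dim(v$mask), dim(v$by_class))
  }
  v1 <- vip[[1]]
  at_2400 <- which.min(abs(v1$wavenumbers - 2400))
  flat <- which(v1$wavenumbers < 1200 & v1$wavenumbers > 600)
  expect_true(v1$mask[at_2400, "B"])
  expect_lt(mean(v1$by_class[flat, "B"]), 1)
})
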