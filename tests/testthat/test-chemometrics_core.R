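test_that("PCA reproduces geometry on degenerate cases", {
  # rank-1 matrix: one component reconstructs exactly
  u <- rnorm(8); v <- rnorm(5)
  X <- tcrossprod(u, v)
  m <- pca_fit(X, 1)
  recon <- tcrossprod(m$scores, m$loadings) + rep(m$mean, each = 8)
  expect_equal(recon, X, tolerance = 1e-10)
  # two points: PC1 parallel to their difference
  X2 <- rbind(c(1, 2, 3), c(3, 1, 0))
  m2 <- pca_fit(X2, 1)
  dvec <- X2[1, ] - X2[2, ]
  cosang <- sum(m2$loadings * dvec) / sqrt(sum(dvec^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-12)
  expect_error(pca_fit(X2, 2), "between 1 and")
})

test_that("PCA matches an explicit covariance eigendecomposition", {
  set.seed(11)
  X <- matrix(rnorm(60), 10, 6)
  k <- 4
  m <- pca_fit(X, k)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(m$component_variances, eg$values[1:k], tolerance = 1e-10)
  expect_equal(align_signs(eg$vectors[, 1:k], m$loadings), eg$vectors[, 1:k],
               tolerance = 1e-8)
  expect_equal(crossprod(m$loadings), diag(k), tolerance = 1e-10)
  expect_true(all(diff(m$component_variances) <= 1e-12))
})

test_that("T2 and Q match brute-force projection and residual computation", {
  set.seed(12)
  X <- matrix(rnorm(80), 16, 5)
  m <- pca_fit(X, 3)
  new <- matrix(rnorm(20), 4, 5)
  dg <- pca_t2_q(m, new)
  for (i in 1:4) {
    xc <- new[i, ] - m$mean
    t_ <- drop(crossprod(m$loadings, xc))
    expect_equal(dg$t2[i], sum(t_^2 / m$component_variances),
                 tolerance = 1e-10)
    expect_equal(dg$q[i], sum((xc - drop(m$loadings %*% t_))^2),
                 tolerance = 1e-10)
  }
  # the training mean row sits at the model center
  at_mean <- pca_t2_q(m, matrix(m$mean, 1))
  expect_equal(at_mean$t2, 0, tolerance = 1e-16)
  # full-rank model: all training Q vanish, and Q never grows with k
  full <- pca_t2_q(pca_fit(X, 5), X)
  expect_lt(max(full$q), 1e-18)
  q_prev <- pca_t2_q(pca_fit(X, 1), X)$q
  for (k in 2:5) {
    q_k <- pca_t2_q(pca_fit(X, k), X)$q
    expect_true(all(q_k <= q_prev + 1e-12))
    q_prev <- q_k
  }
})

test_that("PLS2 matches the textbook NIPALS oracle", {
  set.seed(13)
  X <- matrix(rnorm(12 * 5), 12, 5)
  Y <- matrix(rnorm(12 * 2), 12, 2)
  A <- 2
  m <- pls2_fit(X, Y, A)
  o <- nipals_oracle(X, Y, A)
  expect_equal(align_signs(o$weights, m$weights), o$weights,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(align_signs(o$scores, m$scores), o$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(align_signs(o$x_loadings, m$x_loadings), o$x_loadings,
               tolerance = 1e-8, ignore_attr = TRUE)
  # predictions are sign-invariant and must agree directly
  o_coef <- o$weights %*% solve(crossprod(o$x_loadings, o$weights),
                                t(o$y_loadings))
  pred_oracle <- scale(X, scale = FALSE) %*% o_coef +
    rep(colMeans(Y), each = 12)
  expect_equal(pls2_predict(m, X), pred_oracle, tolerance = 1e-8)
})

test_that("PLS2 score projection reproduces training scores and oracle scores on new data", {
  set.seed(14)
  X <- matrix(rnorm(15 * 6), 15, 6)
  Y <- dummy_code(rep(c("a", "b", "c"), 5))
  m <- pls2_fit(X, Y, 3)
  expect_equal(pls2_scores(m, X), m$scores, tolerance = 1e-8)
  # a row at the center projects to zero scores
  expect_equal(drop(pls2_scores(m, matrix(m$x_mean, 1))), rep(0, 3),
               tolerance = 1e-10)
  # score columns are mutually orthogonal
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("one latent variable suffices when Y is linear in one X direction", {
  set.seed(15)
  # orthonormal mean-zero predictor columns: the single informative
  # direction is then recovered exactly by the first component
  X <- qr.Q(qr(scale(matrix(rnorm(30 * 4), 30, 4), scale = FALSE)))
  w <- c(1, -2, 0.5, 3)
  Y <- cbind(X %*% w, -2 * X %*% w)
  m <- pls2_fit(X, Y, 1)
  resid <- scale(Y, scale = FALSE) - m$scores %*% t(m$y_loadings)
  expect_lt(sum(resid^2) / sum(scale(Y, scale = FALSE)^2), 1e-20)
})

test_that("with all LVs PLS2 predictions equal ordinary least squares", {
  set.seed(16)
  X <- matrix(rnorm(12 * 5), 12, 5)
  Y <- matrix(rnorm(12 * 3), 12, 3)
  m <- pls2_fit(X, Y, 5)
  ols <- stats::lm.fit(cbind(1, X), Y)
  expect_equal(pls2_predict(m, X), cbind(1, X) %*% ols$coefficients,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PLS deflation shrinks the X Frobenius norm monotonically", {
  set.seed(17)
  X <- matrix(rnorm(20 * 8), 20, 8)
  Y <- dummy_code(rep(c("a", "b"), 10))
  Xc <- scale(X, scale = FALSE)
  m <- pls2_fit(X, Y, 4)
  norms <- numeric(5)
  norms[1] <- sum(Xc^2)
  Xd <- Xc
  for (a in 1:4) {
    Xd <- Xd - tcrossprod(m$scores[, a], m$x_loadings[, a])
    norms[a + 1] <- sum(Xd^2)
  }
  expect_true(all(diff(norms) < 0))
})

test_that("VIP satisfies its normalization identity and formula", {
  set.seed(18)
  X <- matrix(rnorm(25 * 9), 25, 9)
  Y <- dummy_code(rep(c("a", "b", "c", "d", "e"), 5))
  m <- pls2_fit(X, Y, 3)
  v <- vip_scores(m)
  expect_equal(sum(v^2), 9, tolerance = 1e-8)
  # direct-formula oracle
  ssy <- m$ssy
  W <- m$weights
  vip_direct <- sqrt(9 * colSums(t(W^2) / colSums(W^2) * ssy) / sum(ssy))
  expect_equal(v, vip_direct, tolerance = 1e-10)
  # class-wise variant obeys the identity too
  for (ci in 1:5) {
    expect_equal(sum(vip_scores(m, ci)^2), 9, tolerance = 1e-8)
  }
})

test_that("a single informative variable gets the maximal VIP above 1", {
  set.seed(19)
  n <- 40
  X <- matrix(rnorm(n * 12, sd = 0.05), n, 12)
  cls <- rep(c("a", "b"), each = n / 2)
  X[cls == "b", 7] <- X[cls == "b", 7] + 3
  m <- pls2_fit(X, dummy_code(cls), 2)
  v <- vip_scores(m)
  expect_identical(which.max(v), 7L)
  expect_gt(v[7], 1)
})

test_that("LDA separates blobs, classifies class means, and matches a brute-force Mahalanobis oracle", {
  set.seed(21)
  n <- 30
  mu <- rbind(c(0, 0, 0), c(6, 0, 2), c(0, 7, -2))
  T_ <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(n * 3), n, 3), 2, mu[i, ], "+")
  }))
  labs <- rep(c("a", "b", "c"), each = n)
  m <- lda_fit(T_, labs)
  expect_identical(sum(lda_predict(m, T_) != labs), 0L)
  expect_identical(lda_predict(m, m$class_means), m$class_names)
  # oracle: equal-prior Mahalanobis under the same regularized pooled cov
  new <- matrix(rnorm(60), 20, 3)
  Sinv <- solve(m$pooled_cov)
  oracle <- apply(new, 1, function(x) {
    d2 <- apply(m$class_means, 1, function(mc) {
      drop(t(x - mc) %*% Sinv %*% (x - mc))
    })
    m$class_names[which.min(d2)]
  })
  expect_identical(lda_predict(m, new), oracle)
})

test_that("canonical variates are ordered and whitened within class", {
  set.seed(22)
  T_ <- rbind(matrix(rnorm(40), 20, 2),
              sweep(matrix(rnorm(40), 20, 2), 2, c(4, 1), "+"),
              sweep(matrix(rnorm(40), 20, 2), 2, c(2, -4), "+"))
  labs <- rep(c("a", "b", "c"), each = 20)
  m <- lda_fit(T_, labs)
  expect_true(all(diff(m$canonical_ratios) <= 1e-12))
  # unit pooled within-class variance along each canonical direction
  for (j in seq_len(ncol(m$canonical_directions))) {
    u <- m$canonical_directions[, j]
    expect_equal(drop(t(u) %*% m$pooled_cov %*% u), 1, tolerance = 1e-8)
  }
  cs <- canonical_scores(m, T_)
  expect_identical(dim(cs), c(60L, 2L))
  # between/within ratio computed from the scores is decreasing
  ratio <- vapply(1:2, function(j) {
    stats::anova(stats::lm(cs[, j] ~ labs))$`F value`[1]
  }, numeric(1))
  expect_gt(ratio[1], ratio[2])
})

test_that("LDA decisions are invariant to a consistent full-rank affine map", {
  set.seed(23)
  T_ <- rbind(matrix(rnorm(30), 15, 2),
              sweep(matrix(rnorm(30), 15, 2), 2, c(3, -2), "+"))
  labs <- rep(c("a", "b"), each = 15)
  new <- matrix(rnorm(24), 12, 2)
  M <- matrix(c(2, 0.5, -1, 1.5), 2)
  shift <- c(5, -7)
  base <- lda_predict(lda_fit(T_, labs, lambda = 0), new)
  mapped <- lda_predict(lda_fit(T_ %*% M + rep(shift, each = 30), labs,
                                lambda = 0),
                        new %*% M + rep(shift, each = 12))
  expect_identical(base, mapped)
})

test_that("LDA precondition failures are informative", {
  expect_error(lda_fit(matrix(rnorm(10), 5, 2), rep("a", 5)), "2 classes")
  expect_error(lda_fit(matrix(rnorm(6), 3, 2), c("a", "a", "b")),
               "fewer than 2 rows")
  # collinear features: singular without ridge, fit succeeds with it
  T_ <- cbind(rnorm(10), 0)
  T_ <- cbind(T_[, 1], T_[, 1])
  labs <- rep(c("a", "b"), 5)
  expect_error(lda_fit(T_, labs, lambda = 0), "singular")
  expect_s3_class(lda_fit(T_, labs, lambda = 1e-8), "lda_model")
})
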