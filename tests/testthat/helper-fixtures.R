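# Shared fixtures: small, fast synthetic datasets built in code.

# Short axis for unit tests (61 points, 3960..360 is out of band range, so
# use in-range ends).
tiny_axis <- function(n = 61) seq(4000, 400, length.out = n)

# Two-band, two-class profiles with controllable nuisance levels.
toy_profiles <- function(amplitude_cv = 0, scatter_sd = 0, offset_sd = 0,
                         slope_sd = 0, noise_sd = 0, n_classes = 2) {
  centers <- c(3000, 1500, 2200, 1000)
  lapply(seq_len(n_classes), function(ci) {
    amp <- rep(0.2, 4)
    amp[ci %% 4 + 1L] <- 0.6
    class_profile(
      class_name = paste0("C", ci),
      bands = data.frame(center = centers, width = c(60, 40, 50, 30),
                         amplitude = amp, amplitude_cv = amplitude_cv),
      scatter_sd = scatter_sd, baseline_offset_sd = offset_sd,
      baseline_slope_sd = slope_sd, noise_sd = noise_sd)
  })
}

# A small labeled dataset that is easy to classify: 4 classes, clear band
# contrasts, mild nuisance.
easy_dataset <- function(n_per_class = 21, n_axis = 101, seed = 42) {
  profiles <- lapply(1:4, function(ci) {
    amp <- c(0.3, 0.3, 0.3, 0.3)
    amp[ci] <- 0.9
    class_profile(
      class_name = LETTERS[ci],
      bands = data.frame(center = c(3200, 2400, 1600, 800),
                         width = c(80, 60, 50, 40),
                         amplitude = amp, amplitude_cv = 0.05),
      scatter_sd = 0.1, baseline_offset_sd = 0.01,
      baseline_slope_sd = 5e-6, noise_sd = 0.004)
  })
  simulate_dataset(profiles, n_per_class = n_per_class,
                   axis = seq(4000, 400, length.out = n_axis), seed = seed)
}

default_specs <- function() {
  list(preprocess_spec("MC"), preprocess_spec("SNV"),
       preprocess_spec("D1"), preprocess_spec("D2"))
}

# Independent textbook NIPALS PLS2 oracle: the u/w/t/q iteration with both
# X and Y deflation, exactly as written in the standard references.
nipals_oracle <- function(X, Y, A, tol = 1e-13, maxit = 10000) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  n <- nrow(X)
  W <- NULL; T_ <- NULL; P <- NULL; Q <- NULL
  for (a in seq_len(A)) {
    u <- Y[, which.max(colSums(Y^2))]
    repeat {
      w <- drop(crossprod(X, u)); w <- w / sqrt(sum(w^2))
      t_ <- drop(X %*% w)
      q <- drop(crossprod(Y, t_)) / sum(t_^2)
      u_new <- drop(Y %*% q) / sum(q^2)
      if (sqrt(sum((u_new - u)^2)) < tol * sqrt(sum(u_new^2))) {
        u <- u_new; break
      }
      u <- u_new
      maxit <- maxit - 1
      if (maxit < 0) stop("oracle did not converge")
    }
    p_ <- drop(crossprod(X, t_)) / sum(t_^2)
    X <- X - tcrossprod(t_, p_)
    Y <- Y - tcrossprod(t_, q)
    W <- cbind(W, w); T_ <- cbind(T_, t_); P <- cbind(P, p_); Q <- cbind(Q, q)
  }
  list(weights = W, scores = T_, x_loadings = P, y_loadings = Q)
}

# align column signs of B to A (PLS/PCA directions are sign-indeterminate)
align_signs <- function(A, B) {
  s <- sign(colSums(A * B))
  s[s == 0] <- 1
  B * rep(s, each = nrow(B))
}
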