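#' Spectral pretreatment specification
#'
#' One of the four pretreatments the ensemble uses: `MC` (mean centering
#' only), `SNV` (standard normal variate), `D1`/`D2` (first/second
#' Savitzky-Golay derivative). Package defaults follow the common
#' chemometric settings for mid-IR: 15-point window with a second-order
#' polynomial for D1 and a third-order polynomial for D2.
#'
#' @param method one of `"MC"`, `"SNV"`, `"D1"`, `"D2"`.
#' @param window odd filter window length (derivatives only).
#' @param polyorder polynomial order (derivatives only); must be smaller
#'   than `window`.
#' @return An object of class `preprocess_spec` with fields `method`,
#'   `window`, `polyorder`, `deriv_order`.
#' @examples
#' preprocess_spec("D1")
#' @export
preprocess_spec <- function(method = c("MC", "SNV", "D1", "D2"),
                            window = 15, polyorder = NULL) {
  method <- match.arg(method)
  deriv_order <- switch(method, MC = 0L, SNV = 0L, D1 = 1L, D2 = 2L)
  if (is.null(polyorder)) {
    polyorder <- switch(method, D1 = 2L, D2 = 3L, 0L)
  }
  if (method %in% c("D1", "D2")) {
    if (window %% 2 == 0) stop("'window' must be odd")
    if (window <= polyorder) stop("'window' must exceed 'polyorder'")
    if (polyorder < deriv_order) stop("'polyorder' must be >= derivative order")
  }
  structure(list(method = method, window = as.integer(window),
                 polyorder = as.integer(polyorder),
                 deriv_order = deriv_order),
            class = "preprocess_spec")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  if (x$method %in% c("D1", "D2")) {
    cat(sprintf("<preprocess_spec> %s (window %d, polyorder %d)\n",
                x$method, x$window, x$polyorder))
  } else {
    cat(sprintf("<preprocess_spec> %s\n", x$method))
  }
  invisible(x)
}

#' Standard normal variate
#'
#' Row-wise standardization: subtract the row mean, divide by the row
#' standard deviation (n-1 denominator). Removes per-spectrum additive
#' offsets and multiplicative scatter; invariant to any per-row affine map
#' `c*x + d` with `c > 0` (a negative `c` flips the sign of the output row).
#'
#' @param X numeric matrix, rows = spectra.
#' @return Matrix of the same shape; each row has mean 0 and sd 1.
#' @examples
#' snv(matrix(1:3, 1))  # -1 0 1
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop("SNV needs at least 2 spectral variables")
  m <- rowMeans(X)
  Xc <- X - m
  s <- sqrt(rowSums(Xc^2) / (p - 1))
  zero <- which(s == 0)
  if (length(zero)) {
    stop("constant spectrum (zero variance) in row ", zero[1L],
         ": SNV undefined for degenerate spectra")
  }
  Xc / s
}

#' Savitzky-Golay derivative
#'
#' Row-wise smoothed derivative by local polynomial least squares
#' (delegated to `signal::sgolayfilt`). Output has the same length as the
#' input: the `(window-1)/2` points at each edge are obtained by evaluating
#' the derivative of the polynomial fitted in the terminal window at the
#' off-center positions, so all preprocessed blocks stay column-aligned.
#'
#' The derivative is taken with respect to column index. On the
#' conventional descending wavenumber axis this flips the sign relative to
#' a derivative in wavenumber; the flip is a fixed linear transform of each
#' block and is irrelevant to classification.
#'
#' @param X numeric matrix, rows = spectra.
#' @param spec a [preprocess_spec()] with method `"D1"` or `"D2"`.
#' @return Matrix of derivatives, same shape as `X`.
#' @export
savgol_derivative <- function(X, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  if (!spec$method %in% c("D1", "D2")) {
    stop("'spec' must be a derivative pretreatment (D1 or D2)")
  }
  X <- as.matrix(X)
  if (spec$window %% 2 == 0) stop("'window' must be odd")
  if (ncol(X) < spec$window) {
    stop("need at least 'window' (", spec$window, ") spectral variables, got ",
         ncol(X))
  }
  t(apply(X, 1L, signal::sgolayfilt, p = spec$polyorder, n = spec$window,
          m = spec$deriv_order, ts = 1))
}

#' Column mean centering (fit / apply)
#'
#' Centering parameters are always fitted on training rows and re-applied
#' to new rows, so test spectra are centered with training means only.
#'
#' @param X numeric matrix of training rows.
#' @return `mean_center_fit`: the column-mean vector.
#' @export
mean_center_fit <- function(X) {
  colMeans(as.matrix(X))
}

#' @rdname mean_center_fit
#' @param means column-mean vector from [mean_center_fit()].
#' @return `mean_center_apply`: `X` with `means` subtracted from each row.
#' @export
mean_center_apply <- function(X, means) {
  X <- as.matrix(X)
  if (ncol(X) != length(means)) {
    stop("length of 'means' (", length(means),
         ") does not match number of columns (", ncol(X), ")")
  }
  X - rep(means, each = nrow(X))
}

# Apply the pretreatment part of a spec (everything except centering).
apply_pretreatment <- function(X, spec) {
  switch(spec$method,
         MC = as.matrix(X),
         SNV = snv(X),
         D1 = savgol_derivative(X, spec),
         D2 = savgol_derivative(X, spec))
}

#' Build the ensemble-preprocessed block set
#'
#' Applies each pretreatment to the training spectra and mean-centers every
#' block with its own training column means — the multiblock input of
#' SPORT. The canonical ensemble is `MC, SNV, D1, D2` (blocks X1..X4).
#'
#' @param train a labeled [spectra_dataset()] of training rows.
#' @param specs list of [preprocess_spec()] objects, one per block.
#' @return An object of class `block_set`: `blocks` (list of centered
#'   n x p matrices), `specs`, `train_means` (per-block column means),
#'   `wavenumbers`.
#' @export
build_blocks <- function(train, specs) {
  stopifnot(inherits(train, "spectra_dataset"))
  if (length(specs) == 0) stop("'specs' must be nonempty")
  specs <- lapply(specs, function(s) {
    if (is.character(s)) preprocess_spec(s) else s
  })
  blocks <- vector("list", length(specs))
  means <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    P <- apply_pretreatment(train$intensities, specs[[i]])
    means[[i]] <- mean_center_fit(P)
    blocks[[i]] <- mean_center_apply(P, means[[i]])
  }
  structure(list(blocks = blocks, specs = specs, train_means = means,
                 wavenumbers = train$wavenumbers),
            class = "block_set")
}

#' Preprocess new spectra with training block parameters
#'
#' Re-applies each block's pretreatment to new spectra and centers with the
#' *stored training* means — never re-fitted, so no information leaks from
#' prediction data into the model.
#'
#' @param blockset a [build_blocks()] result.
#' @param new a [spectra_dataset()] on the same wavenumber axis.
#' @return List of centered matrices, one per block.
#' @export
transform_blocks <- function(blockset, new) {
  stopifnot(inherits(blockset, "block_set"), inherits(new, "spectra_dataset"))
  if (!isTRUE(all.equal(blockset$wavenumbers, new$wavenumbers))) {
    stop("wavenumber axis of 'new' does not match the training axis")
  }
  lapply(seq_along(blockset$specs), function(i) {
    P <- apply_pretreatment(new$intensities, blockset$specs[[i]])
    mean_center_apply(P, blockset$train_means[[i]])
  })
}
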