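#' Spectral dataset container
#'
#' Bundles a wavenumber axis, an absorbance matrix and per-sample metadata
#' into the object every other function in the package consumes. Rows are
#' samples (spectra), columns are spectral variables; the axis is stored in
#' acquisition order, conventionally descending from 4000 to 400 cm^-1.
#'
#' @param intensities numeric matrix, n samples x p wavenumbers (absorbance,
#'   arbitrary units). No missing or non-finite values are allowed.
#' @param wavenumbers numeric vector of length p, strictly monotone
#'   (descending by convention).
#' @param sample_ids character vector of unique per-row identifiers;
#'   generated as `s001, s002, ...` when `NULL`.
#' @param labels optional character vector of class names, one per row;
#'   `NULL` for unlabeled prediction sets.
#' @return An object of class `spectra_dataset`: a list with elements
#'   `wavenumbers`, `intensities`, `labels`, `sample_ids`.
#' @examples
#' ds <- spectra_dataset(matrix(rnorm(12), 3, 4), c(10, 8, 6, 4))
#' ds
#' @export
spectra_dataset <- function(intensities, wavenumbers, sample_ids = NULL,
                            labels = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  n <- nrow(intensities)
  p <- ncol(intensities)
  if (length(wavenumbers) != p) {
    stop("length of 'wavenumbers' (", length(wavenumbers),
         ") does not match number of intensity columns (", p, ")")
  }
  if (p >= 2) {
    d <- diff(wavenumbers)
    if (!(all(d > 0) || all(d < 0))) {
      stop("wavenumber axis must be strictly monotone")
    }
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    bad <- which(!is.finite(intensities), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-finite intensity at row %d, column %d (%.6g cm^-1)",
      bad[1L], bad[2L], wavenumbers[bad[2L]]))
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%03d", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) {
    stop("'sample_ids' must have one entry per row")
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) {
    stop("duplicated sample id: ", dup[1L])
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("'labels' must have one entry per row")
  }
  dimnames(intensities) <- NULL
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         labels = labels, sample_ids = sample_ids),
    class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("<spectra_dataset> %d spectra x %d variables (%.6g-%.6g cm^-1)\n",
              nrow(x$intensities), ncol(x$intensities), rng[2L], rng[1L]))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  } else {
    cat("  unlabeled\n")
  }
  invisible(x)
}

#' Default wavenumber axis
#'
#' The mid-infrared export grid used throughout the package: 4000 down to
#' 400 cm^-1. At the default 1 cm^-1 spacing this yields exactly 3601
#' points, the width of the 320 x 3601 data matrix the workflow is designed
#' around. Spacing is a parameter, never hard-coded downstream: all
#' operations read the spacing off the stored axis.
#'
#' @param from,to axis end points in cm^-1 (descending storage order).
#' @param by positive step in cm^-1.
#' @return Numeric vector, descending.
#' @examples
#' length(default_wavenumber_axis())        # 3601
#' length(default_wavenumber_axis(by = 4))  # 901
#' @export
default_wavenumber_axis <- function(from = 4000, to = 400, by = 1) {
  if (by <= 0) stop("'by' must be positive")
  seq(from, to, by = -by)
}

#' Subset a spectral dataset by row
#'
#' @param ds a [spectra_dataset()].
#' @param idx integer or logical row index.
#' @return A `spectra_dataset` with the selected rows, in index order.
#' @export
spectra_subset <- function(ds, idx) {
  stopifnot(inherits(ds, "spectra_dataset"))
  spectra_dataset(ds$intensities[idx, , drop = FALSE], ds$wavenumbers,
                  sample_ids = ds$sample_ids[idx],
                  labels = if (!is.null(ds$labels)) ds$labels[idx])
}

#' Read a wide-format spectral CSV
#'
#' Expects the layout written by [write_spectra_csv()]: a `sample_id`
#' column, an optional `label` column, and one column per wavenumber with
#' the wavenumber value as its header. Row order is preserved.
#'
#' @param path path to a CSV file.
#' @return A [spectra_dataset()].
#' @export
read_spectra_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = "sample_id"),
                          data.table = TRUE, showProgress = FALSE)
  nm <- names(dt)
  if (!"sample_id" %in% nm) stop("missing 'sample_id' column in ", path)
  has_label <- "label" %in% nm
  wn_cols <- setdiff(nm, c("sample_id", "label"))
  wavenumbers <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(wavenumbers)) {
    stop("non-numeric wavenumber header: ", wn_cols[which(is.na(wavenumbers))[1L]])
  }
  n <- nrow(dt)
  X <- matrix(NA_real_, n, length(wn_cols))
  for (j in seq_along(wn_cols)) {
    col <- dt[[wn_cols[j]]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric intensity '%s' at row %d, column %s",
                     col[bad[1L]], bad[1L], wn_cols[j]))
      }
      col <- num
    }
    if (anyNA(col)) {
      stop(sprintf("missing intensity at row %d, column %s",
                   which(is.na(col))[1L], wn_cols[j]))
    }
    X[, j] <- col
  }
  spectra_dataset(X, wavenumbers,
                  sample_ids = dt[["sample_id"]],
                  labels = if (has_label) as.character(dt[["label"]]))
}

#' Write a spectral dataset to CSV
#'
#' Numeric values are formatted with 17 significant digits so that
#' `read_spectra_csv(write_spectra_csv(ds))` is lossless (bit-exact round
#' trip for doubles). Datasets without labels are written without a label
#' column.
#'
#' @param ds a [spectra_dataset()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_spectra_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectra_dataset"))
  header <- c("sample_id",
              if (!is.null(ds$labels)) "label",
              sprintf("%.17g", ds$wavenumbers))
  body <- matrix(sprintf("%.17g", ds$intensities), nrow = nrow(ds$intensities))
  cols <- c(list(ds$sample_ids),
            if (!is.null(ds$labels)) list(ds$labels),
            lapply(seq_len(ncol(body)), function(j) body[, j]))
  dt <- data.table::setDT(cols)
  data.table::setnames(dt, header)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  close(con)
  data.table::fwrite(dt, path, quote = FALSE, sep = ",")
  invisible(path)
}
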