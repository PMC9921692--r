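#' Duplex calibration/test split of one class
#'
#' Snee's Duplex selection on Euclidean distances: the two mutually
#' farthest points seed the calibration set, the two farthest among the
#' remainder seed the test set (with `n_test = 1` only the lower-id member
#' of that pair is taken); thereafter the sets alternate — calibration
#' first — each time receiving the remaining point with maximal minimum
#' distance to the receiving set, until the test set reaches `n_test`. All
#' remaining points then join the calibration set. Fully deterministic;
#' distance ties are broken by lowest sample id.
#'
#' Distances are computed on the rows as given (the raw spectral
#' representation); Euclidean distances are translation-invariant, so
#' mean centering the block beforehand would not change the split.
#'
#' @param X numeric matrix, rows of one class.
#' @param n_test number of rows to place in the test set
#'   (`1 <= n_test < n`; `2*n_test <= n` recommended).
#' @param ids row identifiers (default `1..n` as character).
#' @return List with `calibration_ids` and `test_ids`: disjoint, together
#'   covering all ids.
#' @export
duplex_split <- function(X, n_test, ids = as.character(seq_len(nrow(X)))) {
  X <- as.matrix(X)
  n <- nrow(X)
  ids <- as.character(ids)
  if (length(ids) != n) stop("'ids' must have one entry per row")
  if (n < 4) stop("Duplex needs at least 4 rows")
  if (n_test < 1) stop("'n_test' must be >= 1")
  if (n_test >= n) stop("'n_test' must be smaller than the number of rows")
  D <- as.matrix(stats::dist(X))

  farthest_pair <- function(avail) {
    av <- avail[order(ids[avail])]
    best <- c(av[1L], av[2L]); bd <- -Inf
    for (a in seq_along(av)) {
      for (b in seq_along(av)) {
        if (b <= a) next
        if (D[av[a], av[b]] > bd) {
          bd <- D[av[a], av[b]]
          best <- c(av[a], av[b])
        }
      }
    }
    best
  }
  next_point <- function(avail, members) {
    av <- avail[order(ids[avail])]
    dmin <- apply(D[av, members, drop = FALSE], 1L, min)
    av[which.max(dmin)]
  }

  avail <- seq_len(n)
  cal <- farthest_pair(avail)
  avail <- setdiff(avail, cal)
  if (n_test >= 2) {
    test <- farthest_pair(avail)
  } else {
    pair <- farthest_pair(avail)
    test <- pair[order(ids[pair])][1L]
  }
  avail <- setdiff(avail, test)
  while (length(test) < n_test && length(avail) > 0) {
    if (length(avail) > 0) {           # calibration receives first
      nx <- next_point(avail, cal)
      cal <- c(cal, nx)
      avail <- setdiff(avail, nx)
    }
    if (length(test) < n_test && length(avail) > 0) {
      nx <- next_point(avail, test)
      test <- c(test, nx)
      avail <- setdiff(avail, nx)
    }
  }
  cal <- c(cal, avail)
  list(calibration_ids = ids[sort(cal)], test_ids = ids[sort(test)])
}

#' Stratified Duplex split of a labeled dataset
#'
#' Applies [duplex_split()] within every class and unions the results, so
#' each class contributes exactly `n_test_per_class` spectra to the test
#' set. With the reference design (4 classes x 80 spectra, 25 per class to
#' the test set) this yields a 220-spectrum calibration set and a
#' 100-spectrum validation set.
#'
#' @param dataset a labeled [spectra_dataset()].
#' @param n_test_per_class test spectra per class.
#' @return List with `calibration_ids` and `test_ids` (sample ids).
#' @export
stratified_duplex <- function(dataset, n_test_per_class) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (is.null(dataset$labels)) stop("dataset must be labeled")
  cal <- character(0)
  test <- character(0)
  for (cl in sort(unique(dataset$labels))) {
    rows <- which(dataset$labels == cl)
    if (length(rows) <= n_test_per_class) {
      stop("class ", cl, " has only ", length(rows),
           " rows; needs more than n_test_per_class = ", n_test_per_class)
    }
    sp <- duplex_split(dataset$intensities[rows, , drop = FALSE],
                       n_test_per_class, ids = dataset$sample_ids[rows])
    cal <- c(cal, sp$calibration_ids)
    test <- c(test, sp$test_ids)
  }
  list(calibration_ids = cal, test_ids = test)
}

#' Deterministic stratified k-fold assignment
#'
#' Venetian-blinds folds: rows are sorted by class, then by sample id, and
#' assigned cyclically to folds `1, 2, ..., k, 1, 2, ...` within each
#' class. Per-class fold sizes differ by at most one, every fold contains
#' every class, and the assignment is seed-independent.
#'
#' @param labels class label per row.
#' @param folds number of folds (default 7).
#' @param ids optional sample ids defining the within-class ordering
#'   (default: original row order).
#' @return Integer vector of fold ids (1..folds), in input row order.
#' @export
kfold_indices <- function(labels, folds = 7, ids = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (is.null(ids)) ids <- seq_len(n)
  if (folds < 2) stop("'folds' must be >= 2")
  cnt <- table(labels)
  if (any(cnt < folds)) {
    stop("class ", names(cnt)[which(cnt < folds)[1L]],
         " has fewer rows (", min(cnt), ") than folds (", folds, ")")
  }
  fold <- integer(n)
  for (cl in sort(unique(labels))) {
    rows <- which(labels == cl)
    rows <- rows[order(ids[rows])]
    fold[rows] <- rep_len(seq_len(folds), length(rows))
  }
  fold
}

#' Confusion matrix and classification metrics
#'
#' Rows of the confusion matrix are true classes, columns predictions.
#' Per-class sensitivity is the percentage of the class's samples
#' correctly assigned to it; per-class specificity the percentage of
#' other-class samples not assigned to it; total correct % is
#' `100 * trace / n` (the complement of the classification error CE).
#'
#' @param true_labels,predicted_labels aligned label vectors over a shared
#'   class set.
#' @param class_names optional fixed class ordering.
#' @return List: `confusion` (c x c count matrix), `sensitivity`,
#'   `specificity` (named % vectors), `total_correct` (%).
#' @export
confusion_and_metrics <- function(true_labels, predicted_labels,
                                  class_names = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels) ||
      length(true_labels) == 0) {
    stop("label vectors must be nonempty and aligned")
  }
  if (is.null(class_names)) {
    class_names <- sort(unique(c(true_labels, predicted_labels)))
  }
  out <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(out)) stop("label outside the class set: ", out[1L])
  f_true <- factor(true_labels, levels = class_names)
  f_pred <- factor(predicted_labels, levels = class_names)
  cm <- unclass(table(true = f_true, predicted = f_pred))
  n <- length(true_labels)
  sens <- 100 * diag(cm) / rowSums(cm)
  spec <- vapply(seq_along(class_names), function(i) {
    others <- sum(cm) - sum(cm[i, ])
    rejected <- others - (sum(cm[, i]) - cm[i, i])
    100 * rejected / others
  }, numeric(1))
  names(spec) <- class_names
  list(confusion = cm, sensitivity = sens, specificity = spec,
       total_correct = 100 * sum(diag(cm)) / n)
}
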