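#' Class profile for synthetic FT-IR spectra
#'
#' Describes one class of the generator: a set of Gaussian absorbance bands
#' plus the nuisance structure real ATR-FT-IR measurements carry —
#' per-spectrum multiplicative scatter, linear baseline drift and additive
#' white noise.
#'
#' @param class_name class label attached to generated rows.
#' @param bands data frame with columns `center` (cm^-1), `width`
#'   (Gaussian sigma, cm^-1), `amplitude` (mean peak absorbance, a.u.) and
#'   `amplitude_cv` (relative sd of the per-spectrum lognormal amplitude
#'   jitter).
#' @param scatter_sd sd of the per-spectrum log-multiplicative scatter
#'   factor (0 disables scatter).
#' @param baseline_offset_sd sd of the per-spectrum constant baseline
#'   offset (a.u.).
#' @param baseline_slope_sd sd of the per-spectrum baseline slope
#'   (a.u. per cm^-1).
#' @param noise_sd sd of additive white Gaussian noise per spectral point.
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(class_name, bands, scatter_sd = 0,
                          baseline_offset_sd = 0, baseline_slope_sd = 0,
                          noise_sd = 0) {
  bands <- as.data.frame(bands)
  need <- c("center", "width", "amplitude", "amplitude_cv")
  if (!all(need %in% names(bands))) {
    stop("'bands' must have columns ", paste(need, collapse = ", "))
  }
  if (any(bands$width <= 0)) stop("band widths must be > 0")
  if (any(bands$amplitude < 0)) stop("band amplitudes must be >= 0")
  if (any(bands$amplitude_cv < 0)) stop("amplitude_cv must be >= 0")
  if (scatter_sd < 0 || noise_sd < 0 || baseline_offset_sd < 0 ||
      baseline_slope_sd < 0) {
    stop("nuisance standard deviations must be >= 0")
  }
  structure(
    list(class_name = as.character(class_name), bands = bands,
         scatter_sd = scatter_sd, baseline_offset_sd = baseline_offset_sd,
         baseline_slope_sd = baseline_slope_sd, noise_sd = noise_sd),
    class = "class_profile")
}

# Shared band table of the four celery ecotype profiles. Centers are the
# wavenumbers where real celery leaf spectra absorb (O-H/N-H around 3276,
# C-H stretches at 2916/2849, ester C=O at 1735, water bending/amide around
# 1640, aromatic/skeletal 1584, 1405, and polysaccharide C-O modes at
# 1100/1050/1029/1007 cm^-1); widths reflect the broad hydroxyl band vs the
# sharper fingerprint peaks.
.default_band_table <- function() {
  data.frame(
    center = c(3276, 2916, 2849, 1735, 1640, 1584, 1405, 1100, 1050, 1029, 1007),
    width  = c(  85,   16,   13,   11,   28,   12,   11,   16,   12,    9,    8),
    base   = c(0.45, 0.20, 0.12, 0.08, 0.35, 0.10, 0.10, 0.15, 0.15, 0.12, 0.10))
}

#' Default four-class celery ecotype profiles
#'
#' Four profiles (Elne, Magnum, TorricellaBlack, TreviBlack) share eleven
#' band centers; class structure comes from amplitude contrasts. The two
#' black-celery profiles carry elevated carbohydrate/lipid bands at
#' 2916, 2849 and 1735 cm^-1; the two common profiles carry elevated
#' hydroxyl and cell-wall bands at 3276, 1584, 1405, 1029 and 1007 cm^-1,
#' so the black-vs-common contrast dominates the variance. A smaller
#' secondary amplitude offset separates the two ecotypes within each pair,
#' making all four classes separable.
#'
#' Nuisance defaults (multiplicative scatter sd 0.15 on the log scale,
#' baseline offset/slope drift, additive noise sd 0.005 a.u., 8% amplitude
#' jitter) are sized so that no single pretreatment is sufficient on its
#' own: SNV removes the scatter, derivatives remove the baseline.
#' `hard = TRUE` doubles the scatter, roughly quadruples the noise and
#' inflates the amplitude jitter, for stress-testing the multiblock
#' advantage.
#'
#' @param hard logical; raise noise, scatter and amplitude jitter.
#' @return Named list of four [class_profile()] objects.
#' @examples
#' pr <- default_profiles()
#' names(pr)
#' @export
default_profiles <- function(hard = FALSE) {
  tab <- .default_band_table()
  black_idx <- match(c(2916, 2849, 1735), tab$center)
  common_idx <- match(c(3276, 1584, 1405, 1029, 1007), tab$center)
  mult <- matrix(1, 4, nrow(tab),
                 dimnames = list(c("Elne", "Magnum", "TorricellaBlack",
                                   "TreviBlack"), NULL))
  mult[c("Elne", "Magnum"), common_idx] <- 1.20
  mult[c("TorricellaBlack", "TreviBlack"), black_idx] <- 1.25
  # secondary within-pair contrasts
  mult["Elne", match(c(1029, 1007), tab$center)] <- 1.50
  mult["Magnum", match(c(3276, 1584, 1405), tab$center)] <- 1.50
  mult["TorricellaBlack", match(2916, tab$center)] <- 1.55
  mult["TorricellaBlack", match(1100, tab$center)] <- 1.20
  mult["TreviBlack", match(c(2849, 1735), tab$center)] <- 1.55
  mult["TreviBlack", match(1050, tab$center)] <- 1.20

  amplitude_cv <- if (hard) 0.15 else 0.08
  scatter_sd <- if (hard) 0.30 else 0.15
  noise_sd <- if (hard) 0.02 else 0.005
  lapply(stats::setNames(nm = rownames(mult)), function(cl) {
    class_profile(
      class_name = cl,
      bands = data.frame(center = tab$center, width = tab$width,
                         amplitude = tab$base * mult[cl, ],
                         amplitude_cv = amplitude_cv),
      scatter_sd = scatter_sd,
      baseline_offset_sd = 0.02,
      baseline_slope_sd = 2e-5,
      noise_sd = noise_sd)
  })
}

# Noiseless band sum of a profile on an axis: sum_b a_b exp(-(v-c_b)^2/(2 s_b^2))
band_sum <- function(profile, axis) {
  G <- exp(-outer(axis, profile$bands$center, "-")^2 /
             rep(2 * profile$bands$width^2, each = length(axis)))
  drop(G %*% profile$bands$amplitude)
}

#' Simulate a class-structured spectral dataset
#'
#' Each spectrum is
#' `m_i * sum_b a_ib * exp(-(v - c_b)^2 / (2 s_b^2)) + (o_i + sl_i * v) + eps_i(v)`
#' with lognormal per-spectrum band amplitudes `a_ib` (mean `amplitude`,
#' relative sd `amplitude_cv`), multiplicative scatter `m_i = exp(N(0,
#' scatter_sd))`, Gaussian baseline offset/slope `o_i`, `sl_i`, and white
#' Gaussian noise `eps`. Classes are generated on independent substreams
#' seeded as `seed + class index`, so adding a class never perturbs the
#' spectra of earlier classes.
#'
#' @param profiles list of [class_profile()] objects (e.g.
#'   [default_profiles()]).
#' @param n_per_class spectra per class (the reference design uses 80).
#' @param axis wavenumber axis; default [default_wavenumber_axis()].
#' @param seed integer seed; the run is fully reproducible from it.
#' @return A labeled [spectra_dataset()] with
#'   `length(profiles) * n_per_class` rows, grouped by class in profile
#'   order; sample ids are `<class>_<index>`.
#' @examples
#' ds <- simulate_dataset(default_profiles(), n_per_class = 3,
#'                        axis = default_wavenumber_axis(by = 50), seed = 1)
#' nrow(ds$intensities)
#' @export
simulate_dataset <- function(profiles, n_per_class = 80,
                             axis = default_wavenumber_axis(), seed = 1) {
  if (length(profiles) == 0) stop("'profiles' must be a nonempty list")
  if (n_per_class < 1) stop("'n_per_class' must be >= 1")
  axis <- as.numeric(axis)
  p <- length(axis)
  rng <- range(axis)
  blocks <- vector("list", length(profiles))
  ids <- character(0)
  labels <- character(0)
  for (ci in seq_along(profiles)) {
    pr <- profiles[[ci]]
    stopifnot(inherits(pr, "class_profile"))
    if (any(pr$bands$center < rng[1L] | pr$bands$center > rng[2L])) {
      stop("band center outside the axis range for class ", pr$class_name)
    }
    set.seed(seed + ci)
    n <- n_per_class
    nb <- nrow(pr$bands)
    # lognormal amplitudes with exact mean = amplitude, relative sd = cv
    sdlog <- sqrt(log1p(pr$bands$amplitude_cv^2))
    meanlog <- log(pr$bands$amplitude) - sdlog^2 / 2
    A <- matrix(stats::rlnorm(n * nb, rep(meanlog, each = n),
                              rep(sdlog, each = n)), n, nb)
    A[, pr$bands$amplitude == 0] <- 0
    G <- exp(-outer(pr$bands$center, axis, "-")^2 /
               (2 * pr$bands$width^2))        # nb x p
    m <- exp(stats::rnorm(n, 0, pr$scatter_sd))
    off <- stats::rnorm(n, 0, pr$baseline_offset_sd)
    slope <- stats::rnorm(n, 0, pr$baseline_slope_sd)
    eps <- matrix(stats::rnorm(n * p, 0, pr$noise_sd), n, p)
    X <- (m * (A %*% G)) + outer(off, rep(1, p)) + outer(slope, axis) + eps
    blocks[[ci]] <- X
    ids <- c(ids, sprintf("%s_%03d", pr$class_name, seq_len(n)))
    labels <- c(labels, rep(pr$class_name, n))
  }
  spectra_dataset(do.call(rbind, blocks), axis, sample_ids = ids,
                  labels = labels)
}
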