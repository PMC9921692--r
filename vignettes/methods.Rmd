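---
title: "Multiblock SPORT-LDA and SIMCA for infrared spectral fingerprints: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiblock SPORT-LDA and SIMCA for infrared spectral fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

ATR-FT-IR spectroscopy gives one absorbance spectrum per plant sample with
no sample preparation: a vector of ~3600 absorbances over 4000–400 cm⁻¹.
Ecotypes of the same crop grown under identical conditions differ only in
the relative abundance of shared constituents (water, carbohydrates,
lipids, cell-wall polysaccharides), so their spectra share every band and
differ by small amplitude contrasts buried under per-measurement nuisance:
multiplicative scatter from variable contact with the ATR crystal,
baseline drift, and detector noise. The task is four-class discrimination
(two common and two black celery ecotypes) plus one-class modeling of the
protected black ecotypes.

This package implements the full workflow: spectral pretreatments, the
ensemble-preprocessed multiblock classifier SPORT-LDA, SIMCA class
modeling, PCA diagnostics, VIP variable ranking, and Duplex set splitting
— together with a synthetic spectra generator that stands in for the
original field samples, which are not publicly released.

## Models

### Pretreatment ensemble

Four copies of the calibration matrix form the blocks X₁…X₄:

* **MC** — column mean centering only;
* **SNV** — each row standardized to mean 0, sd 1 (n−1 denominator);
  removes per-spectrum offset and multiplicative scatter; invariant to
  `c·x + d` with `c > 0`;
* **D1 / D2** — Savitzky–Golay derivatives, 15-point window, polynomial
  order 2 (first derivative) and 3 (second derivative); remove baseline
  offset (D1) and slope (D2).

Every block, including the derivative blocks, is mean-centered with its
training column means (centering is required by PLS; whether the original
analysis centered its derivative blocks is not stated, so the package
always does and records the choice here). The 7 points at each spectrum
edge are filled by evaluating the derivative of the polynomial fitted in
the terminal window, so all blocks keep the full width and stay
column-aligned. Derivatives are taken with respect to column index on the
conventional descending axis; this flips the sign relative to a
derivative in wavenumber, a fixed linear map with no effect on any
classifier downstream (it is nevertheless documented and tested).

### SPORT-LDA

SPORT is SO-PLS applied to differently preprocessed copies of one matrix.
Blocks are visited in order; block *i* is orthogonalized against the
scores already extracted (X⊥ = X − T(TᵀT)⁻¹TᵀX), then contributes its own
PLS2 components against the centered one-hot class matrix; a per-block
count of 0 discards the block. LDA (equal priors, pooled covariance,
minimum Mahalanobis distance) on the concatenated scores gives the
classifier, and its canonical variates give the class-separation map.

Two conventions were genuinely open and are resolved as follows:

* orthogonalization acts on the next block's X against accumulated
  *scores* (the SO-PLS convention), not on predicted responses;
* each block's PLS is fitted against the original centered dummy Y rather
  than Y-residuals — provably equivalent here, because the orthogonalized
  block has zero covariance with the previously extracted scores
  (X⊥ᵀT = 0 implies X⊥ᵀ(Y − TQᵀ) = X⊥ᵀY), so the weights and scores are
  identical either way.

PLS2 components are extracted at the NIPALS fixed point: the weight
vector of each component is the dominant left singular vector of the
current XᵀY, computed exactly through the c×c eigenproblem of (XᵀY)ᵀ(XᵀY).
This is what the textbook u/w/t/q iteration converges to; solving it
exactly makes the fit deterministic and immune to the slow convergence the
iteration exhibits when deflated components have near-equal response
eigenvalues. Components are nested, which the model-selection search
exploits.

Model complexity is chosen by stratified 7-fold cross-validation over all
per-block LV combinations 0–10, minimizing the pooled classification
error CE (100 × misclassified / total); ties prefer the smallest total LV
count, then the lexicographically earliest combination (parsimony first,
determinism second). Folds are deterministic venetian blinds after
sorting by class and sample id; the fold scheme of the original analysis
is unstated, so a seed-independent choice was preferred. Preprocessing
means, orthogonalization, PLS and LDA are all refitted inside every fold
— a leakage test corrupts held-out rows and checks that the fold model is
bit-identical.

Two computational devices keep the full 11⁴-combination grid tractable,
neither changing any number: nested NIPALS components let one fit at the
largest requested LV count serve all smaller counts for a given
orthogonalization state, and because p ≫ n the whole tree runs in the
n-dimensional sample space on Gram matrices (G = XXᵀ), whose recursions
are the exact images of the wide-matrix operations. The test suite checks
the kernel path against the plain path on whole combinations. A `coarse`
grid (levels 0, 1, 3, 5, 7, 10 per block, 1295 combinations) is the
desk-scale default in the analysis scripts.

### SIMCA

One PCA model per modeled class, fitted to that class's training rows
only, after the class's own pretreatment and centering ("individual
modeling of categories" taken literally — no other class influences any
model parameter). Samples are scored by the reduced combined distance

d = √( (Q/Q₀)² + (T²/T²₀)² ),

where Q is the squared orthogonal residual, T² the Hotelling leverage,
and Q₀, T²₀ their training means. A sample is accepted iff d ≤ threshold
(boundary inclusive, an arbitrary but fixed convention). The reference
analysis states neither its distance statistic nor its threshold; any
standard SIMCA variant was admissible, and this one was chosen because it
is simple, distribution-light and cross-validation-honest: the threshold
is the empirical 95th percentile of *cross-validated* training distances,
so it is not biased low by resubstitution. Coverage on held-out
same-distribution data is checked to sit within three binomial standard
deviations of the nominal 95% at n = 2000.

Model selection scans the four pretreatments × component counts up to
K_max = 15 in 7-fold CV over the target class (non-target rows are scored
against every fold model); efficiency — the geometric mean of sensitivity
and specificity — is maximized, with ties resolved toward fewer
components. Inside the scan, fold models use the 95th percentile of their
own training distances as threshold (nested CV would be disproportionate);
the finally chosen configuration is refitted with the CV-calibrated
threshold.

### Duplex splitting

Calibration/test splitting uses Snee's Duplex per class: mutually
farthest pair to calibration, next farthest pair to test, then alternate
(calibration first), each set receiving the remaining point with maximal
minimum distance to it, until the test set holds its quota; leftovers go
to calibration. Distances are Euclidean on the raw spectra (translation
invariance makes prior centering irrelevant; the representation the
original analysis fed Duplex is unstated, and raw-spectrum distances use
no fitted parameters). Ties are broken by lowest sample id, and with a
test quota of one the lower-id member of the farthest remaining pair is
taken, so the algorithm is fully deterministic — a property the tests
exercise together with the partition guarantees. With 80 spectra per
class and 25 to the test set, the reference 220/100 partition follows.

## The synthetic generator

Each class is a `class_profile`: eleven Gaussian bands at the wavenumbers
where celery leaf spectra absorb (3276, 2916, 2849, 1735, 1640, 1584,
1405, 1100, 1050, 1029, 1007 cm⁻¹), with class-specific mean amplitudes;
a spectrum is

m·Σ_b a_b g_b(ν) + (o + s·ν) + ε(ν),

with lognormal per-spectrum band amplitudes (mean exactly the profile
amplitude, relative sd `amplitude_cv` — lognormality keeps absorbance
positive), multiplicative scatter m = exp N(0, 0.15) (the effect SNV
removes, justifying block X₂), Gaussian baseline offset (sd 0.02 a.u.)
and slope (sd 2·10⁻⁵ a.u./cm⁻¹, the effect derivatives remove), and white
noise (sd 0.005 a.u.). Gaussian rather than Lorentzian/Voigt line shapes
suffice for exercising the statistics and are one line to change. Classes
are generated on substreams seeded `seed + class index`, so adding a
class never perturbs earlier ones.

The default amplitude table makes the black-vs-common contrast dominant
(elevated 2916/2849/1735 cm⁻¹ bands for the black pair, elevated
3276/1584/1405/1029/1007 cm⁻¹ bands for the common pair) and separates
the ecotypes within each pair by secondary offsets on disjoint bands
(ratio ≈ 1.25 against 8% amplitude jitter). These levels were fixed once,
at design time, so that the four classes are clearly separable — the
benchmark regime sits in the high 90s of percent test accuracy — while no
single pretreatment alone handles all the nuisance. A `hard = TRUE` mode
doubles the scatter and roughly quadruples the noise for stress tests.

What the generator does *not* emulate: ATR penetration-depth physics,
instrument line-shape, band-position shifts, correlated (pink) noise, and
biological covariance between constituents. Passing benchmarks on these
spectra therefore demonstrate the correctness and statistical behavior of
the algorithms under the stated nuisance model — not field performance on
real leaves.

## Problem sizes and numerical choices

* The package default axis is 4000…400 cm⁻¹ at 1 cm⁻¹ (3601 variables),
  matching the reference matrix geometry; structural checks use it. The
  analysis scripts, the repeated-seed benchmarks and the acceptance
  script work on the 4 cm⁻¹ grid (901 variables) — the instrument's
  stated optical resolution; the 1 cm⁻¹ export grid carries no extra
  information, and the coarser grid keeps the repeated studies at desk
  scale.
* The 20-seed SPORT benchmark (80 spectra/class, Duplex 25/class, coarse
  grid, 7-fold CV) expects ≥ 90% test accuracy and VIP > 1 coverage of
  the black-celery marker bands (2916, 2849, 1735 cm⁻¹, within one grid
  step) in at least 18 of 20 seeds.
* Orthonormal bases for orthogonalization truncate singular values below
  10⁻¹⁰ relative (rank-deficient prior scores degrade gracefully, with a
  message, never an error).
* LDA regularizes the pooled covariance by λ·trace(S)/d on the diagonal,
  λ = 10⁻⁸ — CV folds can make score covariances near-singular; the
  canonical eigenproblem is solved in whitened (Cholesky) coordinates.
* SNV uses the n−1 standard deviation (the common chemometric
  convention; any consistent choice only rescales rows).
* Class-wise VIP (used to color variables by the class they
  characterize) computes the response sum of squares from that class's
  dummy column within each retained block's submodel; the variant used in
  the original analysis is not defined, and this is the recorded choice.
  `ΣⱼVIPⱼ² = p` holds per block and class.
* CSV round trips are lossless: numerics are written with 17 significant
  digits.

## Known limitations

* SIMCA efficiencies are not comparable to any published table computed
  on the unreleased field data; the workflow reproduces the *shape* of
  that analysis (selection table, acceptance plots, test metrics), not
  its numbers.
* The grid search's parsimony tie-break deliberately discards redundant
  blocks: on clearly separable data the winning combination often uses
  one or two blocks at CE_CV ≈ 0, and which pretreatment survives varies
  with the seed. That is the expected behavior of an ensemble of
  deliberately redundant pretreatments, not a defect.
* Duplex, being deterministic and extremal, places the most peripheral
  samples in the calibration set; its test sets are interpolative by
  construction.
* No multi-class fusion rule is provided for SIMCA (the two black-celery
  models are independent, as in the reference analysis), and
  F-distribution acceptance limits with estimated degrees of freedom are
  out of scope.
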