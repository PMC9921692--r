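# sportsimca

Chemometric classification of ATR-FT-IR spectral fingerprints, built for
the problem of telling apart closely related plant ecotypes — here four
celery (*Apium graveolens*) varieties, two common (Elne, Magnum) and two
protected black ones (Torricella Peligna Black, Trevi Black) — whose
spectra share every absorption band and differ only in relative band
amplitudes under heavy measurement nuisance.

The package implements the complete workflow:

* **Spectral pretreatments** — mean centering (MC), standard normal
  variate (SNV), first/second Savitzky–Golay derivatives (D1/D2;
  15-point window, polynomial order 2/3), assembled into the
  ensemble-preprocessed block set X₁…X₄.
* **SPORT-LDA** — sequential preprocessing through orthogonalization:
  each block is orthogonalized against the PLS scores already extracted
  from earlier blocks (X⊥ = X − T(TᵀT)⁻¹TᵀX), contributes its own PLS2
  latent variables against the dummy-coded classes, and linear
  discriminant analysis on the concatenated scores classifies by pooled-
  covariance Mahalanobis distance. Per-block LV counts (0–10, 0 =
  discard) are selected by stratified 7-fold cross-validation minimizing
  the classification error CE_CV.
* **SIMCA** — one-class modeling: a per-class PCA with acceptance by the
  reduced distance d = √((Q/Q₀)² + (T²/T²₀)²) against a cross-validated
  95th-percentile threshold; models are selected by CV efficiency
  √(sensitivity × specificity) across pretreatments and component counts.
* **Diagnostics and ranking** — PCA with Hotelling T² vs Q residuals;
  variable importance in projection (VIP), overall and class-wise, with
  the conventional VIP > 1 relevance mask mapped back to wavenumbers.
* **Validation machinery** — deterministic per-class Duplex
  calibration/test splitting, venetian-blind k-fold partitioning,
  confusion matrices with per-class sensitivity/specificity.
* **Synthetic data** — a generator of class-structured FT-IR-like spectra
  (Gaussian bands + lognormal amplitude jitter + multiplicative scatter +
  baseline drift + white noise) emulating the four ecotype classes, so
  the entire workflow is testable end to end without the original field
  data (available only on request from its authors).

## Worked example

The `analysis/` scripts run the whole study on synthetic spectra
(4 classes × 80 spectra, 901 variables on the 4 cm⁻¹ grid, seed 2026):

```sh
Rscript analysis/01_simulate.R    # simulate + Duplex split
Rscript analysis/02_explore_pca.R # exploratory PCA, T2/Q
Rscript analysis/03_sport.R       # SPORT-LDA: CV grid, test metrics, VIP
Rscript analysis/04_simca.R       # SIMCA: selection tables, test metrics
```

Stage 1 prints the partition the classifiers consume — 220 calibration /
100 validation spectra (25 per class, Duplex within each class). Stage 3
then reports:

```
selected LVs per block (MC,SNV,D1,D2): 0,0,0,5 | CE_CV 0.00% (correct rate 100.0%)
test accuracy: 100.0%
```

i.e. cross-validation kept five latent variables from the D2 block and
discarded the redundant blocks (the parsimony tie-break at CE_CV = 0),
and every one of the 100 held-out spectra is classified correctly — the
synthetic ecotypes are deliberately clearly separable. Stage 4 models the
two black classes alone:

```
TorricellaBlack: chose D2 with 5 PCs (CV efficiency 95.8%)
  test: sensitivity 80.0%, specificity 98.7%, efficiency 88.8%
TreviBlack: chose D2 with 5 PCs (CV efficiency 95.6%)
  test: sensitivity 96.0%, specificity 97.3%, efficiency 96.7%
```

sensitivity being the share of the modeled ecotype's validation spectra
accepted by its class model, specificity the share of all other ecotypes'
spectra rejected. Outputs (CV grids, canonical scores, VIP > 1
wavenumbers, SIMCA distances with thresholds) land as CSV under
`results/`.

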