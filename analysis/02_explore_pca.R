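#!/usr/bin/env Rscript
# Stage 2 — exploratory PCA.
#
# Fits a mean-centered PCA to all spectra, writes scores (with T2/Q outlier
# diagnostics) and loadings, and reports whether any sample exceeds the
# conventional 99% diagnostic limits. On the synthetic ecotypes the
# black-vs-common contrast shows up as a trend along one of the leading
# components, while the four individual classes overlap — the reason a
# supervised method is needed downstream.

library(sportsimca)

ds <- read_spectra_csv("results/spectra.csv")
ex <- explore_pca(ds, k = 10)

cat("explained variance (%):",
    paste(sprintf("%.1f", ex$explained[1:5]), collapse = ", "), "...\n")

# flag extreme samples (empirical 99th percentiles as working limits)
t2_lim <- stats::quantile(ex$scores$t2, 0.99)
q_lim <- stats::quantile(ex$scores$q, 0.99)
flags <- ex$scores$t2 > t2_lim & ex$scores$q > q_lim
cat(sum(flags), "samples exceed both diagnostic limits\n")

utils::write.csv(ex$scores, "results/pca_scores.csv", row.names = FALSE)
utils::write.csv(ex$loadings, "results/pca_loadings.csv", row.names = FALSE)

# black-vs-common separation along the leading components
grp <- ifelse(grepl("Black", ex$scores$label), "black", "common")
for (pc in c("PC1", "PC2")) {
  ms <- tapply(ex$scores[[pc]], grp, mean)
  cat(sprintf("%s group means: black %.3f, common %.3f\n",
              pc, ms["black"], ms["common"]))
}
cat("wrote results/pca_scores.csv and results/pca_loadings.csv\n")
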