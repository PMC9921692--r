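#!/usr/bin/env Rscript
# Stage 1 — generate the working dataset.
#
# Simulates the four celery-ecotype classes (Elne, Magnum, Torricella
# Black, Trevi Black), 80 leaf spectra each, on the 4 cm^-1 analysis grid
# (901 variables over 4000-400 cm^-1), and splits them Duplex-wise into a
# 220-spectrum calibration set and a 100-spectrum validation set
# (25 per class), exactly the partition shape the downstream classifiers
# expect. Everything is reproducible from the seed below.

library(sportsimca)

seed <- 2026L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

axis <- default_wavenumber_axis(by = 4)
ds <- simulate_dataset(default_profiles(), n_per_class = 80, axis = axis,
                       seed = seed)
print(ds)

write_spectra_csv(ds, file.path(out_dir, "spectra.csv"))

sp <- stratified_duplex(ds, n_test_per_class = 25)
cat(sprintf("Duplex split: %d calibration / %d validation spectra\n",
            length(sp$calibration_ids), length(sp$test_ids)))
utils::write.csv(
  data.frame(sample_id = ds$sample_ids, label = ds$labels,
             role = ifelse(ds$sample_ids %in% sp$test_ids,
                           "validation", "calibration")),
  file.path(out_dir, "split.csv"), row.names = FALSE)
cat("wrote results/spectra.csv and results/split.csv\n")
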