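#!/usr/bin/env Rscript
# Simulate the anti-PD-1 study cohort: 17 responder-like specimens (adaptive
# PD-L1, PD-1-rich infiltrate) and 8 non-responder-like specimens
# (constitutive PD-L1, sparse PD-1). Every specimen runs through the full
# spatial pipeline; per-specimen data and the derived metric table are
# written under results/.

suppressPackageStartupMessages(library(mcctme))
seed <- 42L
dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

run <- run_pipeline(list(seed = seed, n_r = 17, n_nr = 8,
                         outdir = "results/cohort"))
rec <- run$records

cat("Simulated", nrow(rec), "specimens (seed", seed, ")\n")
cat(sprintf("Median total PD-1+ density:  R %.1f vs NR %.1f cells/mm^2\n",
            median(rec$pd1_total[rec$responder]),
            median(rec$pd1_total[!rec$responder])))
cat(sprintf("Median total PD-L1+ density: R %.1f vs NR %.1f cells/mm^2\n",
            median(rec$pdl1_total[rec$responder]),
            median(rec$pdl1_total[!rec$responder])))
cat(sprintf("Median total CD8+ density:   R %.1f vs NR %.1f cells/mm^2\n",
            median(rec$cd8_total[rec$responder]),
            median(rec$cd8_total[!rec$responder])))
cat("Per-specimen cell tables, partitions and metrics: results/cohort/\n")
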