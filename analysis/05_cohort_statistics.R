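#!/usr/bin/env Rscript
# Cohort-level statistics on the metric table from 01_simulate_cohort.R:
# responder vs non-responder Mann-Whitney comparisons, quartile
# stratification of the key densities, and the density-adjusted proximity
# comparison. Run 01 first.

suppressPackageStartupMessages(library(mcctme))
metrics_path <- "results/cohort/specimen_metrics.csv"
if (!file.exists(metrics_path))
  stop("run analysis/01_simulate_cohort.R first")
rec <- utils::read.csv(metrics_path)

st <- cohort_stats(rec)
write_metrics(st$tests, "results/cohort_tests.csv")
cat("Responder vs non-responder comparisons (two-sided Mann-Whitney):\n")
print(st$tests[, c("metric", "median_r", "median_nr", "p_value")], digits = 3)

for (m in names(st$quartiles)) {
  cat("\nQuartiles of", m, "(responder fraction per quartile):\n")
  print(st$quartiles[[m]]$summary)
}
qdf <- do.call(rbind, lapply(names(st$quartiles), function(m)
  cbind(metric = m, st$quartiles[[m]]$summary)))
write_metrics(qdf, "results/cohort_quartiles.csv")

cat("\nDensity-adjusted proximity comparison:\n")
print(st$adjusted)

# figure-style summary (median +/- IQR per group) for plotting
fig <- do.call(rbind, lapply(unique(st$tests$metric), function(m) {
  do.call(rbind, lapply(c(TRUE, FALSE), function(g) {
    v <- rec[[m]][rec$responder == g & !is.na(rec[[m]])]
    data.frame(metric = m, group = if (g) "R" else "NR", n = length(v),
               median = median(v), iqr_lo = quantile(v, .25),
               iqr_hi = quantile(v, .75))
  }))
}))
write_metrics(fig, "results/cohort_group_summaries.csv")
cat("\nWrote results/cohort_tests.csv, cohort_quartiles.csv,",
    "cohort_group_summaries.csv\n")
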