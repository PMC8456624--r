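#!/usr/bin/env Rscript
# Doubling time, lag phase, and final OD for the two strains' curves,
# plus the percent slowdown of the mutant.

suppressPackageStartupMessages(library(ecscreen))

rows <- list()
for (strain in c("reference", "mutant")) {
  cur <- read_growth_curve(sprintf("results/scenario/curve_%s.csv", strain),
                           label = strain)
  fit <- fit_doubling_time(cur)
  rows[[strain]] <- data.frame(
    label = strain,
    doubling_time_min = fit$doubling_time,
    lag_min = lag_phase(cur),
    final_od = final_od(cur, 48 * 60),
    r2 = fit$r2)
}
metrics <- do.call(rbind, rows)
ecscreen:::write_tsv_plain(metrics, "results/growth_metrics.tsv")
print(metrics, row.names = FALSE)
cat(sprintf("glucose doubling time slowdown (mutant vs reference): %d%%\n",
            percent_change(metrics$doubling_time_min[1],
                           metrics$doubling_time_min[2], round_to_int = TRUE)))
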