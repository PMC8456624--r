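#!/usr/bin/env Rscript
# Generate the synthetic study inputs: calibrated toy enzyme-constrained
# model, planted DE tables, count matrix, growth curves, gene sets.

suppressPackageStartupMessages(library(ecscreen))

scenario <- synthetic_scenario(seed = 1)
paths <- write_scenario(scenario, "results/scenario")

model <- load_ecmodel(paths[["model"]])
cat("scenario written to results/scenario\n")
print(model)
eth <- fba(apply_flexible_constraint(
  set_bounds(model, model$carbon_exchange_ids[["glucose"]], upper = 0),
  flex_spec(model$biomass_id, 0.22, 0.05)),
  stats::setNames(1, model$biomass_id))
cat(sprintf("max growth on ethanol with growth window imposed: %.4f h^-1 (status %s)\n",
            eth$objective_value, eth$status))
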