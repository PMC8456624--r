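# ecscreen

Enzyme-constrained metabolic modeling with transcriptome-derived enzyme
bounds, random flux sampling, and an in-silico single-enzyme rescue
screen — plus the growth-curve and expression analyses that surround
such a study.

The package targets the question a systems biologist asks when a
mutant grows poorly on a non-fermentable carbon source while its
transcriptome shows weak induction of the relevant pathway genes:
*is the measured expression deficit sufficient to explain the growth
deficit, and which enzymes could single-handedly rescue it?*

## The model at the core

Flux balance analysis optimizes fluxes over
`{v : S v = 0, lb ≤ v ≤ ub}`. The enzyme-constrained (GECKO-style)
extension couples each catalyzed flux to enzyme usage and caps total
enzyme mass by a pool parameter *P*:

```
v_j ≤ kcat_ij · e_i          (enzyme pseudo-metabolite at 1/kcat per flux unit)
Σ_i MW_i · e_i ≤ P           (pool exchange, default P = 0.1 g/gDW)
```

The analysis pipeline then:

1. samples feasible reference flux distributions under growth fixed to
   0.22 h⁻¹ ± 5% on ethanol, by maximizing randomly weighted pairs of
   reaction fluxes (seeded, reproducible);
2. caps each differentially expressed enzyme's usage at
   `usage_in_sample · 2^log2FC · 1.20` (deleted genes: multiplier 0)
   and maximizes growth per sampled background;
3. fixes growth at its maximum ± 5% and maximizes net carbon
   consumption, then maintenance ATP (NGAM), lexicographically;
4. relaxes the perturbed enzymes one at a time back to their pool-only
   limit and calls an enzyme a **rescuer** if the mean maximum growth
   over feasible backgrounds returns to ≥ 0.209 h⁻¹;
5. tests rescuer genes for hypergeometric gene-set enrichment (BH
   adjusted).

Everything runs on a synthetic scenario the package generates itself: a
calibrated ~40-reaction toy model of yeast central carbon metabolism
(maximum growth on ethanol calibrated into [0.209, 0.231] h⁻¹), DE
tables with 111 planted poorly induced genes among 2000, negative-
binomial count matrices with planted read fractions (7.1% vs 3.56%),
and batch growth curves at doubling times 111 and 120 min.

## Worked example

```r
library(ecscreen)

scenario <- synthetic_scenario(seed = 1)
model    <- make_core_ecmodel(scenario)          # calibrated ec-model
de       <- simulate_de_tables(scenario)

pset <- build_perturbation_set(
  de$de_strain, setNames(model$enzymes$genes, model$enzymes$id),
  deleted_genes = scenario$deleted_genes, delta = 0.20)

samples <- sample_flux_distributions(model, sampling_config(n_samples = 200, seed = 1))
screen  <- perturbed_growth_screen(model, samples, pset)
rescue  <- single_enzyme_rescue(model, samples, pset, screen = screen)

mean(screen$mu_max[screen$feasible])
#> [1] 0.02607  # h^-1: the capped network grows ~8x below the 0.209 target
rescue[rescue$rescuer, ]
#>   enzyme mean_mu_max n_samples rescuer
#> 5  ACS1x      0.2141       200    TRUE
```

The perturbed network's mean maximum growth collapses to ~0.026 h⁻¹,
and relaxing only the acetyl-CoA synthetase analog (the planted
10-fold-down bottleneck at the entry of ethanol assimilation) restores
it into the growth window — the screen recovers the planted cause,
and no other enzyme qualifies.

Growth-curve metrics from the same scenario's curves:

```r
cur <- simulate_growth_curve(scenario, "reference")
fit_doubling_time(cur)$doubling_time   # 111.02 min
lag_phase(cur)                         # 146.7 min (OD 0.1 -> 0.25)
percent_change(111, 120, round_to_int = TRUE)  # 8 (% slowdown of the mutant)
```

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the whole
study on the synthetic scenario and write tables under `results/`:

```
analysis/01_simulate_data.R    # scenario inputs -> results/scenario/
analysis/02_growth_metrics.R   # doubling time, lag, final OD per strain
analysis/03_transcriptome.R    # CPM filter, poorly-induced classifier, read fractions
analysis/04_flux_sampling.R    # flux sampling + max-NGAM demonstration
analysis/05_rescue_screen.R    # perturbation -> screen -> rescue -> enrichment
```

Run them in order with `Rscript analysis/01_simulate_data.R` etc.; each
prints what it found and is reproducible from its fixed seed.

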