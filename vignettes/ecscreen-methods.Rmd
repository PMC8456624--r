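---
title: "Enzyme-constrained modeling of a diauxic growth defect: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme-constrained modeling of a diauxic growth defect: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecscreen)
```

# The scientific problem

A yeast strain whose expression program fails to switch on after the
diauxic shift grows poorly on ethanol. ecscreen implements the
computational side of asking *why*: it encodes an enzyme-constrained
metabolic model, caps the usage of differentially expressed enzymes in
proportion to their measured fold changes, asks how much growth the
capped network still supports across many plausible reference flux
states, and then relaxes the caps one enzyme at a time to find which
single enzymes could rescue growth. Around this core it provides the
supporting analyses such a study needs: growth-curve metrics (doubling
time, lag, final OD600), a classifier for genes that fail to be induced
on the glucose-to-ethanol transition, read-fraction accounting, CPM
filtering, and hypergeometric gene-set enrichment.

All stages run on synthetic inputs built by the package itself, so every
claim in the test suite is checked against planted ground truth.

# The enzyme-constrained model

A metabolic model is a stoichiometric matrix $S$ with flux bounds; flux
balance analysis (FBA) maximizes a linear objective over
$\{v : S v = 0,\ lb \le v \le ub\}$. The enzyme-constrained (GECKO-style)
extension makes each catalyzed flux pay for its enzyme: reaction $j$
using enzyme $i$ consumes a pseudo-metabolite $\mathrm{prot}_i$ at
$1/k_{cat,ij}$ per flux unit, a usage reaction supplies $\mathrm{prot}_i$
at rate $e_i$ (mmol gDW$^{-1}$), and a single pool exchange caps total
enzyme mass:

$$ v_j \le k_{cat,ij}\, e_i, \qquad \sum_i MW_i\, e_i \le P . $$

Units are chosen so the pool constraint is dimensionally consistent:
fluxes in mmol gDW$^{-1}$ h$^{-1}$, $k_{cat}$ in h$^{-1}$ (input files
may declare s$^{-1}$; the loader multiplies by 3600), molecular weights
in g mmol$^{-1}$ (numerically kDa), and the pool $P$ in g gDW$^{-1}$
with default 0.1, the conventional enzyme pool parameter.

Two conventions resolve ambiguities the formulation leaves open:

* **Complexes vs isozymes.** The enzyme list attached to one reaction is
  treated as a complex (every subunit is drawn at $1/k_{cat}$);
  isozymes are written as parallel reaction copies, one per enzyme.
* **Usage bounds.** Each usage reaction's upper bound is its pool-only
  limit $P/MW_i$ rather than infinity: no enzyme can exceed the whole
  pool, and finite bounds keep the linear programs well posed. This same
  limit is what "removing the constraint" restores in the rescue screen.

Reversible reactions are split into irreversible pairs before
augmentation, because enzyme demand must couple to non-negative flux.

# The linear-programming engine

All operations reduce to LPs over the flux polytope. The package solves
them with its own dense bounded-variable revised simplex (two phases,
Bland's rule), written for the model sizes this package targets (tens of
reactions). Bland's rule makes every solve deterministic — identical
inputs give identical vertices — which the sampling and pipeline layers
rely on for bitwise reproducibility. Optimal solutions are recomputed
from a fresh factorization each iteration, so no update drift
accumulates. Infeasibility is certified by phase 1, unboundedness by an
unlimited ratio test in phase 2. The test suite checks every optimum
against an exhaustive vertex-enumeration oracle on all small fixtures
(objective agreement to $10^{-9}$) and cross-checks random well-scaled
LPs against an independent simplex implementation.

Degenerate optima are genuinely degenerate: the solver returns *an*
optimal vertex, deterministically, and tests assert objective values and
feasibility invariants, never full flux vectors of degenerate problems.

Three higher-level operations are built on the solver:

* `apply_flexible_constraint()` fixes a flux to an observed value with
  relative slack $\pm\delta$ (bounds $[v(1-\delta),\ v(1+\delta)]$,
  clipped below at 0).
* `lexicographic_optimize()` solves an ordered objective list, fixing
  each achieved optimum with relative tolerance $10^{-6}$ before the
  next solve. The study phrase "maximize both ethanol consumption and
  maintenance" is implemented lexicographically (consumption first) by
  default because a weighted sum would need an arbitrary weight choice;
  the equal-weight sum is available via `objective_mode = "weighted"`.
* `max_ngam()` fixes exchange fluxes to observations and maximizes the
  non-growth-associated maintenance (NGAM) ATP hydrolysis flux.

Carbon *consumption* in the screen is scored net of re-secretion
(uptake minus its paired export reaction): with both an import and an
export exchange present, a gross-uptake objective would ride a futile
import/export cycle to the exchange bound and hide every enzymatic
limit.

# Flux sampling

Reference-strain flux states are sampled by fixing growth to
$0.22\ \mathrm{h^{-1}} \pm 5\%$ on ethanol as sole carbon source and
repeatedly maximizing $w_1 v_i + w_2 v_j$ for a uniformly drawn pair of
distinct reactions and independent $U(0,1)$ weights. Draw order is
fixed (pair, then weights) under one seeded generator, so a seed fully
determines the sample list. Unbounded draws are rejected and redrawn —
every retained sample is a true vertex of the constrained polytope —
and the redraw count is recorded. The candidate set defaults to all
reactions except the pool exchange. This scheme makes no claim of
uniform polytope coverage; it is a spread of extreme but feasible
states, which is what the downstream per-background screen needs.

# Perturbation, screen, and rescue

The strain-contrast DE table is translated into per-enzyme multipliers
$2^{\log_2 FC}$ (0 for deleted genes; the minimum across genes for
multi-gene enzymes, a conservative bottleneck assumption). For each
sampled background the perturbed model caps each enzyme's usage at
$e_i \le u_i \cdot m_i \cdot (1 + 0.20)$, where $u_i$ is the usage in
that background. Growth is maximized; infeasible backgrounds are
flagged and excluded from downstream means; for feasible ones growth is
fixed at its maximum $\pm 5\%$ and net carbon consumption and NGAM are
maximized lexicographically.

The rescue screen then, for every perturbed enzyme and every feasible
background, restores only that enzyme's cap to the pool-only limit and
re-maximizes growth. An enzyme is a **rescuer** when its mean maximum
growth rate over feasible backgrounds reaches
$0.22 \cdot (1 - 0.05) = 0.209\ \mathrm{h^{-1}}$.

Rescuer genes are tested for gene-set enrichment with the upper-tail
hypergeometric test and Benjamini–Hochberg adjustment; the "more than 5
genes" reporting rule is applied to the term's overlap with the query by
default (configurable to term size — the underlying phrase is ambiguous
between the two).

# Growth-curve metrics

Doubling time comes from a nonlinear fit $OD = A e^{\mu t}$ over an
automatically selected exponential window, $T_d = \ln 2 / \mu$.
Window selection: candidate points have OD between 0.15 and half the
curve maximum; within each contiguous candidate run the *longest*
sub-window whose log-linear $R^2$ is at least 0.995 is kept (slope
breaks length ties), and among runs — i.e., among competing growth
phases — the one with the highest fitted rate wins. Selecting the
longest gate-passing window, rather than the steepest sub-window, is
essential: the steepest-window rule chases noise and under 2%
multiplicative noise biases $T_d$ downward by about 10%, while the
longest-window rule recovers it within about 1.5%. The OD range, the
$R^2$ gate, and the minimum window length (5 points) are exposed as
arguments.

Lag phase is the time to first reach OD 0.25 from inoculation at
OD 0.1 (linear interpolation between samples) — about 1.32 doublings.
The "1.5 doublings" gloss sometimes attached to this measurement is
internally inconsistent with the 0.1→0.25 span ($\log_2 2.5 = 1.32$);
the OD-threshold definition is taken as operative since it is the
stated measurement. Final OD is linear interpolation at the requested
time, with nearest-endpoint fallback and a warning outside the recorded
range.

# The synthetic scenario

`synthetic_scenario()` fixes the study conditions; its defaults are the
study's stated values wherever one exists, and one-time realistic
choices elsewhere:

* **Toy model.** A lumped irreversible network of yeast central carbon
  metabolism: glucose and ethanol exchange, glycolysis, fermentation
  (split reversible alcohol dehydrogenase), the
  acetaldehyde→acetate→acetyl-CoA assimilation route, TCA +
  oxidative phosphorylation, glyoxylate-shunt anaplerosis, closed
  fatty-acid/carnitine and propionate branches, biomass, and an NGAM
  reaction with lower bound 0.7 mmol ATP gDW$^{-1}$ h$^{-1}$ (a
  conventional maintenance load). Gene/enzyme names are yeast-inspired
  analogs (ACS1x, ADH2x, CIT2x, …); the network claims no real
  stoichiometry or kcats. A deterministic calibration rescales all
  kcats until maximum growth on ethanol lies in $[0.209, 0.231]$
  h$^{-1}$ while glucose growth stays faster; the pool (0.1) then
  limits ethanol growth, so enzyme-usage caps bite.
* **Planted perturbation.** The acetyl-CoA synthetase analog — the sole
  ethanol-assimilation entry point — is down-regulated 10-fold
  (multiplier 0.1); other ethanol-pathway enzymes get mild multipliers
  ($\ge 0.85$, whose caps times 1.20 still admit each background's own
  solution), one decorative enzyme on a closed pathway is deleted
  (multiplier 0). By construction the bottleneck is the unique
  rescuer, giving the screen a known answer.
* **DE tables.** 2000 genes; 111 planted poorly induced (reference
  log2FC $\sim N(2.5, 0.5)$ truncated $> 1.2$, FDR $\sim U(10^{-6},
  0.005)$; mutant attenuation $\sim N(1.8, 0.3)$ truncated $> 1.05$);
  300 genes induced equally in both strains; background log2FC $\sim
  N(0, 0.3)$ with FDR $\ge 0.1$. These margins make exact recovery the
  correct expectation for the classifier's strict thresholds, so any
  misclassification is a real defect.
* **Counts.** Negative-binomial (dispersion 0.05) around group means
  composed so the planted set holds 7.1% of reads in reference-ethanol
  and 3.56% in mutant-ethanol samples (2% in the glucose phases, a
  pre-shift baseline choice); 2 strains × 2 phases × 3 replicates at
  ~$10^5$ reads — roughly 80-fold below real sequencing depth, because
  read *fractions*, not depth, drive every downstream statistic.
* **Curves.** OD600 every 10 min: optional dead time, exponential phase
  at the printed doubling times (reference 111 min, mutant 120 min),
  and a sharp saturation $OD = E/(1+(E/K)^q)^{1/q}$ with $q = 8$ at
  capacity $K = 10$. Batch cultures stop growing abruptly at substrate
  exhaustion, so the shoulder is deliberately much sharper than classic
  logistic growth; below $K/2$ the curve is exponential to within
  0.05%, which is what makes sub-minute doubling-time recovery
  possible at all.

Every generator is a pure function of (scenario, seed); one master seed
derives fixed per-stage sub-seeds, so any stage can be re-run
independently and the whole pipeline is bitwise reproducible.

## What the synthetic data does not emulate

The toy model has ~40 reactions, not a genome-scale network; real
kcat/MW values, isozyme multiplicity, and compartmentalization are
absent. Planted DE effects are cleanly separated from the background,
so classifier recovery is exact by design — passing says the decision
rule and thresholds are implemented correctly, not that real noisy
contrasts would separate as cleanly. Under the default mild
co-perturbations every sampled background stays feasible in the
perturbed screen (the manifest reports the count); at genome scale a
small fraction of backgrounds is typically lost. Count simulation
plants composition only, not differential dispersion or batch effects.

# Numerical choices

Solver feasibility tolerances are $10^{-9}$ (reduced costs) and
$10^{-7}$ relative (phase-1 residual); flux distributions are validated
to mass balance and bounds within $10^{-6}$ absolute. Lexicographic
stages are fixed with slack $10^{-6}\max(1, |z|)$. Canonical model JSON
sorts all keys and object arrays by id and renders floats with 12
significant digits, so save∘load is byte-identical to canonical
re-serialization. Calibration iterates multiplicative kcat rescaling at
most 40 times (it converges in a handful because maintenance is small
relative to growth demands) and fails loudly with diagnostics
otherwise. The CPM filter's "below threshold in three conditions" reads
as "in every sample of at least 3 condition groups" by default, with
the "at least 3 samples" reading behind `mode = "samples"`.

# Problem sizes used in tests and scripts

The shipped analyses sample 200 flux distributions (the pipeline
default remains 1000) and screen 12 perturbed enzymes over them; the
acceptance checks use 200 sampled backgrounds for the screen/rescue
analog, 20–30 random fixtures for the oracle comparisons, and 100
seeded trials for the monotonicity properties. These sizes were chosen
so the planted signal is unambiguous — the perturbed-screen mean sits
an order of magnitude below the rescue threshold — while the whole
suite stays interactive.

# Known limitations

* The sampler characterizes the polytope by optimal vertices only;
  interior flux states are never produced.
* Rescue means are conditional on the sampled backgrounds; with few
  samples the rescuer set can be sensitive to the seed (the shipped
  scenario is constructed so it is not).
* The simplex is dense and refactorizes every iteration; it is built
  for lumped models, not genome-scale ones (thousands of reactions
  would need a sparse LP code).
* The growth-curve fitter assumes a single monotone batch curve per
  file; diauxic two-phase curves are handled only insofar as the two
  exponential phases occupy disjoint OD windows.
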