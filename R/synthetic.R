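# Seeded generators for every input the pipeline consumes: a calibrated
# toy enzyme-constrained model of yeast central carbon metabolism, planted
# differential-expression tables, negative-binomial count matrices, and
# growth curves. Gene/enzyme names are yeast-inspired analogs (ACS1x,
# ADH2x, CIT2x, ...) — readable, but not claiming real S. cerevisiae
# stoichiometry or kcats.

#' Synthetic scenario definition
#'
#' One object holding every knob of the synthetic study: the toy model
#' calibration target, the planted differential-expression structure, the
#' count-matrix composition, and the growth-curve parameters. All
#' generators are pure functions of (scenario, seed).
#'
#' @param seed master integer seed; per-stage sub-seeds are derived from it.
#' @param pool_bound enzyme pool parameter P in g·gDW^-1 (default 0.1).
#' @param mu_target calibration target for maximum growth on ethanol
#'   (default 0.22 h^-1); the calibrated optimum must fall within
#'   `mu_target * (1 +/- mu_window)`.
#' @param mu_window half-width of the calibration window (default 0.05).
#' @param ngam_min lower bound of the maintenance reaction (default 0.7
#'   mmol ATP·gDW^-1·h^-1).
#' @param n_genes size of the simulated transcriptome (default 2000).
#' @param n_poorly_induced number of planted poorly induced genes (default
#'   111).
#' @param n_induced_extra genes induced equally in both strains (default
#'   300).
#' @param wt_fc_mean,wt_fc_sd,wt_fc_min induced-gene log2FC distribution in
#'   the reference strain: Normal(2.5, 0.5) truncated above `wt_fc_min`
#'   (1.2).
#' @param atten_mean,atten_sd,atten_min attenuation of the planted genes in
#'   the mutant: Normal(1.8, 0.3) truncated above `atten_min` (1.05).
#' @param enzyme_multipliers named numeric of planted usage multipliers for
#'   the strain contrast; the default plants a strong acetyl-CoA synthetase
#'   bottleneck (ACS1x at 0.1) with mild co-regulation elsewhere.
#' @param deleted_genes genes deleted in the mutant (multiplier 0).
#' @param library_size expected reads per count-matrix sample (default
#'   1e5; ~80x below real depth — read fractions, not depth, drive the
#'   downstream statistics).
#' @param dispersion negative-binomial dispersion (default 0.05).
#' @param n_reps replicates per condition group (default 3).
#' @param read_fractions named percentages of reads occupied by the planted
#'   poorly induced set per condition group.
#' @param td_reference,td_mutant glucose-phase doubling times in minutes
#'   (defaults 111 and 120).
#' @param curve_capacity,curve_od0,curve_dead_time,curve_noise_sd,curve_duration,curve_every
#'   growth-curve shape: carrying capacity (OD600), inoculation OD, lag
#'   dead time (min), multiplicative noise sd, duration and sampling
#'   interval (min).
#' @return a `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(
    seed = 1,
    pool_bound = 0.1, mu_target = 0.22, mu_window = 0.05, ngam_min = 0.7,
    n_genes = 2000, n_poorly_induced = 111, n_induced_extra = 300,
    wt_fc_mean = 2.5, wt_fc_sd = 0.5, wt_fc_min = 1.2,
    atten_mean = 1.8, atten_sd = 0.3, atten_min = 1.05,
    enzyme_multipliers = c(ACS1x = 0.1, ADH2x = 0.85, ALD3x = 0.9,
                           CIT2x = 0.9, YAT1x = 0.85, CIT3x = 0.9,
                           PDH1x = 0.95, CIT1x = 1.0, COX1x = 1.0,
                           HXK1x = 1.2, PDC6x = 0.9, POX1x = 0),
    deleted_genes = "POX1x",
    library_size = 1e5, dispersion = 0.05, n_reps = 3,
    read_fractions = c(ref_glucose = 2.0, ref_ethanol = 7.1,
                       mut_glucose = 2.0, mut_ethanol = 3.56),
    td_reference = 111, td_mutant = 120,
    curve_capacity = 10, curve_od0 = 0.1, curve_dead_time = 0,
    curve_noise_sd = 0, curve_duration = 2880, curve_every = 10) {
  structure(as.list(environment()), class = "synthetic_scenario")
}

core_network <- function(scenario) {
  mets <- data.frame(
    id = c("glc", "etoh", "acald", "ac", "accoa", "accoa_m", "pyr", "prec",
           "atp", "nadh", "o2", "co2", "fa", "prop"),
    name = c("glucose", "ethanol", "acetaldehyde", "acetate", "acetyl-CoA",
             "peroxisomal acetyl-CoA", "pyruvate", "biomass precursor",
             "ATP", "NADH", "oxygen", "CO2", "fatty acid", "propionate"),
    compartment = "c", stringsAsFactors = FALSE)
  enz <- data.frame(
    id = c("HXK1x", "PDC6x", "ADH1x", "ADH2x", "ALD3x", "ACS1x", "PDH1x",
           "CIT1x", "CIT2x", "PYC1x", "COX1x", "POX1x", "YAT1x", "CIT3x"),
    mw = c(54, 61, 37, 37, 54, 79, 110, 53, 51, 130, 95, 84, 77, 55),
    stringsAsFactors = FALSE)
  enz$genes <- as.list(enz$id)
  # base turnover numbers (h^-1); a deterministic calibration rescales all
  # of them so that maximum growth on ethanol lands in the target window
  kc <- c(HXK1x = 9e4, PDC6x = 8e4, ADH1x = 1.2e5, ADH2x = 6e4, ALD3x = 5e4,
          ACS1x = 3e4, PDH1x = 4e4, CIT1x = 5e4, CIT2x = 3e4, PYC1x = 4e4,
          COX1x = 1.5e5, POX1x = 2e4, YAT1x = 6e4, CIT3x = 2e4)
  e1 <- function(id) list(list(id = id, kcat = kc[[id]]))
  rxns <- list(
    reaction("EX_glc", c(glc = 1), 0, 10, "exchange"),
    reaction("EX_etoh_in", c(etoh = 1), 0, 10, "exchange"),
    reaction("EX_etoh_out", c(etoh = -1), 0, 1000, "exchange"),
    reaction("EX_ac_out", c(ac = -1), 0, 1000, "exchange"),
    reaction("EX_o2", c(o2 = 1), 0, 1000, "exchange"),
    reaction("EX_co2", c(co2 = -1), 0, 1000, "exchange"),
    reaction("EX_fa", c(fa = 1), 0, 0, "exchange"),
    reaction("EX_prop", c(prop = 1), 0, 0, "exchange"),
    reaction("GLYC", c(glc = -1, pyr = 2, atp = 2, nadh = 2), 0, 1000,
             "metabolic", e1("HXK1x")),
    reaction("PDC", c(pyr = -1, acald = 1, co2 = 1), 0, 1000,
             "metabolic", e1("PDC6x")),
    reaction("ADH_fwd", c(acald = -1, nadh = -1, etoh = 1), 0, 1000,
             "metabolic", e1("ADH1x")),
    reaction("ADH_rev", c(etoh = -1, acald = 1, nadh = 1), 0, 1000,
             "metabolic", e1("ADH2x")),
    reaction("ALD", c(acald = -1, ac = 1, nadh = 1), 0, 1000,
             "metabolic", e1("ALD3x")),
    reaction("ACS", c(ac = -1, atp = -2, accoa = 1), 0, 1000,
             "metabolic", e1("ACS1x")),
    reaction("PDH", c(pyr = -1, accoa = 1, nadh = 1, co2 = 1), 0, 1000,
             "metabolic", e1("PDH1x")),
    reaction("TCA", c(accoa = -1, co2 = 2, nadh = 4), 0, 1000,
             "metabolic", e1("CIT1x")),
    reaction("GLX", c(accoa = -2, prec = 1, nadh = 1), 0, 1000,
             "metabolic", e1("CIT2x")),
    reaction("PYC", c(pyr = -1, atp = -1, prec = 1), 0, 1000,
             "metabolic", e1("PYC1x")),
    reaction("OXPHOS", c(nadh = -1, o2 = -0.5, atp = 1.5), 0, 1000,
             "metabolic", e1("COX1x")),
    reaction("FAOX", c(fa = -1, accoa_m = 4, nadh = 6), 0, 1000,
             "metabolic", e1("POX1x")),
    reaction("CRNSHUTTLE", c(accoa_m = -1, accoa = 1), 0, 1000,
             "metabolic", e1("YAT1x")),
    reaction("PRPASSIM", c(prop = -1, atp = -1, accoa = 1), 0, 1000,
             "metabolic", e1("CIT3x")),
    reaction("BIOMASS", c(prec = -2, accoa = -2, atp = -30), 0, 10, "biomass"),
    reaction("NGAM", c(atp = -1), scenario$ngam_min, 1000, "ngam"))
  ec_model(mets, rxns, enzymes = enz, pool_bound = scenario$pool_bound,
           biomass_id = "BIOMASS", ngam_id = "NGAM",
           carbon_exchange_ids = c(glucose = "EX_glc", ethanol = "EX_etoh_in",
                                   fatty_acid = "EX_fa", propionate = "EX_prop"),
           validate = FALSE)
}

scale_kcats <- function(model, factor) {
  for (i in seq_along(model$reactions)) {
    ez <- model$reactions[[i]]$enzymes
    if (length(ez))
      model$reactions[[i]]$enzymes <-
        lapply(ez, function(e) { e$kcat <- e$kcat * factor; e })
  }
  model
}

#' Build the calibrated toy enzyme-constrained model
#'
#' Constructs a lumped irreversible model of yeast central carbon
#' metabolism — glucose and ethanol exchange, glycolysis, fermentation
#' (split reversible alcohol dehydrogenase), the acetaldehyde-acetate-
#' acetyl-CoA route, TCA cycle with oxidative phosphorylation, glyoxylate
#' shunt, closed fatty-acid/carnitine and propionate branches, maintenance
#' and biomass — augments it with GECKO-style enzyme constraints, and
#' deterministically rescales all kcats until the maximum growth rate on
#' ethanol as sole carbon source falls within
#' `mu_target * (1 +/- mu_window)` while glucose growth stays faster.
#'
#' @param scenario a [synthetic_scenario()].
#' @param max_iter calibration iteration cap (default 40).
#' @return a calibrated enzyme-constrained `ec_model`.
#' @export
make_core_ecmodel <- function(scenario = synthetic_scenario(), max_iter = 40) {
  plain <- core_network(scenario)
  lo <- scenario$mu_target * (1 - scenario$mu_window)
  hi <- scenario$mu_target * (1 + scenario$mu_window)
  factor <- 1
  mu <- NA_real_
  for (it in seq_len(max_iter)) {
    m <- to_enzyme_constrained(scale_kcats(plain, factor),
                               pool_bound = scenario$pool_bound)
    eth <- constrain_to_carbon_source(m, "ethanol", NULL, 0)
    sol <- fba(eth, stats::setNames(1, m$biomass_id), "max")
    if (sol$status != "optimal")
      stop("calibration failed: ethanol growth LP status ", sol$status,
           call. = FALSE)
    mu <- sol$objective_value
    if (mu >= lo && mu <= hi) {
      glc <- constrain_to_carbon_source(m, "glucose", NULL, 0)
      mu_glc <- fba(glc, stats::setNames(1, m$biomass_id), "max")$objective_value
      if (mu_glc <= mu)
        stop("calibration failed: glucose growth ", signif(mu_glc, 4),
             " does not exceed ethanol growth ", signif(mu, 4), call. = FALSE)
      return(m)
    }
    if (mu <= 0)
      stop("calibration failed: non-positive ethanol growth", call. = FALSE)
    factor <- factor * scenario$mu_target / mu
  }
  stop(sprintf("calibration did not converge in %d iterations (last mu %.4g, window [%.4g, %.4g])",
               max_iter, mu, lo, hi), call. = FALSE)
}

# truncated-normal draws by rejection (seeded by the caller)
rtnorm_min <- function(n, mean, sd, min) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > min])
  }
  out[seq_len(n)]
}

#' Simulate planted differential-expression tables
#'
#' Generates the two phase-contrast tables (ethanol vs glucose, one per
#' strain) with a planted poorly-induced structure, plus the strain
#' contrast (mutant vs reference in ethanol phase) over the model's enzyme
#' genes carrying the planted usage multipliers.
#'
#' In the reference table, planted induced genes get log2FC ~ Normal(2.5,
#' 0.5) truncated above 1.2 with FDR ~ U(1e-6, 0.005); background genes get
#' log2FC ~ Normal(0, 0.3) with FDR ~ U(0.1, 1). In the mutant table the
#' planted poorly induced genes are attenuated by Normal(1.8, 0.3)
#' truncated above 1.05; the other induced genes are induced equally (up to
#' Normal(0, 0.1) jitter).
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `de_wt`, `de_mut`, `de_strain` (DE tables) and
#'   `truth` (planted sets and multipliers).
#' @export
simulate_de_tables <- function(scenario = synthetic_scenario()) {
  set.seed(stage_seed(scenario$seed, "de"))
  genes <- sprintf("gene%04d", seq_len(scenario$n_genes))
  poor <- sort(sample(genes, scenario$n_poorly_induced))
  induced <- sort(sample(setdiff(genes, poor), scenario$n_induced_extra))
  up <- c(poor, induced)
  wt_fc <- stats::setNames(rep(0, scenario$n_genes), genes)
  wt_fdr <- stats::setNames(stats::runif(scenario$n_genes, 0.1, 1), genes)
  wt_fc[up] <- rtnorm_min(length(up), scenario$wt_fc_mean, scenario$wt_fc_sd,
                          scenario$wt_fc_min)
  bg <- setdiff(genes, up)
  wt_fc[bg] <- stats::rnorm(length(bg), 0, 0.3)
  wt_fdr[up] <- stats::runif(length(up), 1e-6, 0.005)
  mut_fc <- stats::setNames(stats::rnorm(scenario$n_genes, 0, 0.3), genes)
  mut_fdr <- stats::setNames(stats::runif(scenario$n_genes, 0.1, 1), genes)
  mut_fc[induced] <- wt_fc[induced] - stats::rnorm(length(induced), 0, 0.1)
  mut_fc[poor] <- wt_fc[poor] - rtnorm_min(length(poor), scenario$atten_mean,
                                           scenario$atten_sd, scenario$atten_min)
  mut_fdr[up] <- stats::runif(length(up), 1e-6, 0.01)
  de_wt <- data.frame(gene = genes, log2FC = unname(wt_fc),
                      FDR = unname(wt_fdr), stringsAsFactors = FALSE)
  de_mut <- data.frame(gene = genes, log2FC = unname(mut_fc),
                       FDR = unname(mut_fdr), stringsAsFactors = FALSE)
  attr(de_wt, "contrast") <- "reference: ethanol vs glucose"
  attr(de_mut, "contrast") <- "mutant: ethanol vs glucose"
  mult <- scenario$enzyme_multipliers
  tab <- mult[setdiff(names(mult), scenario$deleted_genes)]
  de_strain <- data.frame(gene = names(tab), log2FC = log2(unname(tab)),
                          FDR = stats::runif(length(tab), 1e-4, 0.04),
                          stringsAsFactors = FALSE)
  attr(de_strain, "contrast") <- "mutant vs reference, ethanol phase"
  list(de_wt = de_wt, de_mut = de_mut, de_strain = de_strain,
       truth = list(poorly_induced = poor, induced = induced,
                    enzyme_multipliers = mult,
                    deleted_genes = scenario$deleted_genes))
}

#' Simulate a negative-binomial count matrix with planted read fractions
#'
#' Per-group mean compositions are chosen so the designated gene set's
#' expected share of reads equals the scenario's `read_fractions`; counts
#' are negative-binomial around those means. Relative abundances within
#' and outside the set are log-normal and shared across groups.
#'
#' @param scenario a [synthetic_scenario()].
#' @param designated gene set carrying the planted fractions (default: the
#'   scenario's planted poorly induced genes).
#' @return list with `cm` (a [count_matrix()]) and `truth` (designated set
#'   and planted fractions).
#' @export
simulate_counts <- function(scenario = synthetic_scenario(), designated = NULL) {
  if (any(scenario$read_fractions > 100))
    stop("requested read fraction exceeds 100%", call. = FALSE)
  if (is.null(designated))
    designated <- simulate_de_tables(scenario)$truth$poorly_induced
  set.seed(stage_seed(scenario$seed, "counts"))
  genes <- sprintf("gene%04d", seq_len(scenario$n_genes))
  inset <- genes %in% designated
  w_in <- exp(stats::rnorm(sum(inset), 0, 1))
  w_out <- exp(stats::rnorm(sum(!inset), 0, 1))
  groups <- names(scenario$read_fractions)
  samples <- as.vector(t(outer(groups, seq_len(scenario$n_reps),
                               function(g, r) paste0(g, "_", r))))
  counts <- matrix(0L, scenario$n_genes, length(samples),
                   dimnames = list(genes, samples))
  size <- 1 / scenario$dispersion
  for (g in groups) {
    f <- scenario$read_fractions[[g]] / 100
    mu <- numeric(scenario$n_genes)
    if (sum(inset)) mu[inset] <- scenario$library_size * f * w_in / sum(w_in)
    mu[!inset] <- scenario$library_size * (1 - f) * w_out / sum(w_out)
    for (r in seq_len(scenario$n_reps)) {
      smp <- paste0(g, "_", r)
      counts[, smp] <- stats::rnbinom(scenario$n_genes, mu = mu, size = size)
    }
  }
  grp <- stats::setNames(rep(groups, each = scenario$n_reps), samples)
  list(cm = count_matrix(counts, grp),
       truth = list(designated = sort(designated),
                    fractions = scenario$read_fractions))
}

#' Simulate a batch growth curve
#'
#' OD600 follows the inoculum through an optional dead time, an exponential
#' phase with the requested doubling time, and a sharp saturation at the
#' carrying capacity: `OD = E / (1 + (E/K)^q)^(1/q)` with
#' `E = od0 * 2^((t - dead)/Td)` and shoulder exponent q = 8. Batch
#' cultures stop growing abruptly at substrate exhaustion, so the shoulder
#' is deliberately much sharper than classic logistic growth; below half
#' the capacity the curve is exponential to within 0.05%. Optional
#' multiplicative log-normal noise is seeded.
#'
#' @param scenario a [synthetic_scenario()].
#' @param strain `"reference"` (Td = `td_reference`) or `"mutant"`
#'   (`td_mutant`).
#' @param td doubling time in minutes (overrides the strain default).
#' @param capacity,od0,dead_time,noise_sd,duration,sample_every curve
#'   knobs, defaulting to the scenario's.
#' @param seed seed for the noise stream (default derived from the
#'   scenario seed and strain).
#' @return a [growth_curve()].
#' @export
simulate_growth_curve <- function(scenario = synthetic_scenario(),
                                  strain = c("reference", "mutant"),
                                  td = NULL, capacity = scenario$curve_capacity,
                                  od0 = scenario$curve_od0,
                                  dead_time = scenario$curve_dead_time,
                                  noise_sd = scenario$curve_noise_sd,
                                  duration = scenario$curve_duration,
                                  sample_every = scenario$curve_every,
                                  seed = NULL) {
  strain <- match.arg(strain)
  if (is.null(td))
    td <- if (strain == "reference") scenario$td_reference else scenario$td_mutant
  stopifnot(td > 0, capacity >= od0)
  t <- seq(0, duration, by = sample_every)
  expo <- od0 * 2^(pmax(0, t - dead_time) / td)
  q <- 8
  od <- expo / (1 + (expo / capacity)^q)^(1 / q)
  if (noise_sd > 0) {
    set.seed(seed %||% (stage_seed(scenario$seed, "curves") +
                          (strain == "mutant")))
    od <- od * exp(stats::rnorm(length(od), 0, noise_sd))
  }
  growth_curve(t, od, label = strain)
}

#' Write a complete synthetic scenario directory
#'
#' Materializes every pipeline input as plain text: the calibrated model
#' JSON, the three DE tables, the count matrix with its group map, one
#' growth curve per strain, gene sets over the model's enzyme genes (GMT),
#' and the planted truth as JSON.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_scenario <- function(scenario = synthetic_scenario(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  model <- make_core_ecmodel(scenario)
  save_ecmodel(model, p("model.json"))
  de <- simulate_de_tables(scenario)
  write_de_table(de$de_wt, p("de_wt.tsv"))
  write_de_table(de$de_mut, p("de_mut.tsv"))
  write_de_table(de$de_strain, p("de_strain.tsv"))
  cts <- simulate_counts(scenario, designated = de$truth$poorly_induced)
  cm <- cts$cm
  write_tsv_plain(data.frame(gene = rownames(cm$counts),
                             as.data.frame(cm$counts), check.names = FALSE),
                  p("counts.tsv"))
  write_tsv_plain(data.frame(sample = names(cm$groups),
                             group = unname(cm$groups)), p("groups.tsv"))
  write_growth_curve(simulate_growth_curve(scenario, "reference"),
                     p("curve_reference.csv"))
  write_growth_curve(simulate_growth_curve(scenario, "mutant"),
                     p("curve_mutant.csv"))
  sets <- list(
    ethanol_utilization = c("ADH2x", "ALD3x", "ACS1x", "PDC6x"),
    tca_and_respiration = c("PDH1x", "CIT1x", "COX1x"),
    anaplerosis_glyoxylate = c("CIT2x", "PYC1x"),
    fatty_acid_carnitine = c("POX1x", "YAT1x"),
    propionate_metabolism = c("CIT3x"),
    glycolysis_fermentation = c("HXK1x", "PDC6x", "ADH1x"))
  write_gmt(sets, p("gene_sets.gmt"))
  truth <- de$truth
  truth$enzyme_multipliers <- as.list(truth$enzyme_multipliers)
  truth$read_fractions <- as.list(scenario$read_fractions)
  truth$td <- list(reference = scenario$td_reference,
                   mutant = scenario$td_mutant)
  writeLines(to_json_canonical(truth), p("truth.json"))
  invisible(stats::setNames(
    p(c("model.json", "de_wt.tsv", "de_mut.tsv", "de_strain.tsv",
        "counts.tsv", "groups.tsv", "curve_reference.csv",
        "curve_mutant.csv", "gene_sets.gmt", "truth.json")),
    c("model", "de_wt", "de_mut", "de_strain", "counts", "groups",
      "curve_reference", "curve_mutant", "gene_sets", "truth")))
}
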