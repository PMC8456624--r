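test_that("the calibrated toy model hits the ethanol growth window", {
  m <- calibrated_model()
  eth <- ecscreen:::constrain_to_carbon_source(m, "ethanol", NULL, 0)
  mu_eth <- fba(eth, stats::setNames(1, m$biomass_id))$objective_value
  expect_gte(mu_eth, 0.22 * 0.95)
  expect_lte(mu_eth, 0.22 * 1.05)
  glc <- ecscreen:::constrain_to_carbon_source(m, "glucose", NULL, 0)
  mu_glc <- fba(glc, stats::setNames(1, m$biomass_id))$objective_value
  expect_gt(mu_glc, mu_eth)

  # ethanol assimilation strictly requires the acetyl-CoA synthetase analog
  ko <- set_bounds(eth, "usage_ACS1x", upper = 0)
  expect_lt(abs(fba(ko, stats::setNames(1, m$biomass_id))$objective_value), 1e-9)
  ko_glc <- set_bounds(glc, "usage_ACS1x", upper = 0)
  expect_equal(fba(ko_glc, stats::setNames(1, m$biomass_id))$objective_value,
               mu_glc, tolerance = 1e-6)

  # no carbon source: the mandatory maintenance load cannot be met, and
  # with maintenance relaxed growth is exactly zero
  none <- set_bounds(eth, m$carbon_exchange_ids[["ethanol"]], upper = 0)
  expect_identical(fba(none, stats::setNames(1, m$biomass_id))$status,
                   "infeasible")
  none0 <- set_bounds(none, m$ngam_id, lower = 0)
  expect_lt(abs(fba(none0, stats::setNames(1, m$biomass_id))$objective_value),
            1e-9)
})

test_that("planted DE tables are deterministic and recoverable", {
  sc <- scenario_fixture(seed = 8)
  d1 <- simulate_de_tables(sc)
  d2 <- simulate_de_tables(sc)
  expect_identical(d1, d2)
  expect_false(identical(d1$de_wt, simulate_de_tables(scenario_fixture(seed = 9))$de_wt))

  got <- classify_poorly_induced(d1$de_wt, d1$de_mut)
  expect_identical(got, d1$truth$poorly_induced)
  expect_length(got, 111)

  none <- simulate_de_tables(scenario_fixture(seed = 8, n_poorly_induced = 0))
  expect_identical(classify_poorly_induced(none$de_wt, none$de_mut),
                   character())

  # strain contrast carries the planted multipliers
  ps <- build_perturbation_set(
    d1$de_strain,
    stats::setNames(as.list(d1$de_strain$gene), d1$de_strain$gene))
  expect_equal(ps$multipliers[["ACS1x"]], 0.1, tolerance = 1e-12)
})

test_that("count matrices carry the planted read fractions", {
  sc <- scenario_fixture(seed = 5)
  cts <- simulate_counts(sc)
  for (g in names(sc$read_fractions)) {
    got <- read_fraction(cts$cm, cts$truth$designated, g)
    expect_lt(abs(got - sc$read_fractions[[g]]), 0.3)
  }
  expect_identical(simulate_counts(sc)$cm$counts, cts$cm$counts)

  # fractions over a partition of all genes sum to 100
  genes <- rownames(cts$cm$counts)
  thirds <- split(genes, rep(1:3, length.out = length(genes)))
  tot <- sum(vapply(thirds, function(s)
    read_fraction(cts$cm, s, "ref_ethanol"), numeric(1)))
  expect_equal(tot, 100, tolerance = 1e-9)

  expect_error(simulate_counts(scenario_fixture(
    seed = 5, read_fractions = c(ref_ethanol = 120))), "100")
})

test_that("synthetic growth curves reproduce their generative parameters", {
  sc <- scenario_fixture(seed = 2)
  ref <- simulate_growth_curve(sc, "reference")
  expect_equal(fit_doubling_time(ref)$doubling_time, 111, tolerance = 0.5)
  mut <- simulate_growth_curve(sc, "mutant")
  expect_equal(fit_doubling_time(mut)$doubling_time, 120, tolerance = 0.5)
  expect_equal(lag_phase(ref), log2(2.5) * 111, tolerance = 0.01 * 111)

  # dead time shifts the lag additively
  lagged <- simulate_growth_curve(sc, "reference", dead_time = 60)
  expect_equal(lag_phase(lagged), 60 + log2(2.5) * 111, tolerance = 2)

  flat <- simulate_growth_curve(sc, "reference", capacity = 0.1)
  expect_error(fit_doubling_time(flat), "no exponential phase")

  n1 <- simulate_growth_curve(sc, "reference", noise_sd = 0.02)
  n2 <- simulate_growth_curve(sc, "reference", noise_sd = 0.02)
  expect_identical(n1$od, n2$od)
})

test_that("scenario directories contain consistent, reloadable inputs", {
  sc <- scenario_fixture(seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_scenario(sc, dir)
  expect_true(all(file.exists(paths)))
  m <- load_ecmodel(paths[["model"]])
  expect_equal(m$pool_bound, 0.1)
  de_wt <- read_de_table(paths[["de_wt"]])
  truth <- jsonlite::fromJSON(paths[["truth"]])
  expect_identical(
    classify_poorly_induced(de_wt, read_de_table(paths[["de_mut"]])),
    sort(truth$poorly_induced))
  cm <- read_count_matrix(paths[["counts"]], paths[["groups"]])
  expect_lt(abs(read_fraction(cm, truth$poorly_induced, "ref_ethanol") - 7.1),
            0.3)
  sets <- read_gmt(paths[["gene_sets"]])
  expect_true(all(unlist(sets) %in% m$enzymes$id))
  cur <- read_growth_curve(paths[["curve_reference"]])
  expect_equal(fit_doubling_time(cur)$doubling_time, 111, tolerance = 0.5)
})
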