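de_row <- function(gene, fc, fdr = 0.001)
  data.frame(gene = gene, log2FC = fc, FDR = fdr, stringsAsFactors = FALSE)

test_that("poorly induced classification follows its definition and bounds", {
  wt <- rbind(de_row("g1", 2.0, 0.001),   # induced, strongly attenuated
              de_row("g2", 1.0, 0.001),   # exactly at threshold: excluded
              de_row("g3", 2.0, 0.02),    # FDR too high
              de_row("g4", 2.0, 0.001),   # attenuated exactly by the gap
              de_row("g5", 2.0, 0.001))   # equally induced in the mutant
  mut <- rbind(de_row("g1", 0.5), de_row("g2", -1), de_row("g3", 0),
               de_row("g4", 1.0), de_row("g5", 1.9))
  got <- classify_poorly_induced(wt, mut)
  expect_identical(got, c("g1", "g4"))

  # genes absent from the mutant table count as not induced
  expect_warning(
    got2 <- classify_poorly_induced(rbind(de_row("g1", 2.0, 0.001)),
                                    rbind(de_row("zz", 0, 0.5))),
    "absent")
  expect_identical(got2, "g1")

  expect_warning(empty <- classify_poorly_induced(wt[0, ], mut), "empty")
  expect_identical(empty, character())

  # monotone in the gap: larger gap can only shrink the set
  for (g in c(0.5, 1, 1.5, 2.5)) {
    bigger <- classify_poorly_induced(wt, mut, gap = g)
    smaller <- classify_poorly_induced(wt, mut, gap = g + 0.5)
    expect_true(all(smaller %in% bigger))
  }
})

test_that("CPM filtering matches hand-computed values in both modes", {
  counts <- rbind(
    allzero = c(0, 0, 0, 0, 0, 0, 0, 0),
    high    = c(50, 60, 50, 60, 50, 60, 50, 60),
    gx      = c(0, 0, 0, 0, 90, 80, 70, 60),
    border  = c(1, 1, 1, 1, 1, 1, 1, 1),
    dub     = c(30, 30, 30, 30, 30, 30, 30, 30),
    filler  = c(919, 909, 919, 909, 829, 829, 849, 849))
  colnames(counts) <- paste0("s", 1:8)
  groups <- stats::setNames(rep(c("g1", "g2", "g3", "g4"), each = 2),
                            colnames(counts))
  cm <- count_matrix(counts, groups)
  # library sizes are 1000 per sample, so CPM = count * 1000:
  # allzero: 0 everywhere -> below 1 CPM in all 4 groups -> dropped
  # gx: zero in groups g1, g2 only (2 groups < 3) -> kept
  # border: CPM 1000 -> kept ; dub: dropped by the dubious list
  expect_equal(colSums(counts), rep(1000, 8), ignore_attr = TRUE)
  kept <- cpm_filter(cm, dubious_orfs = "dub")
  expect_identical(kept, sort(c("high", "gx", "border", "filler")))
  # sample mode: allzero low in 8 samples, gx low in 4 samples -> both out
  kept2 <- cpm_filter(cm, group_threshold = 3, mode = "samples",
                      dubious_orfs = "dub")
  expect_identical(kept2, sort(c("high", "border", "filler")))
  expect_error(count_matrix(counts, groups[-1]), "without a group")
})

test_that("read fractions are conserved and match hand arithmetic", {
  counts <- rbind(a = c(10, 10), b = c(490, 490), c = c(500, 500))
  colnames(counts) <- c("s1", "s2")
  cm <- count_matrix(counts, c(s1 = "grp", s2 = "grp"))
  expect_equal(read_fraction(cm, "a", "grp"), 1.0)
  expect_equal(read_fraction(cm, c("a", "b", "c"), "grp"), 100)
  parts <- read_fraction(cm, "a", "grp") + read_fraction(cm, "b", "grp") +
    read_fraction(cm, "c", "grp")
  expect_equal(parts, 100, tolerance = 1e-9)
  expect_warning(f <- read_fraction(cm, c("a", "nope"), "grp"), "absent")
  expect_equal(f, 1.0)
  expect_error(read_fraction(cm, "a", "zzz"), "unknown sample group")
})

test_that("perturbation sets translate fold changes into multipliers", {
  de <- rbind(de_row("gA", -1), de_row("gB", 2), de_row("gC", -0.5))
  map <- list(E1 = "gA", E2 = "gB", E3 = c("gB", "gC"), E4 = "gDel",
              E5 = "gMissing")
  ps <- build_perturbation_set(de, map, deleted_genes = "gDel", delta = 0.2)
  expect_equal(ps$multipliers[["E1"]], 0.5)
  expect_equal(ps$multipliers[["E2"]], 4)
  # multi-gene enzymes take the minimum multiplier
  expect_equal(ps$multipliers[["E3"]], 2^-0.5)
  expect_equal(ps$multipliers[["E4"]], 0)
  expect_true(ps$table$deleted[ps$table$enzyme == "E4"])
  expect_identical(ps$unmapped, "E5")
})

test_that("the perturbed growth screen responds to planted bottlenecks", {
  m <- calibrated_model()
  samples <- sample_flux_distributions(m, sampling_config(n_samples = 12,
                                                          seed = 3))
  enzymes <- m$enzymes$id
  neutral <- toy_pset(stats::setNames(rep(1, length(enzymes)), enzymes))
  scr <- perturbed_growth_screen(m, samples, neutral)
  expect_true(all(scr$feasible))
  for (i in seq_along(samples))
    expect_gte(scr$mu_max[i], samples[[i]]$values[[m$biomass_id]] - 1e-6)

  # zeroing the sole ethanol-assimilation enzyme kills ethanol growth
  acs0 <- toy_pset(c(ACS1x = 0))
  scr0 <- perturbed_growth_screen(m, samples, acs0)
  expect_true(all(abs(scr0$mu_max[scr0$feasible]) < 1e-6))

  # planted down-regulation of the ethanol pathway (10x on the
  # acetyl-CoA synthetase bottleneck, mild on alcohol dehydrogenase)
  # lowers both growth and ethanol uptake
  acs01 <- toy_pset(c(ACS1x = 0.1, ADH2x = 0.85))
  scr01 <- perturbed_growth_screen(m, samples, acs01)
  expect_lt(mean(scr01$mu_max), mean(scr$mu_max))
  expect_lt(mean(scr01$carbon_uptake), mean(scr$carbon_uptake))

  # weighted-objective variant reports the same growth maxima
  scrw <- perturbed_growth_screen(m, samples, acs01,
                                  objective_mode = "weighted")
  expect_equal(scrw$mu_max, scr01$mu_max, tolerance = 1e-9)

  # growth maxima are non-increasing in any single multiplier
  for (mult in c(0.05, 0.2, 0.6)) {
    lower <- perturbed_growth_screen(m, samples, toy_pset(c(ACS1x = mult)))
    expect_true(all(lower$mu_max <= scr$mu_max + 1e-6))
  }
})
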