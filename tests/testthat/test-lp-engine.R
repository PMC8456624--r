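test_that("fba solves box/chain toys and reports statuses", {
  m <- chain_model(ub_mid = 7)
  expect_equal(fba(m, c(EX_B = 1))$objective_value, 7, tolerance = 1e-9)
  m0 <- set_bounds(m, "EX_B", upper = 0)
  expect_equal(fba(m0, c(EX_B = 1))$objective_value, 0, tolerance = 1e-12)

  cyc <- ec_model(mets_df("A"),
                  list(reaction("in", c(A = 1), 0, Inf),
                       reaction("out", c(A = -1), 0, Inf)))
  expect_equal(fba(cyc, c(out = 1))$status, "unbounded")
  inf <- set_bounds(set_bounds(cyc, "in", lower = 5, upper = 5),
                    "out", upper = 3)
  expect_equal(fba(inf, c(out = 1))$status, "infeasible")
})

test_that("fba agrees with exhaustive vertex enumeration", {
  fixtures <- c(list(chain_model(), tradeoff_model()),
                lapply(1:6, random_toy_model))
  set.seed(99)
  for (m in fixtures) {
    lp <- model_lp_parts(m)
    for (rep in 1:3) {
      w <- stats::runif(length(lp$rxn_ids), -1, 1)
      oracle <- vertex_enum_optimum(lp$S, lp$lb, lp$ub, w)$value
      got <- fba(m, stats::setNames(w, lp$rxn_ids))
      expect_equal(got$objective_value, oracle, tolerance = 1e-9)
      chk <- check_distribution(m, got)
      expect_true(chk$ok)
    }
  }
})

test_that("flexibilized constraints follow the +/-delta arithmetic", {
  m <- chain_model()
  m1 <- apply_flexible_constraint(m, flex_spec("AtoB", 0.22, 0.05))
  expect_equal(m1$reactions[["AtoB"]]$lower_bound, 0.209)
  expect_equal(m1$reactions[["AtoB"]]$upper_bound, 0.231)
  m2 <- apply_flexible_constraint(m, flex_spec("AtoB", 1.0, 0.20))
  expect_equal(m2$reactions[["AtoB"]]$lower_bound, 0.8)
  expect_equal(m2$reactions[["AtoB"]]$upper_bound, 1.2)
  m3 <- apply_flexible_constraint(m, flex_spec("AtoB", 3, 0))
  expect_equal(m3$reactions[["AtoB"]]$lower_bound, 3)
  expect_equal(m3$reactions[["AtoB"]]$upper_bound, 3)
})

test_that("lexicographic optimization matches sequential brute force", {
  m <- tradeoff_model()
  lp <- model_lp_parts(m)

  single <- lexicographic_optimize(m, list(list(objective = c(v1 = 1))))
  expect_equal(single$objective_value, fba(m, c(v1 = 1))$objective_value,
               tolerance = 1e-9)

  o1 <- ecscreen:::expand_objective(c(v1 = 1), lp$rxn_ids)
  o2 <- ecscreen:::expand_objective(c(v2 = 1), lp$rxn_ids)
  oracle12 <- vertex_enum_lexicographic(lp$S, lp$lb, lp$ub,
                                        list(list(obj = o1), list(obj = o2)))
  got12 <- lexicographic_optimize(m, list(list(objective = c(v1 = 1)),
                                          list(objective = c(v2 = 1))))
  expect_equal(got12$stage_optima, oracle12$optima, tolerance = 1e-4)

  # order swap changes the outcome as the sequential oracle predicts
  oracle21 <- vertex_enum_lexicographic(lp$S, lp$lb, lp$ub,
                                        list(list(obj = o2), list(obj = o1)))
  got21 <- lexicographic_optimize(m, list(list(objective = c(v2 = 1)),
                                          list(objective = c(v1 = 1))))
  expect_equal(got21$stage_optima, oracle21$optima, tolerance = 1e-4)

  # colinear second objective changes nothing
  gotcol <- lexicographic_optimize(m, list(list(objective = c(v1 = 1)),
                                           list(objective = c(v1 = 2))))
  expect_equal(gotcol$stage_optima[2], 2 * gotcol$stage_optima[1],
               tolerance = 1e-4)

  # infeasible stage is reported with its index
  mi <- set_bounds(m, "EX_A", lower = 20, upper = 20)
  bad <- lexicographic_optimize(mi, list(list(objective = c(v1 = 1))))
  expect_equal(bad$status, "infeasible")
  expect_equal(bad$failed_stage, 1)
})

test_that("max NGAM reproduces hand stoichiometry and edge cases", {
  m <- ec_model(mets_df(c("glc", "atp")),
                list(reaction("EX_glc", c(glc = 1), 0, 1000, "exchange"),
                     reaction("CAT", c(glc = -1, atp = 2), 0, 1000),
                     reaction("BIO", c(atp = -5), 0, 1000, "biomass"),
                     reaction("NGAM", c(atp = -1), 0, 1000, "ngam")),
                biomass_id = "BIO", ngam_id = "NGAM")
  expect_equal(max_ngam(m, list(flex_spec("EX_glc", 10, 0),
                                flex_spec("BIO", 0, 0))), 20, tolerance = 1e-9)
  # biomass fixed at its own maximum leaves nothing for maintenance
  mu_max <- fba(set_bounds(m, "EX_glc", lower = 10, upper = 10),
                c(BIO = 1))$objective_value
  expect_equal(max_ngam(m, list(flex_spec("EX_glc", 10, 0),
                                flex_spec("BIO", mu_max, 0))), 0,
               tolerance = 1e-6)
  expect_equal(max_ngam(m, list(flex_spec("EX_glc", 0, 0))), 0,
               tolerance = 1e-12)
  expect_error(max_ngam(m, list(flex_spec("EX_glc", 0, 0),
                                flex_spec("BIO", 5, 0))),
               "BIO.*infeasible")
})

test_that("tightening a bound never improves a maximization", {
  set.seed(7)
  for (trial in 1:20) {
    m <- random_toy_model(trial)
    lp <- model_lp_parts(m)
    obj <- stats::setNames(stats::runif(length(lp$rxn_ids)), lp$rxn_ids)
    base <- fba(m, obj)$objective_value
    pick <- sample(names(m$reactions), 1)
    mt <- set_bounds(m, pick,
                     upper = m$reactions[[pick]]$upper_bound * stats::runif(1))
    tightened <- fba(mt, obj)
    if (tightened$status == "optimal")
      expect_lte(tightened$objective_value, base + 1e-9)
  }
})

test_that("the simplex agrees with boot::simplex on well-scaled LPs", {
  skip_if_not_installed("boot")
  set.seed(31)
  for (trial in 1:10) {
    n <- 5
    A <- matrix(sample(-2:2, 2 * n, replace = TRUE), 2, n)
    ub <- round(stats::runif(n, 1, 5), 1)
    obj <- round(stats::runif(n), 2)
    ours <- ecscreen:::simplex_bounded(obj, A, rep(0, 2), rep(0, n), ub, "max")
    ref <- tryCatch(
      boot::simplex(a = obj, A1 = diag(n), b1 = ub,
                    A3 = A, b3 = rep(0, 2), maxi = TRUE, n.iter = 500),
      error = function(e) NULL)
    if (!is.null(ref) && ref$solved == 1)
      expect_equal(ours$value, ref$value, tolerance = 1e-7,
                   ignore_attr = TRUE)
  }
})
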