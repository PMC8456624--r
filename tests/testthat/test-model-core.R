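test_that("model JSON serialization round-trips losslessly and canonically", {
  m <- make_core_ecmodel(synthetic_scenario(seed = 3))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_ecmodel(m, f1)
  m2 <- load_ecmodel(f1)
  save_ecmodel(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # field-by-field equality
  expect_equal(m2$pool_bound, m$pool_bound)
  expect_setequal(names(m2$reactions), names(m$reactions))
  for (id in names(m$reactions)) {
    expect_equal(sort(names(m2$reactions[[id]]$stoichiometry)),
                 sort(names(m$reactions[[id]]$stoichiometry)))
    expect_equal(m2$reactions[[id]]$upper_bound, m$reactions[[id]]$upper_bound,
                 tolerance = 1e-11)
  }
  expect_equal(sort(m2$enzymes$id), sort(m$enzymes$id))
})

test_that("loader converts per-second kcats and flags malformed input", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "schema": "ecmodel-v1", "pool_bound": 0.1,
    "metabolites": [{"id": "A", "name": "A", "compartment": "c"},
                    {"id": "B", "name": "B", "compartment": "c"}],
    "enzymes": [{"id": "E1", "mw": 50.0, "genes": ["E1"]}],
    "reactions": [
      {"id": "EX_A", "stoichiometry": {"A": 1.0}, "lower_bound": 0.0,
       "upper_bound": 10.0, "kind": "exchange", "enzymes": []},
      {"id": "R1", "stoichiometry": {"A": -1.0, "B": 1.0}, "lower_bound": 0.0,
       "upper_bound": 10.0, "kind": "metabolic",
       "enzymes": [{"id": "E1", "kcat": 100.0, "kcat_unit": "per_second"}]},
      {"id": "EX_B", "stoichiometry": {"B": -1.0}, "lower_bound": 0.0,
       "upper_bound": 10.0, "kind": "exchange", "enzymes": []}
    ]}', f)
  m <- load_ecmodel(f)
  expect_equal(m$reactions[["R1"]]$enzymes[[1]]$kcat, 360000)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema": "ecmodel-v1", "metabolites": [], "reactions": [
    {"id": "r1", "stoichiometry": {}, "lower_bound": 5.0, "upper_bound": 1.0,
     "kind": "metabolic", "enzymes": []}]}', bad)
  expect_error(load_ecmodel(bad), "r1.*lower_bound")
  notjson <- withr::local_tempfile(fileext = ".json")
  writeLines("{nope", notjson)
  expect_error(load_ecmodel(notjson), "malformed")
  expect_error(load_ecmodel(file.path(tempdir(), "does-not-exist.json")),
               "no such file")
})

test_that("validation collects all violations", {
  mets <- mets_df(c("A", "A"))
  err <- tryCatch(
    ec_model(mets, list(reaction("r1", c(A = 1), 3, 1),
                        reaction("r2", c(Z = 1), 0, 1))),
    error = conditionMessage)
  expect_match(err, "duplicate metabolite id")
  expect_match(err, "r1: lower_bound 3 > upper_bound 1")
  expect_match(err, "r2: unknown metabolite\\(s\\) Z")
})

test_that("split_reversible matches its definition and preserves optima", {
  m <- ec_model(mets_df(c("A", "B")),
                list(reaction("EX_A", c(A = 1), 0, 10),
                     reaction("v", c(A = -1, B = 1), -5, 10),
                     reaction("EX_B", c(B = -1), -3, 10)))
  s <- split_reversible(m)
  expect_equal(s$reactions[["v_fwd"]]$lower_bound, 0)
  expect_equal(s$reactions[["v_fwd"]]$upper_bound, 10)
  expect_equal(s$reactions[["v_rev"]]$lower_bound, 0)
  expect_equal(s$reactions[["v_rev"]]$upper_bound, 5)
  expect_equal(s$reactions[["v_rev"]]$stoichiometry, c(A = 1, B = -1))

  irr <- chain_model()
  expect_equal(length(split_reversible(irr)$reactions), length(irr$reactions))

  # net flux space unchanged: brute-force optimum equal on both encodings
  lp0 <- model_lp_parts(m)
  lps <- model_lp_parts(s)
  for (obj_named in list(c(EX_B = 1), c(v = 1, EX_A = -0.5))) {
    o0 <- ecscreen:::expand_objective(obj_named, lp0$rxn_ids)
    # map net objective onto split variables: fwd +w, rev -w
    os <- vapply(lps$rxn_ids, function(id) {
      base <- sub("_(fwd|rev)$", "", id)
      w <- if (base %in% names(obj_named)) obj_named[[base]] else 0
      if (grepl("_rev$", id)) -w else w
    }, numeric(1))
    v0 <- vertex_enum_optimum(lp0$S, lp0$lb, lp0$ub, o0)$value
    vs <- vertex_enum_optimum(lps$S, lps$lb, lps$ub, os)$value
    expect_equal(v0, vs, tolerance = 1e-9)
  }
})

test_that("enzyme constraints encode the kcat and pool coupling", {
  m <- single_enzyme_model(kcat = 360000, mw = 50, pool = 0.1)
  v <- fba(m, c(EX_B = 1))
  expect_equal(v$objective_value, 720, tolerance = 1e-9)
  # pool tight at a pool-limited optimum
  usage <- v$values[["usage_E1"]]
  expect_equal(50 * usage, 0.1, tolerance = 1e-9)

  m0 <- single_enzyme_model(pool = 0)
  v0 <- fba(m0, c(EX_B = 1))
  expect_equal(v0$objective_value, 0, tolerance = 1e-12)

  # doubling all kcats doubles a pool-limited optimum
  m2 <- single_enzyme_model(kcat = 720000, mw = 50, pool = 0.1)
  expect_equal(fba(m2, c(EX_B = 1))$objective_value, 1440, tolerance = 1e-6)

  expect_error(to_enzyme_constrained(
    ec_model(mets_df("A"),
             list(reaction("r", c(A = 1), 0, 1, "metabolic",
                           list(list(id = "E1", kcat = -3)))),
             enzymes = {
               e <- data.frame(id = "E1", mw = 50)
               e$genes <- list("E1")
               e
             }, validate = FALSE)), "kcat")
})

test_that("a slack enzyme pool recovers the unconstrained flux polytope", {
  plain <- ecscreen:::core_network(synthetic_scenario(seed = 1))
  eco <- to_enzyme_constrained(plain, pool_bound = 1e9)
  set.seed(11)
  for (i in 1:10) {
    ids <- sample(names(plain$reactions), 2)
    obj <- stats::setNames(stats::runif(2), ids)
    expect_equal(fba(eco, obj)$objective_value,
                 fba(plain, obj)$objective_value, tolerance = 1e-6)
  }
})
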