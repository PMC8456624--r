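# Small models built in code for the unit and property tests.

mets_df <- function(ids) data.frame(id = ids, name = ids, compartment = "c",
                                    stringsAsFactors = FALSE)

# EX_A -> (A -> B, ub 7) -> EX_B
chain_model <- function(ub_mid = 7) {
  ec_model(mets_df(c("A", "B")),
           list(reaction("EX_A", c(A = 1), 0, 10, "exchange"),
                reaction("AtoB", c(A = -1, B = 1), 0, ub_mid),
                reaction("EX_B", c(B = -1), 0, 10, "exchange")))
}

# Uptake splits into two routes with a shared budget: trade-off between v1
# and v2.
tradeoff_model <- function() {
  ec_model(mets_df(c("A", "B", "C")),
           list(reaction("EX_A", c(A = 1), 0, 10),
                reaction("v1", c(A = -1, B = 1), 0, 8),
                reaction("v2", c(A = -1, C = 1), 0, 8),
                reaction("EX_B", c(B = -1), 0, 1000),
                reaction("EX_C", c(C = -1), 0, 1000)))
}

# One reaction, one enzyme: max flux = kcat * P / mw.
single_enzyme_model <- function(kcat = 360000, mw = 50, pool = 0.1) {
  enz <- data.frame(id = "E1", mw = mw, stringsAsFactors = FALSE)
  enz$genes <- list("E1")
  m <- ec_model(mets_df(c("A", "B")),
                list(reaction("EX_A", c(A = 1), 0, 1e6, "exchange"),
                     reaction("R1", c(A = -1, B = 1), 0, 1e6, "metabolic",
                              list(list(id = "E1", kcat = kcat))),
                     reaction("EX_B", c(B = -1), 0, 1e6, "exchange")),
                enzymes = enz)
  to_enzyme_constrained(m, pool_bound = pool)
}

# Random bounded branched network (feasible by construction: all lb 0).
random_toy_model <- function(seed) {
  set.seed(seed)
  ub <- round(stats::runif(6, 1, 10), 2)
  ec_model(mets_df(c("A", "B", "C")),
           list(reaction("EX_A", c(A = 1), 0, ub[1]),
                reaction("r1", c(A = -1, B = 1), 0, ub[2]),
                reaction("r2", c(A = -1, C = 1), 0, ub[3]),
                reaction("r3", c(B = -1, C = 1), 0, ub[4]),
                reaction("EX_B", c(B = -1), 0, ub[5]),
                reaction("EX_C", c(C = -1), 0, ub[6])))
}

# Two-enzyme ethanol-vs-glucose style toy with two extreme pathways to the
# same product, for sampling coverage checks.
two_pathway_model <- function() {
  enz <- data.frame(id = c("Ea", "Eb"), mw = c(50, 50), stringsAsFactors = FALSE)
  enz$genes <- list("Ea", "Eb")
  m <- ec_model(mets_df(c("A", "P")),
                list(reaction("EX_A", c(A = 1), 0, 10, "exchange"),
                     reaction("path_a", c(A = -1, P = 1), 0, 1000, "metabolic",
                              list(list(id = "Ea", kcat = 3600))),
                     reaction("path_b", c(A = -1, P = 1), 0, 1000, "metabolic",
                              list(list(id = "Eb", kcat = 3600))),
                     reaction("BIO", c(P = -1), 0, 1000, "biomass")),
                enzymes = enz, biomass_id = "BIO")
  to_enzyme_constrained(m, pool_bound = 0.1)
}

scenario_fixture <- function(seed = 1, ...) synthetic_scenario(seed = seed, ...)

calibrated_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_core_ecmodel(synthetic_scenario(seed = 1))
    cache
  }
})

toy_pset <- function(multipliers, delta = 0.20) {
  structure(list(multipliers = multipliers, delta = delta,
                 contrast = "fixture", table = NULL, unmapped = character()),
            class = "perturbation_set")
}
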