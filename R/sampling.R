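# Random sampling of feasible flux distributions under fixed growth on a
# single carbon source, by repeatedly maximizing a pair of randomly
# weighted reaction fluxes. Each retained sample is an optimal vertex of
# the constrained polytope, not a uniform draw from its interior.

#' Sampling configuration
#'
#' @param n_samples number of flux distributions to draw (default 1000).
#' @param seed integer seed; the whole sample list is reproducible from it.
#' @param candidate_reactions reaction ids eligible as objective components
#'   (default: all reactions except the pool exchange).
#' @param growth_value growth rate the biomass flux is fixed to (default
#'   0.22 h^-1).
#' @param growth_delta flexibilization factor on the growth constraint
#'   (default 0.05, i.e. +/-5%).
#' @param carbon_source name of the sole carbon source (default
#'   `"ethanol"`); all other carbon exchange uptakes are closed.
#' @return a `sampling_config` list.
#' @export
sampling_config <- function(n_samples = 1000, seed = 1,
                            candidate_reactions = NULL,
                            growth_value = 0.22, growth_delta = 0.05,
                            carbon_source = "ethanol") {
  stopifnot(n_samples >= 1, growth_delta >= 0)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 candidate_reactions = candidate_reactions,
                 growth_value = growth_value, growth_delta = growth_delta,
                 carbon_source = carbon_source),
            class = "sampling_config")
}

# Fix growth and restrict the medium to one carbon source.
constrain_to_carbon_source <- function(model, carbon_source, growth_value,
                                       growth_delta) {
  if (!carbon_source %in% names(model$carbon_exchange_ids))
    stop("unknown carbon source: ", carbon_source, call. = FALSE)
  for (src in setdiff(names(model$carbon_exchange_ids), carbon_source)) {
    id <- model$carbon_exchange_ids[[src]]
    model <- set_bounds(model, id, lower = 0, upper = 0)
  }
  if (!is.null(growth_value))
    model <- apply_flexible_constraint(
      model, flex_spec(model$biomass_id, growth_value, growth_delta))
  model
}

#' Sample feasible flux distributions with random paired objectives
#'
#' With growth fixed to `growth_value*(1 +/- growth_delta)` and
#' `carbon_source` as the sole carbon source, draws for each sample a pair
#' of distinct candidate reactions (i, j) uniformly and weights
#' w1, w2 ~ U(0,1) independently (draw order: pair first, then weights),
#' and maximizes `w1*v_i + w2*v_j`. Draws whose objective is unbounded are
#' rejected and redrawn (count in attribute `n_redrawn`).
#'
#' @param model an enzyme-constrained `ec_model`.
#' @param config a [sampling_config()].
#' @return list of `flux_distribution`s of length `n_samples`; each carries
#'   its `draw` (i, j, w1, w2).
#' @export
sample_flux_distributions <- function(model, config = sampling_config()) {
  base <- constrain_to_carbon_source(model, config$carbon_source,
                                     config$growth_value, config$growth_delta)
  feas <- fba(base, stats::setNames(1, base$biomass_id), "max")
  if (feas$status != "optimal")
    stop("base constraints infeasible: growth in [",
         config$growth_value * (1 - config$growth_delta), ", ",
         config$growth_value * (1 + config$growth_delta), "] on ",
         config$carbon_source, " cannot be met", call. = FALSE)
  kinds <- reaction_kinds(base)
  candidates <- config$candidate_reactions %||%
    names(base$reactions)[kinds != "pool_exchange"]
  if (length(candidates) < 2)
    stop("need at least two candidate reactions", call. = FALSE)
  lp <- model_lp(base)
  set.seed(config$seed)
  out <- vector("list", config$n_samples)
  n_redrawn <- 0L
  for (s in seq_len(config$n_samples)) {
    repeat {
      pair <- sample(candidates, 2)
      w <- stats::runif(2)
      obj <- expand_objective(stats::setNames(w, pair), lp$rxn_ids)
      sol <- solve_lp(obj, lp$S, lp$lb, lp$ub, "max")
      if (sol$status == "optimal") break
      if (sol$status == "infeasible")
        stop("constraints became infeasible during sampling", call. = FALSE)
      n_redrawn <- n_redrawn + 1L
    }
    d <- new_flux_distribution(sol$x, sol$value, "optimal", lp$rxn_ids)
    d$draw <- list(i = pair[1], j = pair[2], w1 = w[1], w2 = w[2])
    out[[s]] <- d
  }
  attr(out, "n_redrawn") <- n_redrawn
  attr(out, "seed") <- config$seed
  out
}

#' Bind sampled distributions into a reactions x samples matrix
#'
#' @param samples list of `flux_distribution`s.
#' @return numeric matrix, rows = reactions (incl. enzyme usages), columns
#'   = samples.
#' @export
samples_to_matrix <- function(samples) {
  stopifnot(length(samples) >= 1)
  m <- vapply(samples, function(d) d$values, samples[[1]]$values)
  colnames(m) <- sprintf("sample_%04d", seq_along(samples))
  m
}
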