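# Linear programming over ec_model objects. The solver behind all
# operations is the two-phase simplex in boot::simplex; this file adapts
# FBA problems (equality mass balance, box bounds, optional extra linear
# constraints) to its A1/A2/A3 form and adds unboundedness detection via a
# finite-cap probe.

# Build the LP data of a model: dense stoichiometric matrix (metabolites x
# reactions) and bound vectors, in reaction order.
model_lp <- function(model) {
  rxn_ids <- names(model$reactions)
  met_ids <- model$metabolites$id
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(rxn_ids)) {
    st <- model$reactions[[j]]$stoichiometry
    if (length(st)) S[names(st), j] <- S[names(st), j] + unname(st)
  }
  list(S = S,
       lb = vapply(model$reactions, function(r) r$lower_bound, numeric(1)),
       ub = vapply(model$reactions, function(r) r$upper_bound, numeric(1)),
       rxn_ids = rxn_ids, met_ids = met_ids)
}

# Solve max/min obj'v subject to S v = 0, lb <= v <= ub and optional extra
# rows (list(a=, dir="<="|">=", rhs=)). Extra inequalities get one slack
# column each. Returns list(x, value, status) with status in {"optimal",
# "infeasible", "unbounded"}.
solve_lp <- function(obj, S, lb, ub, sense = "max", extra = list(),
                     beq = NULL) {
  stopifnot(sense %in% c("max", "min"))
  n <- length(lb)
  if (any(!is.finite(lb)))
    stop("all lower bounds must be finite (irreversible convention)", call. = FALSE)
  if (is.null(beq)) beq <- rep(0, nrow(S))
  A <- S
  b <- beq
  l <- lb
  u <- ub
  cvec <- obj
  if (length(extra)) {
    k <- length(extra)
    A <- rbind(cbind(S, matrix(0, nrow(S), k)),
               cbind(do.call(rbind, lapply(extra, `[[`, "a")),
                     diag(vapply(extra, function(ex)
                       if (ex$dir == "<=") 1 else -1, numeric(1)), k)))
    b <- c(beq, vapply(extra, `[[`, numeric(1), "rhs"))
    l <- c(lb, rep(0, k))
    u <- c(ub, rep(Inf, k))
    cvec <- c(obj, rep(0, k))
  }
  sol <- simplex_bounded(cvec, A, b, l, u, sense)
  if (sol$status != "optimal") return(sol)
  list(x = sol$x[seq_len(n)], value = sum(obj * sol$x[seq_len(n)]),
       status = "optimal")
}

expand_objective <- function(objective, rxn_ids) {
  miss <- setdiff(names(objective), rxn_ids)
  if (length(miss))
    stop("objective references unknown reaction(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  obj <- numeric(length(rxn_ids))
  names(obj) <- rxn_ids
  obj[names(objective)] <- objective
  unname(obj)
}

new_flux_distribution <- function(values, objective_value, status, rxn_ids) {
  v <- if (is.null(values)) stats::setNames(rep(NA_real_, length(rxn_ids)), rxn_ids)
       else stats::setNames(values, rxn_ids)
  structure(list(values = v, objective_value = objective_value, status = status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("flux_distribution: status %s, objective %.6g, %d reactions\n",
              x$status, x$objective_value, length(x$values)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) a linear objective over the steady-state flux
#' polytope `{v : S v = 0, lb <= v <= ub}`.
#'
#' @param model an `ec_model`.
#' @param objective named numeric vector of objective weights, reaction id
#'   -> weight.
#' @param sense `"max"` or `"min"`.
#' @return a `flux_distribution` with fields `values` (named flux vector),
#'   `objective_value`, and `status` (`"optimal"`, `"infeasible"`, or
#'   `"unbounded"`). On non-optimal status the fluxes are `NA`.
#' @export
fba <- function(model, objective, sense = "max") {
  lp <- model_lp(model)
  obj <- expand_objective(objective, lp$rxn_ids)
  sol <- solve_lp(obj, lp$S, lp$lb, lp$ub, sense)
  new_flux_distribution(sol$x, sol$value, sol$status, lp$rxn_ids)
}

#' Check mass balance and bounds of a flux distribution
#'
#' @param model an `ec_model`.
#' @param dist a `flux_distribution`.
#' @param tol absolute tolerance (default 1e-6).
#' @return list with `ok` and the maximal balance/bound violations.
#' @export
check_distribution <- function(model, dist, tol = 1e-6) {
  lp <- model_lp(model)
  v <- dist$values[lp$rxn_ids]
  bal <- max(abs(lp$S %*% v))
  bound <- max(0, lp$lb - v, v - pmin(lp$ub, Inf))
  list(ok = bal <= tol && bound <= tol, balance = bal, bounds = max(bound))
}

#' Construct a flexibilized constraint specification
#'
#' Fixing a flux to an observed or computed value with relative slack
#' `delta`: bounds become `[value*(1-delta), value*(1+delta)]`, clipped
#' below at 0 (irreversible convention).
#'
#' @param reaction_id reaction to constrain.
#' @param value target flux (>= 0).
#' @param delta relative flexibilization factor (e.g. 0.05 for +/-5%).
#' @return a `flex_spec` list.
#' @export
flex_spec <- function(reaction_id, value, delta = 0.05) {
  stopifnot(delta >= 0, value >= 0)
  structure(list(reaction_id = reaction_id, value = value, delta = delta),
            class = "flex_spec")
}

#' Apply a flexibilized constraint to a model
#'
#' @param model an `ec_model`.
#' @param spec a [flex_spec()].
#' @return the model with the reaction's bounds set to
#'   `[max(0, value*(1-delta)), value*(1+delta)]`.
#' @export
apply_flexible_constraint <- function(model, spec) {
  set_bounds(model, spec$reaction_id,
             lower = max(0, spec$value * (1 - spec$delta)),
             upper = spec$value * (1 + spec$delta))
}

#' Lexicographic multi-objective optimization
#'
#' Solves an ordered list of objectives; after each stage, the achieved
#' optimum is fixed as a constraint with relative tolerance `fix_tolerance`
#' (slack `fix_tolerance * max(1, |optimum|)`) before the next solve.
#'
#' @param model an `ec_model`.
#' @param objectives list of `list(objective = <named weights>, sense =
#'   "max"|"min")`, solved in order.
#' @param fix_tolerance relative slack used to fix each stage's optimum.
#' @return the final `flux_distribution`, with `stage_optima` (numeric
#'   vector of per-stage optima) and, on failure, `failed_stage`.
#' @export
lexicographic_optimize <- function(model, objectives, fix_tolerance = 1e-6) {
  stopifnot(length(objectives) >= 1)
  lp <- model_lp(model)
  extra <- list()
  optima <- numeric(0)
  sol <- NULL
  for (k in seq_along(objectives)) {
    ob <- objectives[[k]]
    sense <- ob$sense %||% "max"
    obj <- expand_objective(ob$objective, lp$rxn_ids)
    sol <- solve_lp(obj, lp$S, lp$lb, lp$ub, sense, extra = extra)
    if (sol$status != "optimal") {
      out <- new_flux_distribution(NULL, NA_real_, sol$status, lp$rxn_ids)
      out$stage_optima <- optima
      out$failed_stage <- k
      return(out)
    }
    optima <- c(optima, sol$value)
    slack <- fix_tolerance * max(1, abs(sol$value))
    extra[[length(extra) + 1]] <-
      if (sense == "max") list(a = obj, dir = ">=", rhs = sol$value - slack)
      else list(a = obj, dir = "<=", rhs = sol$value + slack)
  }
  out <- new_flux_distribution(sol$x, sol$value, "optimal", lp$rxn_ids)
  out$stage_optima <- optima
  out
}

#' Maximum non-growth-associated maintenance (NGAM)
#'
#' Fixes the supplied exchange fluxes (uptake, secretion, biomass) to their
#' observed values with their flexibilization factors, then maximizes flux
#' through the model's NGAM reaction (ATP hydrolysis not coupled to
#' growth).
#'
#' @param model an `ec_model` with `ngam_id` set.
#' @param fixed_exchanges list of [flex_spec()] constraints.
#' @return the maximum NGAM flux in mmol ATP·gDW^-1·h^-1.
#' @export
max_ngam <- function(model, fixed_exchanges = list()) {
  if (is.na(model$ngam_id)) stop("model has no NGAM reaction", call. = FALSE)
  m <- model
  for (sp in fixed_exchanges) m <- apply_flexible_constraint(m, sp)
  obj <- stats::setNames(1, model$ngam_id)
  sol <- fba(m, obj, "max")
  if (sol$status != "optimal") {
    # identify the first constraint whose addition breaks feasibility
    m2 <- model
    for (sp in fixed_exchanges) {
      m2 <- apply_flexible_constraint(m2, sp)
      probe <- fba(m2, obj, "max")
      if (probe$status == "infeasible")
        stop(sprintf("fixed exchange on reaction %s (value %g, delta %g) makes the model infeasible",
                     sp$reaction_id, sp$value, sp$delta), call. = FALSE)
    }
    stop("NGAM maximization not optimal: status ", sol$status, call. = FALSE)
  }
  sol$objective_value
}
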