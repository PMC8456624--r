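REACTION_KINDS <- c("metabolic", "exchange", "biomass", "ngam",
                    "enzyme_usage", "pool_exchange")

#' Construct a reaction record
#'
#' A reaction couples metabolites through signed stoichiometric coefficients
#' and carries flux bounds in mmol·gDW^-1·h^-1. Enzyme associations attach
#' one or more catalytic subunits, each with a turnover number kcat (h^-1).
#' A multi-entry `enzymes` list is interpreted as an enzyme complex (all
#' subunits jointly required); isozymes are modeled as parallel reaction
#' copies, one per enzyme.
#'
#' @param id reaction identifier (unique within a model).
#' @param stoichiometry named numeric vector, metabolite id -> coefficient
#'   (negative = consumed, positive = produced).
#' @param lower_bound,upper_bound flux bounds.
#' @param kind one of `"metabolic"`, `"exchange"`, `"biomass"`, `"ngam"`,
#'   `"enzyme_usage"`, `"pool_exchange"`.
#' @param enzymes list of `list(id=, kcat=)` enzyme associations (kcat in
#'   h^-1), or `NULL` for a spontaneous/non-catalyzed reaction.
#' @return a list of class `ec_reaction`.
#' @export
reaction <- function(id, stoichiometry = numeric(), lower_bound = 0,
                     upper_bound = 1000, kind = "metabolic", enzymes = NULL) {
  kind <- match.arg(kind, REACTION_KINDS)
  structure(list(id = as.character(id),
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 kind = kind,
                 enzymes = enzymes),
            class = "ec_reaction")
}

#' Construct a metabolic model
#'
#' The container for (optionally enzyme-constrained) stoichiometric models.
#' Fluxes are in mmol·gDW^-1·h^-1, molecular weights in g·mmol^-1
#' (numerically kDa), kcats in h^-1, and the enzyme pool bound in g·gDW^-1,
#' so that the pool constraint sum(mw_i * e_i) <= pool_bound is
#' dimensionally consistent.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions list of [reaction()] records.
#' @param enzymes data.frame with columns `id`, `mw` and a list column
#'   `genes`, or `NULL` for a plain stoichiometric model.
#' @param pool_bound total enzyme pool in g·gDW^-1 (default 0.1).
#' @param biomass_id,ngam_id ids of the biomass and non-growth-associated
#'   maintenance (NGAM) reactions, or `NA`.
#' @param carbon_exchange_ids named character vector mapping a carbon source
#'   name (e.g. `"glucose"`, `"ethanol"`) to its uptake exchange reaction id.
#' @param validate validate invariants on construction (default TRUE).
#' @return an object of class `ec_model`.
#' @export
ec_model <- function(metabolites, reactions, enzymes = NULL, pool_bound = 0.1,
                     biomass_id = NA_character_, ngam_id = NA_character_,
                     carbon_exchange_ids = character(), validate = TRUE) {
  names(reactions) <- vapply(reactions, function(r) r$id, character(1))
  m <- structure(list(schema = "ecmodel-v1",
                      pool_bound = as.numeric(pool_bound),
                      metabolites = metabolites,
                      enzymes = enzymes,
                      reactions = reactions,
                      biomass_id = as.character(biomass_id),
                      ngam_id = as.character(ngam_id),
                      carbon_exchange_ids = carbon_exchange_ids),
                 class = "ec_model")
  if (validate) validate_ecmodel(m)
  m
}

#' @export
print.ec_model <- function(x, ...) {
  n_enz <- if (is.null(x$enzymes)) 0L else nrow(x$enzymes)
  cat(sprintf("ec_model: %d metabolites, %d reactions, %d enzymes, pool %.4g g/gDW\n",
              nrow(x$metabolites), length(x$reactions), n_enz, x$pool_bound))
  invisible(x)
}

reaction_kinds <- function(model)
  vapply(model$reactions, function(r) r$kind, character(1))

#' Validate model invariants
#'
#' Checks identifier uniqueness, bound ordering, kcat positivity, enzyme
#' references, usage/pool wiring of enzyme-constrained models, and the
#' uniqueness of the biomass and NGAM reactions. All violations are
#' collected and reported together.
#'
#' @param model an `ec_model`.
#' @return the model, invisibly; stops with a validation error listing all
#'   violations otherwise.
#' @export
validate_ecmodel <- function(model) {
  bad <- character()
  met_ids <- model$metabolites$id
  if (any(!nzchar(met_ids))) bad <- c(bad, "empty metabolite id")
  if (anyDuplicated(met_ids))
    bad <- c(bad, paste("duplicate metabolite id:",
                        paste(unique(met_ids[duplicated(met_ids)]), collapse = ", ")))
  rxn_ids <- names(model$reactions)
  if (anyDuplicated(rxn_ids))
    bad <- c(bad, paste("duplicate reaction id:",
                        paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))
  enz_ids <- if (is.null(model$enzymes)) character() else model$enzymes$id
  if (anyDuplicated(enz_ids))
    bad <- c(bad, paste("duplicate enzyme id:",
                        paste(unique(enz_ids[duplicated(enz_ids)]), collapse = ", ")))
  if (length(enz_ids) && any(model$enzymes$mw <= 0))
    bad <- c(bad, paste("non-positive mw for enzyme:",
                        paste(enz_ids[model$enzymes$mw <= 0], collapse = ", ")))
  for (r in model$reactions) {
    if (r$lower_bound > r$upper_bound)
      bad <- c(bad, sprintf("reaction %s: lower_bound %g > upper_bound %g",
                            r$id, r$lower_bound, r$upper_bound))
    mets <- names(r$stoichiometry)
    miss <- setdiff(mets, met_ids)
    if (length(miss))
      bad <- c(bad, sprintf("reaction %s: unknown metabolite(s) %s",
                            r$id, paste(miss, collapse = ", ")))
    for (e in r$enzymes) {
      if (!e$id %in% enz_ids)
        bad <- c(bad, sprintf("reaction %s: unknown enzyme %s", r$id, e$id))
      if (!is.numeric(e$kcat) || e$kcat <= 0)
        bad <- c(bad, sprintf("reaction %s: kcat <= 0 for enzyme %s", r$id, e$id))
    }
  }
  kinds <- reaction_kinds(model)
  for (kd in c("biomass", "ngam"))
    if (sum(kinds == kd) > 1)
      bad <- c(bad, sprintf("more than one reaction of kind %s", kd))
  if (!is.na(model$biomass_id) && !model$biomass_id %in% rxn_ids)
    bad <- c(bad, sprintf("biomass_id %s not a reaction", model$biomass_id))
  if (!is.na(model$ngam_id) && !model$ngam_id %in% rxn_ids)
    bad <- c(bad, sprintf("ngam_id %s not a reaction", model$ngam_id))
  # enzyme-constrained wiring, only once usage reactions exist
  if (any(kinds == "enzyme_usage")) {
    usage_of <- sub("^usage_", "", rxn_ids[kinds == "enzyme_usage"])
    for (eid in enz_ids) {
      n_us <- sum(usage_of == eid)
      if (n_us != 1L)
        bad <- c(bad, sprintf("enzyme %s has %d usage reactions (expected 1)", eid, n_us))
    }
    pool_rxn <- rxn_ids[kinds == "pool_exchange"]
    if (length(pool_rxn) != 1L) {
      bad <- c(bad, "expected exactly one pool_exchange reaction")
    } else if (abs(model$reactions[[pool_rxn]]$upper_bound - model$pool_bound) > 1e-12) {
      bad <- c(bad, sprintf("pool_exchange upper bound %g != pool_bound %g",
                            model$reactions[[pool_rxn]]$upper_bound, model$pool_bound))
    }
  }
  if (length(bad))
    stop("model validation failed:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(model)
}

#' Set the bounds of one reaction
#'
#' @param model an `ec_model`.
#' @param id reaction id.
#' @param lower,upper new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  if (!id %in% names(model$reactions)) stop("unknown reaction: ", id, call. = FALSE)
  if (!is.null(lower)) model$reactions[[id]]$lower_bound <- lower
  if (!is.null(upper)) model$reactions[[id]]$upper_bound <- upper
  model
}

#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with `lower_bound < 0` is replaced by a forward copy
#' (`<id>_fwd`, bounds `[max(lb,0), max(ub,0)]`) and a reverse copy
#' (`<id>_rev`, negated stoichiometry, bounds `[max(-ub,0), -lb]`), leaving
#' the net flux space unchanged. Enzyme associations are copied to both
#' directions. Required before enzyme-constrained augmentation, where enzyme
#' demand couples to non-negative flux.
#'
#' @param model an `ec_model`.
#' @return a model in which every reaction has `lower_bound >= 0`.
#' @export
split_reversible <- function(model) {
  out <- list()
  for (r in model$reactions) {
    if (r$lower_bound >= 0) {
      out[[r$id]] <- r
      next
    }
    fwd <- r
    fwd$id <- paste0(r$id, "_fwd")
    fwd$lower_bound <- max(r$lower_bound, 0)
    fwd$upper_bound <- max(r$upper_bound, 0)
    rev <- r
    rev$id <- paste0(r$id, "_rev")
    rev$stoichiometry <- -r$stoichiometry
    rev$lower_bound <- max(-r$upper_bound, 0)
    rev$upper_bound <- -r$lower_bound
    out[[fwd$id]] <- fwd
    out[[rev$id]] <- rev
  }
  model$reactions <- out
  model
}

#' Add GECKO-style enzyme constraints to an irreversible model
#'
#' For each enzyme-catalyzed reaction j with enzyme subunit i, the enzyme
#' pseudo-metabolite `prot_<i>` is consumed with coefficient 1/kcat_ij; each
#' enzyme i gains an `enzyme_usage` reaction `usage_<i>` producing
#' `prot_<i>` and drawing `mw_i` of the pool pseudo-metabolite `prot_pool`
#' per unit usage flux; the pool metabolite is supplied by a single
#' `pool_exchange` reaction with upper bound `pool_bound`. At steady state
#' this encodes v_j <= kcat_ij * e_i for every subunit and
#' sum(mw_i * e_i) <= pool_bound.
#'
#' Each usage reaction's upper bound is set to its pool-only limit
#' `pool_bound / mw_i` (an enzyme can never exceed the whole pool), which
#' keeps all bounds finite.
#'
#' @param model an irreversible `ec_model` whose reactions carry enzyme
#'   associations with kcat in h^-1.
#' @param enzymes enzyme table (default: the model's own).
#' @param pool_bound total enzyme pool in g·gDW^-1 (default 0.1, the
#'   conventional GECKO enzyme pool parameter).
#' @return an enzyme-constrained `ec_model`.
#' @export
to_enzyme_constrained <- function(model, enzymes = model$enzymes, pool_bound = 0.1) {
  if (is.null(enzymes) || nrow(enzymes) == 0)
    stop("no enzyme table supplied", call. = FALSE)
  if (any(vapply(model$reactions, function(r) r$lower_bound < 0, logical(1))))
    stop("model must be irreversible; call split_reversible() first", call. = FALSE)
  used <- character()
  for (r in model$reactions) {
    for (e in r$enzymes) {
      if (!is.numeric(e$kcat) || e$kcat <= 0)
        stop(sprintf("reaction %s: enzyme %s has kcat <= 0", r$id, e$id),
             call. = FALSE)
      used <- c(used, e$id)
    }
  }
  used <- unique(used)
  rxns <- model$reactions
  for (i in seq_along(rxns)) {
    for (e in rxns[[i]]$enzymes) {
      pm <- paste0("prot_", e$id)
      cur <- rxns[[i]]$stoichiometry
      cur[pm] <- if (pm %in% names(cur)) cur[[pm]] - 1 / e$kcat else -1 / e$kcat
      rxns[[i]]$stoichiometry <- cur
    }
  }
  mets <- model$metabolites
  add_met <- function(mets, id, name)
    rbind(mets, data.frame(id = id, name = name, compartment = "enzyme",
                           stringsAsFactors = FALSE))
  mets <- add_met(mets, "prot_pool", "total enzyme pool")
  for (eid in used) mets <- add_met(mets, paste0("prot_", eid), paste("enzyme", eid))
  for (eid in used) {
    mw <- enzymes$mw[match(eid, enzymes$id)]
    st <- c(-mw, 1)
    names(st) <- c("prot_pool", paste0("prot_", eid))
    rxns[[paste0("usage_", eid)]] <-
      reaction(paste0("usage_", eid), st, 0, pool_bound / mw, "enzyme_usage")
  }
  rxns[["pool_exchange"]] <-
    reaction("pool_exchange", c(prot_pool = 1), 0, pool_bound, "pool_exchange")
  model$metabolites <- mets
  model$reactions <- rxns
  model$enzymes <- enzymes
  model$pool_bound <- pool_bound
  validate_ecmodel(model)
}

#' Pool-only usage limit of one enzyme
#'
#' The usage flux an enzyme could reach if it took up the entire pool:
#' `pool_bound / mw`. This is the bound "removing the constraint" on an
#' enzyme restores in the rescue screen.
#'
#' @param model an enzyme-constrained `ec_model`.
#' @param enzyme_id enzyme id.
#' @return the usage bound in mmol·gDW^-1.
#' @export
pool_usage_limit <- function(model, enzyme_id) {
  i <- match(enzyme_id, model$enzymes$id)
  if (is.na(i)) stop("unknown enzyme: ", enzyme_id, call. = FALSE)
  model$pool_bound / model$enzymes$mw[i]
}
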