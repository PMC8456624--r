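# The in-silico rescue experiment: relax perturbed enzymes one at a time,
# recompute maximum growth per sampled background, average over feasible
# backgrounds, threshold against the target growth window; plus
# hypergeometric enrichment of the rescuers in local gene sets.

#' Single-enzyme rescue screen
#'
#' For each perturbed enzyme, rebuilds the perturbed model per sampled
#' background, removes only that enzyme's usage cap — restoring it to the
#' pool-only limit `pool_bound / mw`, not to infinity — and maximizes
#' growth. The mean maximum growth rate is taken over the backgrounds that
#' were feasible in the perturbed screen; an enzyme is a rescuer when that
#' mean reaches `mu_target * (1 - delta)`.
#'
#' @param model the unconstrained enzyme-constrained model.
#' @param samples list of `flux_distribution`s (the sampled reference
#'   backgrounds).
#' @param pset a [build_perturbation_set()] result.
#' @param mu_target growth rate to rescue to (default 0.22 h^-1).
#' @param delta flexibilization on the rescue criterion (default 0.05).
#' @param screen optional result of [perturbed_growth_screen()]; computed
#'   if missing.
#' @param carbon_source sole carbon source (default `"ethanol"`).
#' @return data.frame with one row per perturbed enzyme: `enzyme`,
#'   `mean_mu_max`, `n_samples`, `rescuer`.
#' @export
single_enzyme_rescue <- function(model, samples, pset, mu_target = 0.22,
                                 delta = 0.05, screen = NULL,
                                 carbon_source = "ethanol") {
  if (!length(pset$multipliers))
    return(data.frame(enzyme = character(), mean_mu_max = numeric(),
                      n_samples = integer(), rescuer = logical()))
  if (is.null(screen))
    screen <- perturbed_growth_screen(model, samples, pset,
                                      carbon_source = carbon_source)
  feas <- which(screen$feasible)
  base <- constrain_to_carbon_source(model, carbon_source, NULL, 0)
  lp <- model_lp(base)
  bio <- match(model$biomass_id, lp$rxn_ids)
  obj_bio <- numeric(length(lp$rxn_ids)); obj_bio[bio] <- 1
  enzymes <- names(pset$multipliers)
  out <- data.frame(enzyme = enzymes, mean_mu_max = NA_real_,
                    n_samples = length(feas), rescuer = FALSE)
  if (!length(feas)) return(out)
  # per-sample perturbed bounds computed once
  bounds <- lapply(feas, function(s)
    perturbed_usage_bounds(lp, pset, samples[[s]]$values))
  for (k in seq_along(enzymes)) {
    relax_idx <- match(paste0("usage_", enzymes[k]), lp$rxn_ids)
    mu <- vapply(bounds, function(pb) {
      ub2 <- lp$ub
      ub2[pb$idx] <- pb$ub
      ub2[relax_idx] <- lp$ub[relax_idx]  # pool-only limit
      g <- solve_lp(obj_bio, lp$S, lp$lb, ub2, "max")
      if (g$status == "optimal") g$value else NA_real_
    }, numeric(1))
    out$mean_mu_max[k] <- mean(mu, na.rm = TRUE)
    out$rescuer[k] <- !is.na(out$mean_mu_max[k]) &&
      out$mean_mu_max[k] >= mu_target * (1 - delta)
  }
  attr(out, "mu_target") <- mu_target
  attr(out, "delta") <- delta
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (term, description, tab-separated genes).
#' @return named list of character vectors; descriptions kept in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character; defaults to the term name.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(tm) {
    desc <- if (!is.null(descriptions) && tm %in% names(descriptions))
      descriptions[[tm]] else tm
    paste(c(tm, desc, sets[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of a query gene set against each term:
#' `p = P(X >= overlap)` with population `|universe|`, successes
#' `|term n universe|`, draws `|query|`; Benjamini-Hochberg adjustment
#' across all tested terms. Only terms passing the `> 5 genes` reporting
#' rule are returned — by default applied to the term's overlap with the
#' query (`count_rule = "overlap"`), or to the term size with
#' `count_rule = "term_size"`.
#'
#' @param query gene set to test (must lie within `universe`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe background gene set; terms are intersected with it
#'   before testing.
#' @param min_genes minimal gene count for reporting (default 6, i.e.
#'   strictly more than 5).
#' @param count_rule `"overlap"` (default) or `"term_size"`.
#' @return data.frame `term`, `term_size`, `overlap`, `p_value`, `q_value`,
#'   sorted by p-value.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, universe,
                                      min_genes = 6,
                                      count_rule = c("overlap", "term_size")) {
  count_rule <- match.arg(count_rule)
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ",
         paste(outside, collapse = ", "), call. = FALSE)
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(gene_sets), function(tm) {
    term <- intersect(gene_sets[[tm]], universe)
    K <- length(term)
    if (K == 0) return(NULL)
    ov <- length(intersect(term, query))
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, term_size = K, overlap = ov, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(term = character(), term_size = integer(),
                      overlap = integer(), p_value = numeric(),
                      q_value = numeric()))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  keep <- if (count_rule == "overlap") res$overlap >= min_genes
          else res$term_size >= min_genes
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
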