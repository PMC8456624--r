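# Differential-expression tables, count matrices, the poorly-induced-gene
# classifier, read-fraction accounting, and the translation of enzyme
# fold-changes into usage-bound perturbations for the growth screen.

#' Read a differential-expression table
#'
#' Tab-separated, UTF-8, with header columns `gene`, `log2FC`, `FDR`.
#'
#' @param path TSV file path.
#' @param contrast optional contrast label stored as an attribute.
#' @return data.frame with columns `gene`, `log2FC`, `FDR`.
#' @export
read_de_table <- function(path, contrast = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2FC", "FDR")
  if (!all(need %in% names(d)))
    stop("DE table ", path, " must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- d[need]
  if (anyDuplicated(d$gene))
    stop("DE table ", path, " has duplicated genes", call. = FALSE)
  if (any(d$FDR < 0 | d$FDR > 1))
    stop("DE table ", path, ": FDR outside [0, 1]", call. = FALSE)
  attr(d, "contrast") <- contrast
  d
}

#' Write a differential-expression table
#' @param de data.frame with `gene`, `log2FC`, `FDR`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  write_tsv_plain(de[c("gene", "log2FC", "FDR")], path)
}

#' Read a count matrix with its sample-group map
#'
#' @param counts_path TSV with first column `gene`, remaining columns
#'   sample ids, non-negative integer read counts.
#' @param groups_path two-column TSV `sample`, `group`.
#' @return list with `counts` (genes x samples integer matrix) and
#'   `groups` (named character, sample -> group).
#' @export
read_count_matrix <- function(counts_path, groups_path) {
  d <- utils::read.delim(counts_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "gene")
    stop("count matrix first column must be 'gene'", call. = FALSE)
  m <- as.matrix(d[-1])
  rownames(m) <- d$gene
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  count_matrix(m, stats::setNames(g$group, g$sample))
}

#' Construct a count matrix object
#' @param counts genes x samples matrix of non-negative counts.
#' @param groups named character vector, sample -> condition group.
#' @return a `count_matrix` list.
#' @export
count_matrix <- function(counts, groups) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  miss <- setdiff(colnames(counts), names(groups))
  if (length(miss))
    stop("sample(s) without a group: ", paste(miss, collapse = ", "),
         call. = FALSE)
  structure(list(counts = counts, groups = groups[colnames(counts)]),
            class = "count_matrix")
}

#' Classify poorly induced genes
#'
#' A gene is poorly induced when it is significantly upregulated in the
#' reference strain on the glucose-to-ethanol transition
#' (`log2FC > fc_threshold` and `FDR < fdr_threshold`, both strict) but at
#' least two-fold less induced in the mutant: reference log2FC minus mutant
#' log2FC `>= gap` (gap 1 on the log2 scale = two-fold).
#'
#' @param de_wt reference-strain DE table (ethanol vs glucose phase).
#' @param de_mut mutant DE table for the same contrast. Genes present in
#'   `de_wt` but absent here are treated as not induced (log2FC 0), with a
#'   warning.
#' @param fc_threshold,fdr_threshold significance thresholds (defaults 1
#'   and 0.01).
#' @param gap minimal log2FC difference reference - mutant (default 1).
#' @return sorted character vector of poorly induced genes.
#' @export
classify_poorly_induced <- function(de_wt, de_mut, fc_threshold = 1,
                                    fdr_threshold = 0.01, gap = 1) {
  if (nrow(de_wt) == 0 || nrow(de_mut) == 0) {
    warning("empty DE table; returning empty set")
    return(character())
  }
  idx <- match(de_wt$gene, de_mut$gene)
  if (anyNA(idx))
    warning(sum(is.na(idx)),
            " gene(s) absent from the mutant table treated as log2FC = 0")
  mut_fc <- ifelse(is.na(idx), 0, de_mut$log2FC[idx])
  hit <- de_wt$log2FC > fc_threshold & de_wt$FDR < fdr_threshold &
    (de_wt$log2FC - mut_fc) >= gap
  sort(de_wt$gene[hit])
}

#' Filter genes by counts-per-million and dubious-ORF status
#'
#' CPM = count * 1e6 / library size. Under the default `mode = "groups"`, a
#' gene is removed when its CPM is below `cpm_threshold` in every sample of
#' at least `group_threshold` condition groups; under `mode = "samples"` it
#' is removed when below threshold in at least `group_threshold` samples.
#' Dubious ORFs are always removed.
#'
#' @param cm a [count_matrix()].
#' @param cpm_threshold CPM cutoff (default 1).
#' @param group_threshold number of offending groups (or samples) required
#'   for removal (default 3).
#' @param dubious_orfs gene ids removed unconditionally.
#' @param mode `"groups"` (default) or `"samples"`.
#' @return sorted character vector of kept genes.
#' @export
cpm_filter <- function(cm, cpm_threshold = 1, group_threshold = 3,
                       dubious_orfs = character(), mode = c("groups", "samples")) {
  mode <- match.arg(mode)
  libsize <- colSums(cm$counts)
  if (any(libsize <= 0)) stop("library sizes must be > 0", call. = FALSE)
  cpm <- sweep(cm$counts, 2, libsize, "/") * 1e6
  low <- cpm < cpm_threshold
  if (mode == "groups") {
    per_group <- vapply(unique(cm$groups), function(g)
      apply(low[, cm$groups == g, drop = FALSE], 1, all), logical(nrow(cpm)))
    drop <- rowSums(per_group) >= group_threshold
  } else {
    drop <- rowSums(low) >= group_threshold
  }
  kept <- rownames(cm$counts)[!drop]
  sort(setdiff(kept, dubious_orfs))
}

#' Fraction of reads attributable to a gene set
#'
#' @param cm a [count_matrix()].
#' @param gene_set character vector of genes; genes absent from the matrix
#'   count as zero, with a warning.
#' @param sample_group condition group over whose samples reads are summed.
#' @return percentage in \[0, 100\]: 100 * set reads / total reads.
#' @export
read_fraction <- function(cm, gene_set, sample_group) {
  if (!sample_group %in% cm$groups)
    stop("unknown sample group: ", sample_group, call. = FALSE)
  cols <- cm$groups == sample_group
  total <- sum(cm$counts[, cols])
  if (total <= 0) stop("group ", sample_group, " has zero total counts",
                       call. = FALSE)
  miss <- setdiff(gene_set, rownames(cm$counts))
  if (length(miss))
    warning(length(miss), " gene(s) absent from the count matrix counted as 0")
  present <- intersect(gene_set, rownames(cm$counts))
  100 * sum(cm$counts[present, cols, drop = FALSE]) / total
}

#' Translate enzyme fold-changes into usage-bound multipliers
#'
#' Each perturbed enzyme's simulated usage is to be capped at
#' `usage * multiplier * (1 + delta)`, with `multiplier = 2^log2FC` from
#' the strain-contrast DE table, `multiplier = 0` for deleted genes, and
#' the minimum multiplier for enzymes mapping to several genes
#' (conservative bottleneck assumption).
#'
#' @param de_table DE table of the mutant-vs-reference contrast.
#' @param enzyme_gene_map named list, enzyme id -> character vector of gene
#'   ids.
#' @param deleted_genes genes deleted in the mutant (multiplier 0).
#' @param delta flexibilization factor on the perturbed bounds (default
#'   0.20).
#' @return a `perturbation_set`: `multipliers` (named numeric),
#'   `delta`, `table` (per-enzyme report with the driving gene), and
#'   `unmapped` (enzymes mapping to no gene in the table).
#' @export
build_perturbation_set <- function(de_table, enzyme_gene_map,
                                   deleted_genes = character(), delta = 0.20) {
  stopifnot(delta >= 0)
  mult <- numeric(0)
  rows <- list()
  unmapped <- character()
  for (enz in names(enzyme_gene_map)) {
    genes <- enzyme_gene_map[[enz]]
    cand_mult <- numeric(0)
    cand_gene <- character(0)
    cand_fc <- numeric(0)
    cand_del <- logical(0)
    for (g in genes) {
      if (g %in% deleted_genes) {
        cand_mult <- c(cand_mult, 0); cand_gene <- c(cand_gene, g)
        cand_fc <- c(cand_fc, NA_real_); cand_del <- c(cand_del, TRUE)
      } else if (g %in% de_table$gene) {
        fc <- de_table$log2FC[match(g, de_table$gene)]
        cand_mult <- c(cand_mult, 2^fc); cand_gene <- c(cand_gene, g)
        cand_fc <- c(cand_fc, fc); cand_del <- c(cand_del, FALSE)
      }
    }
    if (!length(cand_mult)) {
      unmapped <- c(unmapped, enz)
      next
    }
    k <- which.min(cand_mult)
    mult[enz] <- cand_mult[k]
    rows[[enz]] <- data.frame(enzyme = enz, gene = cand_gene[k],
                              log2FC = cand_fc[k], multiplier = cand_mult[k],
                              deleted = cand_del[k], stringsAsFactors = FALSE)
  }
  structure(list(multipliers = mult, delta = delta,
                 contrast = attr(de_table, "contrast"),
                 table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 unmapped = unmapped),
            class = "perturbation_set")
}

# An uptake exchange's secretion counterpart: the exchange reaction whose
# stoichiometry is exactly the negation of the uptake's. Needed to score
# net consumption (gross uptake minus re-secretion), which futile
# import/export cycling cannot inflate.
secretion_counterpart <- function(model, uptake_id) {
  st <- model$reactions[[uptake_id]]$stoichiometry
  for (r in model$reactions) {
    if (r$id == uptake_id || r$kind != "exchange") next
    if (length(r$stoichiometry) == length(st) &&
        setequal(names(r$stoichiometry), names(st)) &&
        all(abs(r$stoichiometry[names(st)] + st) < 1e-12))
      return(r$id)
  }
  NULL
}

# usage bounds implied by a perturbation set, given one sampled background
perturbed_usage_bounds <- function(lp, pset, sample_values) {
  idx <- match(paste0("usage_", names(pset$multipliers)), lp$rxn_ids)
  if (anyNA(idx))
    stop("sample lacks usage reactions for: ",
         paste(names(pset$multipliers)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  list(idx = idx,
       ub = sample_values[lp$rxn_ids[idx]] * pset$multipliers * (1 + pset$delta))
}

#' Growth screen over perturbed enzyme-usage bounds
#'
#' For each sampled reference-strain flux distribution, caps each perturbed
#' enzyme's usage at `usage_in_sample * multiplier * (1 + delta)` and
#' maximizes growth on the given carbon source. Infeasible backgrounds are
#' flagged and excluded from downstream means. For feasible backgrounds,
#' growth is then fixed to the achieved maximum with a +/-`growth_fix_delta`
#' flexibilization, and carbon-source consumption and NGAM are maximized —
#' lexicographically by default (consumption first, then NGAM), or as an
#' equal-weight sum with `objective_mode = "weighted"`.
#'
#' @param model the unconstrained enzyme-constrained model.
#' @param samples list of `flux_distribution`s from
#'   [sample_flux_distributions()].
#' @param pset a [build_perturbation_set()] result.
#' @param carbon_source sole carbon source (default `"ethanol"`).
#' @param growth_fix_delta flexibilization when fixing growth at its
#'   maximum (default 0.05).
#' @param objective_mode `"lexicographic"` (default) or `"weighted"`.
#' @return data.frame with one row per sample: `sample`, `feasible`,
#'   `mu_max` (h^-1), `carbon_uptake` (net consumption: uptake minus any
#'   paired secretion, so futile import/export cycling does not count),
#'   `ngam`.
#' @export
perturbed_growth_screen <- function(model, samples, pset,
                                    carbon_source = "ethanol",
                                    growth_fix_delta = 0.05,
                                    objective_mode = c("lexicographic", "weighted")) {
  objective_mode <- match.arg(objective_mode)
  base <- constrain_to_carbon_source(model, carbon_source, NULL, 0)
  lp <- model_lp(base)
  bio <- match(model$biomass_id, lp$rxn_ids)
  uptake_id <- model$carbon_exchange_ids[[carbon_source]]
  carb <- match(uptake_id, lp$rxn_ids)
  ngam <- match(model$ngam_id, lp$rxn_ids)
  obj_bio <- numeric(length(lp$rxn_ids)); obj_bio[bio] <- 1
  obj_carb <- numeric(length(lp$rxn_ids)); obj_carb[carb] <- 1
  secr <- secretion_counterpart(base, uptake_id)
  if (!is.null(secr)) obj_carb[match(secr, lp$rxn_ids)] <- -1
  obj_ngam <- numeric(length(lp$rxn_ids)); obj_ngam[ngam] <- 1
  out <- data.frame(sample = seq_along(samples), feasible = FALSE,
                    mu_max = NA_real_, carbon_uptake = NA_real_,
                    ngam = NA_real_)
  for (s in seq_along(samples)) {
    pb <- perturbed_usage_bounds(lp, pset, samples[[s]]$values)
    ub2 <- lp$ub
    ub2[pb$idx] <- pb$ub
    g <- solve_lp(obj_bio, lp$S, lp$lb, ub2, "max")
    if (g$status != "optimal") next
    mu <- g$value
    lb2 <- lp$lb; ub3 <- ub2
    lb2[bio] <- max(0, mu * (1 - growth_fix_delta))
    ub3[bio] <- mu * (1 + growth_fix_delta)
    if (objective_mode == "lexicographic") {
      s1 <- solve_lp(obj_carb, lp$S, lb2, ub3, "max")
      extra <- list(list(a = obj_carb, dir = ">=",
                         rhs = s1$value - 1e-6 * max(1, abs(s1$value))))
      s2 <- solve_lp(obj_ngam, lp$S, lb2, ub3, "max", extra = extra)
      uptake <- s1$value
      ng <- s2$value
    } else {
      sw <- solve_lp(obj_carb + obj_ngam, lp$S, lb2, ub3, "max")
      uptake <- sum(obj_carb * sw$x)
      ng <- sw$x[ngam]
    }
    out$feasible[s] <- TRUE
    out$mu_max[s] <- mu
    out$carbon_uptake[s] <- uptake
    out$ngam[s] <- ng
  }
  attr(out, "delta") <- pset$delta
  attr(out, "objective_mode") <- objective_mode
  out
}
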