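# Canonical "ecmodel-v1" JSON serialization. Keys are sorted, arrays of
# objects are sorted by id, and floats are rendered with 12 significant
# digits, so save(load(f)) is byte-identical to the canonical
# re-serialization of f.

fmt_num <- function(x) {
  # 12 significant digits, no scientific notation surprises across platforms
  vapply(x, function(v) {
    if (!is.finite(v)) "null"
    else if (v == floor(v) && abs(v) < 1e15) sprintf("%.1f", v)
    else formatC(v, digits = 12, format = "g")
  }, character(1))
}

json_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub('"', '\\\\"', s)
  s
}

to_json_canonical <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  pad2 <- strrep(" ", indent + 2)
  if (is.null(x)) return("null")
  if (is.list(x) && !is.null(names(x)) && length(x) == 0) return("{}")
  if (is.list(x) && !is.null(names(x)) && length(x) > 0) {
    keys <- sort(names(x))
    items <- vapply(keys, function(k)
      sprintf('%s"%s": %s', pad2, json_escape(k),
              to_json_canonical(x[[k]], indent + 2)), character(1))
    return(paste0("{\n", paste(items, collapse = ",\n"), "\n", pad, "}"))
  }
  if (is.list(x)) {
    if (length(x) == 0) return("[]")
    items <- vapply(x, function(el)
      paste0(pad2, to_json_canonical(el, indent + 2)), character(1))
    return(paste0("[\n", paste(items, collapse = ",\n"), "\n", pad, "]"))
  }
  if (is.character(x)) {
    if (length(x) == 1) return(sprintf('"%s"', json_escape(x)))
    return(paste0("[", paste(sprintf('"%s"', json_escape(x)), collapse = ", "), "]"))
  }
  if (is.numeric(x)) {
    if (length(x) == 1) return(fmt_num(x))
    return(paste0("[", paste(fmt_num(x), collapse = ", "), "]"))
  }
  if (is.logical(x)) return(if (x) "true" else "false")
  stop("cannot serialize object of class ", class(x)[1], call. = FALSE)
}

model_to_canonical_list <- function(model) {
  named_map <- function(v) {
    if (length(v) == 0) return(structure(list(), names = character()))
    as.list(v)[order(names(v))]
  }
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i)
    list(id = model$metabolites$id[i],
         name = model$metabolites$name[i],
         compartment = model$metabolites$compartment[i]))
  mets <- mets[order(vapply(mets, `[[`, character(1), "id"))]
  enzs <- if (is.null(model$enzymes)) list() else
    lapply(seq_len(nrow(model$enzymes)), function(i)
      list(id = model$enzymes$id[i],
           mw = model$enzymes$mw[i],
           genes = as.list(model$enzymes$genes[[i]])))
  if (length(enzs)) enzs <- enzs[order(vapply(enzs, `[[`, character(1), "id"))]
  rxns <- lapply(model$reactions, function(r) {
    ez <- lapply(r$enzymes, function(e)
      list(id = e$id, kcat = e$kcat, kcat_unit = "per_hour"))
    list(id = r$id,
         stoichiometry = named_map(r$stoichiometry),
         lower_bound = r$lower_bound,
         upper_bound = r$upper_bound,
         kind = r$kind,
         enzymes = ez)
  })
  rxns <- rxns[order(vapply(rxns, `[[`, character(1), "id"))]
  list(schema = "ecmodel-v1",
       pool_bound = model$pool_bound,
       metabolites = mets,
       enzymes = enzs,
       reactions = unname(rxns),
       biomass_id = if (is.na(model$biomass_id)) NULL else model$biomass_id,
       ngam_id = if (is.na(model$ngam_id)) NULL else model$ngam_id,
       carbon_exchange_ids = named_map(model$carbon_exchange_ids))
}

#' Serialize a model to canonical ecmodel-v1 JSON
#'
#' @param model an `ec_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_ecmodel()]
#' @export
save_ecmodel <- function(model, path) {
  txt <- to_json_canonical(model_to_canonical_list(model))
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

req_key <- function(obj, key, where) {
  if (is.null(obj[[key]]))
    stop(sprintf("malformed model JSON: missing key '%s' in %s", key, where),
         call. = FALSE)
  obj[[key]]
}

#' Load a model from ecmodel-v1 JSON
#'
#' Reads the canonical JSON schema (see [save_ecmodel()]), converting kcats
#' declared with `"kcat_unit": "per_second"` to h^-1 (x3600). A file
#' without an `"enzymes"` table is loaded as a plain stoichiometric model.
#' All model invariants are validated after parsing.
#'
#' @param path path to a model JSON file.
#' @return an `ec_model`.
#' @export
load_ecmodel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed model JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  mets <- do.call(rbind, lapply(raw$metabolites, function(m)
    data.frame(id = req_key(m, "id", "metabolite"),
               name = if (is.null(m$name)) "" else m$name,
               compartment = if (is.null(m$compartment)) "" else m$compartment,
               stringsAsFactors = FALSE)))
  if (is.null(mets)) mets <- data.frame(id = character(), name = character(),
                                        compartment = character())
  enzs <- NULL
  if (length(raw$enzymes)) {
    enzs <- data.frame(
      id = vapply(raw$enzymes, function(e) req_key(e, "id", "enzyme"), character(1)),
      mw = vapply(raw$enzymes, function(e) as.numeric(req_key(e, "mw", "enzyme")),
                  numeric(1)),
      stringsAsFactors = FALSE)
    enzs$genes <- lapply(raw$enzymes, function(e)
      as.character(unlist(e$genes %||% list())))
  }
  rxns <- lapply(raw$reactions, function(r) {
    id <- req_key(r, "id", "reaction")
    st <- unlist(r$stoichiometry %||% list())
    st <- if (is.null(st)) numeric() else st
    ez <- NULL
    if (length(r$enzymes)) {
      ez <- lapply(r$enzymes, function(e) {
        kc <- as.numeric(req_key(e, "kcat", paste("reaction", id)))
        unit <- e$kcat_unit %||% "per_hour"
        if (!unit %in% c("per_hour", "per_second"))
          stop(sprintf("malformed model JSON: reaction %s: unknown kcat_unit '%s'",
                       id, unit), call. = FALSE)
        if (unit == "per_second") kc <- kc * 3600
        list(id = req_key(e, "id", paste("reaction", id)), kcat = kc)
      })
    }
    reaction(id, st,
             as.numeric(req_key(r, "lower_bound", paste("reaction", id))),
             as.numeric(req_key(r, "upper_bound", paste("reaction", id))),
             r$kind %||% "metabolic", ez)
  })
  ec_model(metabolites = mets, reactions = rxns, enzymes = enzs,
           pool_bound = as.numeric(raw$pool_bound %||% 0.1),
           biomass_id = raw$biomass_id %||% NA_character_,
           ngam_id = raw$ngam_id %||% NA_character_,
           carbon_exchange_ids = unlist(raw$carbon_exchange_ids %||%
                                          structure(list(), names = character())) %||%
             character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
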