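# Small shared helpers: deterministic plain-text table output and
# stage-keyed seed derivation.

# Deterministic TSV writer: fixed number formatting so identical inputs
# give byte-identical files across runs.
write_tsv_plain <- function(d, path) {
  fmt <- function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      out <- formatC(col, digits = 10, format = "g")
      out[is.na(col)] <- "NA"
      out
    } else as.character(col)
  }
  d2 <- as.data.frame(lapply(d, fmt), stringsAsFactors = FALSE,
                      check.names = FALSE)
  names(d2) <- names(d)
  utils::write.table(d2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# One master seed governs all stochastic stages; each stage draws from a
# documented fixed offset so stages can be re-run independently. Offsets
# stay below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(model = 101L, de = 202L, counts = 303L, curves = 404L,
               sampling = 505L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.numeric(seed) * 1000 + offsets[[stage]]) %% 2147483647)
}
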