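# Independent oracles for the LP engine: exhaustive vertex enumeration of
# the flux polytope {v : S v = 0, lb <= v <= ub} (all bounds finite).
# Every vertex is a basic solution: n - rank(S) variables sit at a bound,
# the rest solve the reduced equality system. Usable up to ~8 reactions.

independent_rows <- function(S) {
  qrt <- qr(t(S))
  sort(qrt$pivot[seq_len(qrt$rank)])
}

enumerate_vertices <- function(S, lb, ub, tol = 1e-8) {
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  n <- ncol(S)
  S <- S[independent_rows(S), , drop = FALSE]
  r <- nrow(S)
  verts <- list()
  basis_sets <- if (r == 0) list(integer(0)) else utils::combn(n, r, simplify = FALSE)
  for (B in basis_sets) {
    Fr <- setdiff(seq_len(n), B)
    SB <- S[, B, drop = FALSE]
    if (r > 0 && abs(det(SB)) < 1e-10) next
    k <- length(Fr)
    for (mask in 0:(2^k - 1)) {
      at_upper <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
      v <- numeric(n)
      v[Fr] <- ifelse(at_upper, ub[Fr], lb[Fr])
      if (r > 0) {
        rhs <- -if (k) as.vector(S[, Fr, drop = FALSE] %*% v[Fr]) else rep(0, r)
        v[B] <- solve(SB, rhs)
      }
      if (all(v >= lb - tol) && all(v <= ub + tol))
        verts[[length(verts) + 1]] <- pmin(pmax(v, lb), ub)
    }
  }
  verts
}

# Maximum of obj'v over the polytope by brute force; also returns the
# maximizing vertices (needed for lexicographic oracles).
vertex_enum_optimum <- function(S, lb, ub, obj, sense = "max", tol = 1e-8) {
  verts <- enumerate_vertices(S, lb, ub, tol)
  if (!length(verts)) return(list(value = NA_real_, vertices = list()))
  vals <- vapply(verts, function(v) sum(obj * v), numeric(1))
  opt <- if (sense == "max") max(vals) else min(vals)
  list(value = opt,
       vertices = verts[abs(vals - opt) <= tol * (1 + abs(opt))])
}

# Sequential (lexicographic) brute force: optimize objectives in order,
# keeping only the vertices that attain each stage's optimum.
vertex_enum_lexicographic <- function(S, lb, ub, objectives, tol = 1e-8) {
  verts <- enumerate_vertices(S, lb, ub, tol)
  optima <- numeric(0)
  for (ob in objectives) {
    sense <- if (is.null(ob$sense)) "max" else ob$sense
    vals <- vapply(verts, function(v) sum(ob$obj * v), numeric(1))
    opt <- if (sense == "max") max(vals) else min(vals)
    optima <- c(optima, opt)
    verts <- verts[abs(vals - opt) <= tol * (1 + abs(opt))]
  }
  list(optima = optima, vertices = verts)
}

model_lp_parts <- function(model) ecscreen:::model_lp(model)

# Exact hypergeometric upper tail by direct combinatorial summation
# (independent of stats::phyper).
hyper_tail_exact <- function(overlap, term_size, universe_size, query_size) {
  ks <- overlap:min(term_size, query_size)
  sum(vapply(ks, function(k)
    choose(term_size, k) * choose(universe_size - term_size, query_size - k),
    numeric(1))) / choose(universe_size, query_size)
}
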