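# Dense bounded-variable revised simplex. Written for the moderate problem
# sizes of lumped metabolic models (tens of rows/columns): a textbook
# two-phase method with Bland's rule (deterministic, anti-cycling) and
# fresh factorizations every iteration (no update drift). Solves
#   min/max c'x  s.t.  A x = b,  l <= x <= u
# with finite l, u possibly infinite. Status: optimal / infeasible /
# unbounded.

simplex_core <- function(cvec, A, b, l, u, basis, status, tol = 1e-9,
                         max_iter = NULL) {
  m <- nrow(A)
  N <- ncol(A)
  if (is.null(max_iter)) max_iter <- 100L * (N + m) + 1000L
  rtol <- 1e-11
  for (it in seq_len(max_iter)) {
    AB <- A[, basis, drop = FALSE]
    xN <- ifelse(status == "U", u, l)
    nonb <- which(status != "B")
    rhs <- b - if (length(nonb)) as.vector(A[, nonb, drop = FALSE] %*% xN[nonb]) else 0
    xB <- tryCatch(solve(AB, rhs), error = function(e) NULL)
    if (is.null(xB)) stop("LP solver: singular basis", call. = FALSE)
    y <- solve(t(AB), cvec[basis])
    d <- cvec - as.vector(crossprod(A, y))
    d[basis] <- 0
    movable <- u > l
    enter_lo <- status == "L" & d < -tol & movable
    enter_hi <- status == "U" & d > tol & movable
    cand <- which(enter_lo | enter_hi)
    if (!length(cand)) {
      x <- xN
      x[basis] <- xB
      return(list(status = "optimal", x = x, basis = basis,
                  var_status = status))
    }
    j <- cand[1]                      # Bland: smallest index enters
    sgn <- if (status[j] == "L") 1 else -1
    w <- solve(AB, A[, j])
    delta <- -sgn * w                 # change of xB per unit step of x_j
    tvec <- rep(Inf, m)
    dn <- delta < -rtol
    up <- delta > rtol
    tvec[dn] <- (xB[dn] - l[basis[dn]]) / (-delta[dn])
    tvec[up] <- (u[basis[up]] - xB[up]) / delta[up]
    tvec[tvec < 0] <- 0               # degenerate guards
    t_span <- u[j] - l[j]
    t_max <- min(tvec, t_span)
    if (!is.finite(t_max))
      return(list(status = "unbounded", x = NULL))
    if (t_span <= t_max + rtol * (1 + abs(t_max))) {
      status[j] <- if (status[j] == "L") "U" else "L"   # bound flip
      next
    }
    elig <- which(tvec <= t_max + rtol * (1 + abs(t_max)))
    r <- elig[which.min(basis[elig])] # Bland: smallest index leaves
    leave <- basis[r]
    status[leave] <- if (delta[r] < 0) "L" else "U"
    status[j] <- "B"
    basis[r] <- j
  }
  stop("LP solver: iteration limit reached", call. = FALSE)
}

simplex_bounded <- function(cvec, A, b, l, u, sense = "max", tol = 1e-9) {
  stopifnot(sense %in% c("max", "min"))
  if (any(!is.finite(l)))
    stop("all lower bounds must be finite", call. = FALSE)
  obj <- if (sense == "max") -cvec else cvec
  m <- nrow(A)
  N <- ncol(A)
  # phase 1: artificials cover the residual at the all-lower-bound point
  r0 <- b - as.vector(A %*% l)
  s <- ifelse(r0 >= 0, 1, -1)
  A1 <- cbind(A, diag(s, m))
  l1 <- c(l, rep(0, m))
  u1 <- c(u, rep(Inf, m))
  c1 <- c(rep(0, N), rep(1, m))
  basis <- N + seq_len(m)
  status <- c(rep("L", N), rep("B", m))
  p1 <- simplex_core(c1, A1, b, l1, u1, basis, status, tol)
  if (p1$status != "optimal")
    stop("LP solver: phase 1 did not terminate optimally", call. = FALSE)
  resid <- sum(p1$x[N + seq_len(m)])
  if (resid > 1e-7 * (1 + max(abs(b))))
    return(list(x = NULL, value = NA_real_, status = "infeasible"))
  # freeze artificials at zero and optimize the true objective
  u1[N + seq_len(m)] <- 0
  st <- p1$var_status
  st[N + seq_len(m)][st[N + seq_len(m)] == "U"] <- "L"
  c2 <- c(obj, rep(0, m))
  p2 <- simplex_core(c2, A1, b, l1, u1, p1$basis, st, tol)
  if (p2$status == "unbounded")
    return(list(x = NULL, value = NA_real_, status = "unbounded"))
  x <- p2$x[seq_len(N)]
  val <- sum(cvec * x)
  list(x = x, value = val, status = "optimal")
}
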