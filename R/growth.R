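# Growth-curve metrics: exponential-phase doubling time by nonlinear fit,
# lag phase as the time to reach a threshold OD600, final OD by
# interpolation, and percent changes between strains/conditions.

#' Construct a growth curve
#'
#' @param time sampling times in minutes, strictly increasing, >= 5 points.
#' @param od OD600 readings, non-negative.
#' @param label free-text label.
#' @return a `growth_curve` list.
#' @export
growth_curve <- function(time, od, label = "") {
  if (length(time) < 5) stop("growth curve needs >= 5 points", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (length(od) != length(time)) stop("time and od lengths differ", call. = FALSE)
  if (any(od < 0)) stop("OD readings must be non-negative", call. = FALSE)
  structure(list(time = as.numeric(time), od = as.numeric(od),
                 label = as.character(label)), class = "growth_curve")
}

#' Read a growth curve from CSV
#' @param path CSV with header `time_min,od600`.
#' @param label curve label (default: file name).
#' @return a [growth_curve()].
#' @export
read_growth_curve <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  if (!all(c("time_min", "od600") %in% names(d)))
    stop("growth curve CSV needs columns time_min, od600", call. = FALSE)
  growth_curve(d$time_min, d$od600, label)
}

#' Write a growth curve to CSV
#' @param curve a [growth_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_growth_curve <- function(curve, path) {
  d <- data.frame(time_min = curve$time,
                  od600 = formatC(curve$od, digits = 10, format = "g"))
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# O(1) windowed log-linear regression from prefix sums.
loglin_prefix <- function(t, y) {
  list(ct = c(0, cumsum(t)), ct2 = c(0, cumsum(t^2)),
       cy = c(0, cumsum(y)), cy2 = c(0, cumsum(y^2)),
       cty = c(0, cumsum(t * y)))
}

loglin_window <- function(pre, i, j) {
  n <- j - i + 1
  st <- pre$ct[j + 1] - pre$ct[i]
  st2 <- pre$ct2[j + 1] - pre$ct2[i]
  sy <- pre$cy[j + 1] - pre$cy[i]
  sy2 <- pre$cy2[j + 1] - pre$cy2[i]
  sty <- pre$cty[j + 1] - pre$cty[i]
  sxx <- st2 - st^2 / n
  sxy <- sty - st * sy / n
  syy <- sy2 - sy^2 / n
  slope <- sxy / sxx
  r2 <- if (syy > 1e-300) sxy^2 / (sxx * syy) else 1
  c(slope = slope, r2 = r2)
}

#' Doubling time from the exponential phase of a growth curve
#'
#' The exponential window is the contiguous run of at least `min_points`
#' samples with OD between `od_min` and `od_max_frac` times the curve
#' maximum that maximizes the fitted growth rate, subject to a log-linear
#' R^2 of at least `r2_threshold`. A nonlinear least-squares fit of
#' `OD = A * exp(mu * t)` over that window then gives `Td = ln(2) / mu`.
#'
#' @param curve a [growth_curve()] (time in minutes).
#' @param od_min lower OD bound of the candidate window (default 0.15).
#' @param od_max_frac upper OD bound as a fraction of the curve maximum
#'   (default 0.5).
#' @param min_points minimal window length (default 5).
#' @param r2_threshold log-linear R^2 gate (default 0.995).
#' @return a `growth_metrics` list: `doubling_time` (min), `growth_rate`
#'   (per min), `window` (start and end indices), `r2` (nonlinear fit R^2).
#' @export
fit_doubling_time <- function(curve, od_min = 0.15, od_max_frac = 0.5,
                              min_points = 5, r2_threshold = 0.995) {
  eligible <- curve$od >= od_min & curve$od <= od_max_frac * max(curve$od) &
    curve$od > 0
  if (sum(eligible) < min_points)
    stop(sprintf("no exponential phase detected: only %d point(s) with OD in [%g, %g]",
                 sum(eligible), od_min, od_max_frac * max(curve$od)),
         call. = FALSE)
  y <- log(pmax(curve$od, .Machine$double.xmin))
  runs <- rle(eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  pre <- loglin_prefix(curve$time, y)
  best <- NULL
  best_r2_seen <- -Inf
  # Within each eligible contiguous run, keep the longest sub-window that
  # passes the R^2 gate (higher slope breaks length ties); across runs
  # (competing growth phases) take the one with the maximal fitted rate.
  # Fitting the longest log-linear stretch avoids the upward rate bias
  # that picking the steepest short sub-window would incur under noise.
  for (r in which(runs$values & runs$lengths >= min_points)) {
    run_best <- NULL
    len <- ends[r] - starts[r] + 1
    for (L in seq(len, min_points)) {
      for (i in starts[r]:(ends[r] - L + 1)) {
        j <- i + L - 1
        st <- loglin_window(pre, i, j)
        best_r2_seen <- max(best_r2_seen, st["r2"])
        if (st["r2"] >= r2_threshold && st["slope"] > 0 &&
            (is.null(run_best) || st["slope"] > run_best$slope))
          run_best <- list(i = i, j = j, slope = st["slope"])
      }
      if (!is.null(run_best)) break
    }
    if (!is.null(run_best) &&
        (is.null(best) || run_best$slope > best$slope))
      best <- run_best
  }
  if (is.null(best))
    stop(sprintf("no exponential phase detected: best log-linear R^2 %.4f below gate %.4f",
                 max(best_r2_seen, 0), r2_threshold), call. = FALSE)
  tt <- curve$time[best$i:best$j]
  oo <- curve$od[best$i:best$j]
  a0 <- exp(mean(log(oo) - best$slope * tt))
  # Gauss-Newton stalls on zero-residual (noiseless) windows; warnOnly +
  # suppressWarnings keeps the (then exact) estimates.
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(oo ~ A * exp(mu * tt), start = list(A = a0, mu = best$slope),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    mu <- as.numeric(best$slope)
    pred <- a0 * exp(mu * tt)
  } else {
    mu <- stats::coef(fit)[["mu"]]
    pred <- stats::fitted(fit)
  }
  r2 <- 1 - sum((oo - pred)^2) / sum((oo - mean(oo))^2)
  structure(list(doubling_time = log(2) / mu, growth_rate = mu,
                 window = c(best$i, best$j), r2 = r2,
                 label = curve$label),
            class = "growth_metrics")
}

#' @export
print.growth_metrics <- function(x, ...) {
  cat(sprintf("growth_metrics: Td %.2f min (window %d..%d, R^2 %.5f)\n",
              x$doubling_time, x$window[1], x$window[2], x$r2))
  invisible(x)
}

#' Lag phase: time to reach a threshold OD
#'
#' Defined as the time between inoculation (around `od_start`) and the
#' culture first reaching `od_threshold` — with the defaults, the first
#' ~1.32 doublings from OD600 0.1 to 0.25. The crossing time is found by
#' linear interpolation between adjacent samples.
#'
#' @param curve a [growth_curve()].
#' @param od_start inoculation OD (default 0.1; informational).
#' @param od_threshold threshold OD (default 0.25).
#' @return lag duration in minutes.
#' @export
lag_phase <- function(curve, od_start = 0.1, od_threshold = 0.25) {
  if (curve$od[1] >= od_threshold) return(0)
  above <- which(curve$od >= od_threshold)
  if (!length(above))
    stop(sprintf("threshold OD %g never reached (max OD %g)",
                 od_threshold, max(curve$od)), call. = FALSE)
  k <- above[1]
  t0 <- curve$time[k - 1]; t1 <- curve$time[k]
  y0 <- curve$od[k - 1]; y1 <- curve$od[k]
  t0 + (od_threshold - y0) / (y1 - y0) * (t1 - t0)
}

#' Final OD at a given time
#'
#' Linear interpolation of the curve at `at_minutes`; queries beyond the
#' recorded range return the nearest endpoint with a warning.
#'
#' @param curve a [growth_curve()].
#' @param at_minutes query time in minutes.
#' @return OD600 at the requested time.
#' @export
final_od <- function(curve, at_minutes) {
  if (at_minutes < min(curve$time) || at_minutes > max(curve$time)) {
    warning("query time ", at_minutes, " outside curve range; using nearest endpoint")
    return(if (at_minutes < min(curve$time)) curve$od[1]
           else curve$od[length(curve$od)])
  }
  stats::approx(curve$time, curve$od, xout = at_minutes)$y
}

#' Percent change of a test value relative to a reference
#'
#' @param reference reference value (> 0).
#' @param test test value.
#' @param round_to_int round the result to the nearest integer percent.
#' @return `100 * (test - reference) / reference`.
#' @export
percent_change <- function(reference, test, round_to_int = FALSE) {
  if (reference <= 0) stop("reference must be > 0", call. = FALSE)
  pc <- 100 * (test - reference) / reference
  if (round_to_int) round(pc) else pc
}
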