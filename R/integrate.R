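# Quintic (degree-5) interpolating spline through (x, y) and its exact
# integral over [min(x), max(x)]. Uses an order-6 B-spline basis with
# averaged interior knots (Schoenberg-Whitney admissible), solves the
# collocation system, and integrates the basis in closed form:
# int B_{i,k} = (t_{i+k} - t_i) / k over the full support.
.quintic_integral <- function(x, y) {
  n <- length(x)
  k <- 6L
  if (n < k) stop("need at least 6 samples for a degree-5 spline, got ", n)
  if (any(diff(x) <= 0)) stop("sample times must be strictly increasing")
  interior <- if (n > k)
    vapply(seq_len(n - k), function(j) mean(x[(j + 1):(j + k - 1)]), 0)
  else numeric()
  knots <- c(rep(x[1], k), interior, rep(x[n], k))
  B <- splines::splineDesign(knots, x, ord = k)
  coef <- solve(B, y)
  sum(coef * (knots[seq_len(n) + k] - knots[seq_len(n)]) / k)
}

#' Integrate injection peaks of a power trace
#'
#' Splits the trace into per-injection windows `[t_i, t_{i+1})` (the last
#' window extends to the end of the trace), fits an interpolating quintic
#' spline to the samples of each window, integrates it exactly over the
#' sampled span, and normalizes by the moles of ligand injected
#' (`c_L * V_i`) to yield heats in kcal/mol.
#'
#' Optionally a linear baseline through the mean power of the first and
#' last 5% of samples of each window is subtracted first
#' (`baseline = "edges"`); the default is no baseline correction, which
#' keeps the integration exact for synthetic traces with known integrals.
#'
#' @param trace a [power_trace()].
#' @param schedule the matching [titration_schedule()]; the number of
#'   injection times must equal `schedule$T_inj`.
#' @param baseline `"none"` (default) or `"edges"`.
#' @return A [heat_series()] of length `schedule$T_inj`.
#' @export
#' @examples
#' ex <- cona_example(2)
#' spec <- simulation_spec(ex$schedule, ex$wiseman, trace_shape = "rectangular")
#' h <- simulate_heats(spec)
#' tr <- simulate_power_trace(spec, h)
#' max(abs(integrate_peaks(tr, ex$schedule)$q - h$q))  # ~ 0
integrate_peaks <- function(trace, schedule, baseline = c("none", "edges")) {
  stopifnot(inherits(trace, "power_trace"), inherits(schedule, "titration_schedule"))
  baseline <- match.arg(baseline)
  tinj <- trace$injection_times
  if (length(tinj) != schedule$T_inj)
    stop("trace has ", length(tinj), " injections but schedule declares ",
         schedule$T_inj)
  ends <- c(tinj[-1L], max(trace$time) + .Machine$double.eps)
  q <- numeric(length(tinj))
  for (i in seq_along(tinj)) {
    last <- i == length(tinj)
    sel <- trace$time >= tinj[i] &
      (if (last) trace$time <= max(trace$time) else trace$time < ends[i])
    tt <- trace$time[sel]; pp <- trace$power[sel]
    if (length(tt) < 6L)
      stop("injection window ", i, " has ", length(tt),
           " samples; at least 6 are needed for degree-5 spline integration")
    if (baseline == "edges") {
      m <- max(1L, ceiling(0.05 * length(tt)))
      t1 <- mean(tt[seq_len(m)]); p1 <- mean(pp[seq_len(m)])
      t2 <- mean(tt[(length(tt) - m + 1L):length(tt)])
      p2 <- mean(pp[(length(tt) - m + 1L):length(tt)])
      pp <- pp - (p1 + (tt - t1) * (p2 - p1) / (t2 - t1))
    }
    ucal <- .quintic_integral(tt, pp)
    umol <- schedule$c_L * schedule$injection_volumes[i]
    q[i] <- ucal / umol / .CAL_PER_KCAL
  }
  heat_series(q)
}
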