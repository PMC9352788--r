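#' Specification of a synthetic ITC experiment
#'
#' Pairs a titration schedule with ground-truth binding parameters and
#' noise/trace settings for the forward simulators.
#'
#' @param schedule a [titration_schedule()].
#' @param truth a [wiseman_params()] (constant `K_a`) or [qc_params()]
#'   (concentration-dependent `K_i` from the coarse-grained rate model).
#' @param noise_width half-width of the multiplicative uniform noise
#'   applied to each heat (0 = noise-free).
#' @param trace_shape shape of the simulated power peaks: `"none"`,
#'   `"rectangular"` (constant power across the window, exactly
#'   integrable) or `"exponential"` (decay with time constant `tau`).
#' @param tau decay time constant (s) for exponential peaks.
#' @param seed RNG seed for the noise draws.
#' @param mode free-ligand iteration mode for [qc_params()] truths.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(schedule, truth, noise_width = 0,
                            trace_shape = c("none", "rectangular", "exponential"),
                            tau = 15, seed = 1L, mode = "cumulative") {
  stopifnot(inherits(schedule, "titration_schedule"), noise_width >= 0,
            tau > 0)
  if (!inherits(truth, "wiseman_params") && !inherits(truth, "qc_params"))
    stop("'truth' must be wiseman_params or qc_params")
  structure(list(schedule = schedule, truth = truth,
                 noise_width = noise_width,
                 trace_shape = match.arg(trace_shape), tau = tau,
                 seed = as.integer(seed), mode = mode),
            class = "simulation_spec")
}

#' Simulate integrated heats
#'
#' Evaluates the forward model `q_i = W(K, n; l_i, m_i) * dH` on the
#' schedule's concentration series -- with constant `K = K_a` for a
#' Wiseman truth, or per-injection `K_i` from coarse graining the rate
#' model along the free-ligand series for a Q_c truth -- and applies
#' multiplicative uniform noise of the configured width.
#'
#' @param spec a [simulation_spec()].
#' @return A [heat_series()].
#' @export
#' @examples
#' ex <- cona_example(2)
#' simulate_heats(simulation_spec(ex$schedule, ex$qc))$q
simulate_heats <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  conc <- total_concentrations(spec$schedule)
  tr <- spec$truth
  K <- if (inherits(tr, "wiseman_params")) rep(tr$K_a, nrow(conc))
  else suppressWarnings(
    free_ligand_series(tr$rates, tr$n, conc, mode = spec$mode))$K
  W <- vapply(seq_len(nrow(conc)), function(i)
    wiseman_function(K[i], tr$n, conc$l[i], conc$m[i]), 0)
  q <- W * tr$dH
  if (spec$noise_width > 0)
    q <- q * .with_seed(spec$seed,
      stats::runif(length(q), 1 - spec$noise_width, 1 + spec$noise_width))
  heat_series(q)
}

#' Simulate a deconvolved power trace with known integrals
#'
#' Emits a sampled power trace whose per-window integral over the
#' sampled span reproduces the given heats exactly (rectangular shape:
#' constant power across each window) or in closed form (exponential
#' shape: `A_i * exp(-(t - t_i)/tau)` with `A_i` chosen so the sampled
#' span carries the window's heat). Windows are `window_s` seconds long,
#' sampled every `dt_s` seconds, with injection i starting at
#' `(i - 1) * window_s`.
#'
#' @param spec a [simulation_spec()] with `trace_shape` set.
#' @param heats the [heat_series()] to encode (typically from
#'   [simulate_heats()]).
#' @param window_s injection window length (s).
#' @param dt_s sampling interval (s); `window_s / dt_s` must be at least
#'   6 samples.
#' @return A [power_trace()].
#' @export
#' @examples
#' ex <- cona_example(2)
#' spec <- simulation_spec(ex$schedule, ex$wiseman, trace_shape = "exponential")
#' h <- simulate_heats(spec)
#' tr <- simulate_power_trace(spec, h)
#' range(integrate_peaks(tr, ex$schedule)$q - h$q)
simulate_power_trace <- function(spec, heats, window_s = 120, dt_s = 1) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(heats, "heat_series"))
  if (spec$trace_shape == "none")
    stop("'trace_shape' is \"none\"; choose rectangular or exponential")
  sch <- spec$schedule
  T_inj <- sch$T_inj
  if (length(heats$q) != T_inj) stop("heats length does not match schedule")
  n_per <- floor(window_s / dt_s)
  if (n_per < 6L) stop("need at least 6 samples per window")
  time <- seq(0, by = dt_s, length.out = n_per * T_inj)
  power <- numeric(length(time))
  tinj <- (seq_len(T_inj) - 1) * window_s
  span <- (n_per - 1L) * dt_s          # sampled span of each window
  for (i in seq_len(T_inj)) {
    idx <- ((i - 1L) * n_per + 1L):(i * n_per)
    E <- heats$q[i] * sch$c_L * sch$injection_volumes[i] * .CAL_PER_KCAL  # ucal
    tt <- time[idx] - tinj[i]
    power[idx] <- if (spec$trace_shape == "rectangular") E / span
    else E / (spec$tau * (1 - exp(-span / spec$tau))) * exp(-tt / spec$tau)
  }
  power_trace(time, power, tinj)
}
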