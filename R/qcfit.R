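#' Parameters of the concentration-dependent (Q_c) binding model
#'
#' @param rates a [micro_rates()].
#' @param n stoichiometry, positive.
#' @param dH heat of binding (kcal/mol), finite.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(rates, n, dH) {
  stopifnot(inherits(rates, "micro_rates"))
  if (!is.finite(n) || n <= 0) stop("'n' must be positive and finite")
  if (!is.finite(dH)) stop("'dH' must be finite")
  structure(list(rates = rates, n = n, dH = dH), class = "qc_params")
}

#' @export
print.qc_params <- function(x, ...) {
  cat(sprintf("Q_c parameters: n = %.4f, dH = %.4f kcal/mol\n", x$n, x$dH))
  print(x$rates)
  invisible(x)
}

#' Gaussian residual weighting on the molar-ratio axis
#'
#' Specification of the weighting used when the binding signal is
#' concentrated in a narrow slope of the isotherm: residuals are
#' multiplied by an unnormalized Gaussian kernel
#' `exp(-(r - mu)^2 / (2 sigma^2))` in the molar ratio `r`, and listed
#' injections get weight zero.
#'
#' @param enabled logical; if `FALSE` the weights are all ones (excluded
#'   injections still get zero).
#' @param mu kernel mean on the molar-ratio axis.
#' @param sigma kernel standard deviation, positive.
#' @param excluded injection indices forced to weight zero.
#' @return An object of class `weight_spec`.
#' @export
weight_spec <- function(enabled = TRUE, mu = 0.3, sigma = 0.1758,
                        excluded = integer()) {
  if (enabled && (!is.finite(sigma) || sigma <= 0))
    stop("'sigma' must be positive when weighting is enabled")
  structure(list(enabled = isTRUE(enabled), mu = mu, sigma = sigma,
                 excluded = sort(unique(as.integer(excluded)))),
            class = "weight_spec")
}

#' @rdname weight_spec
#' @param molar_ratio numeric vector of molar ratios `l/m`.
#' @param spec a [weight_spec()].
#' @return `gaussian_weights()`: numeric weights, one per injection.
#' @export
#' @examples
#' gaussian_weights(c(0.1, 0.3, 0.4758), weight_spec())
gaussian_weights <- function(molar_ratio, spec) {
  stopifnot(inherits(spec, "weight_spec"))
  w <- if (spec$enabled)
    exp(-(molar_ratio - spec$mu)^2 / (2 * spec$sigma^2))
  else rep(1, length(molar_ratio))
  w[spec$excluded[spec$excluded <= length(w)]] <- 0
  w
}

.resolve_weights <- function(weights, conc) {
  if (is.null(weights)) rep(1, nrow(conc))
  else if (inherits(weights, "weight_spec"))
    gaussian_weights(conc$molar_ratio, weights)
  else as.numeric(weights)
}

#' Residual norm of the Q_c model
#'
#' Forward model: the free-ligand series is computed with
#' [free_ligand_series()], the per-injection association constants `K_i`
#' by [association_constants()], and the modelled heat of injection i is
#' `W(K_i, n; l_i, m_i) * dH`. The returned value is the Euclidean norm
#' of the (optionally Gaussian-weighted) residual against the measured
#' heats, over the non-excluded injections.
#'
#' @param params a [qc_params()].
#' @param heats a [heat_series()].
#' @param conc matching [total_concentrations()].
#' @param weights `NULL` (all ones), a [weight_spec()], or a numeric
#'   vector.
#' @param mode free-ligand iteration mode, see [free_ligand_series()].
#' @return Residual norm (kcal/mol).
#' @export
qc_objective <- function(params, heats, conc, weights = NULL,
                         mode = "cumulative") {
  stopifnot(inherits(params, "qc_params"), inherits(heats, "heat_series"))
  if (length(heats$q) != nrow(conc))
    stop("heats and concentration series lengths differ")
  w <- .resolve_weights(weights, conc)
  use <- setdiff(seq_len(nrow(conc)), heats$excluded)
  lig <- suppressWarnings(
    free_ligand_series(params$rates, params$n, conc, mode = mode))
  model <- .qc_model_heats(params, conc, lig)
  sqrt(sum((w[use] * (heats$q[use] - model[use]))^2))
}

# model heats W(K_i, n; l_i, m_i) * dH for a precomputed ligand series
.qc_model_heats <- function(params, conc, lig) {
  W <- vapply(seq_len(nrow(conc)), function(i)
    wiseman_function(lig$K[i], params$n, conc$l[i], conc$m[i]), 0)
  W * params$dH
}

#' Random-search configuration for [fit_qc()]
#'
#' @param seed RNG seed for the candidate draws.
#' @param rate_bounds lower/upper bounds of the log-uniform proposal for
#'   every microscopic rate.
#' @param max_draws maximum number of candidate draws.
#' @param break_norm stop the search as soon as a candidate's objective
#'   drops below this value (typically the Wiseman fit's norm); `NULL`
#'   means exhaust `max_draws` and keep the best.
#' @return An object of class `search_config`.
#' @export
search_config <- function(seed = 1L, rate_bounds = c(1e-2, 1e4),
                          max_draws = 200L, break_norm = NULL) {
  stopifnot(length(rate_bounds) == 2L, rate_bounds[1] > 0,
            rate_bounds[2] > rate_bounds[1], max_draws >= 1L)
  structure(list(seed = as.integer(seed), rate_bounds = rate_bounds,
                 max_draws = as.integer(max_draws), break_norm = break_norm),
            class = "search_config")
}

# run code with a local, restored RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit the concentration-dependent (Q_c) model
#'
#' Random-search estimation of the microscopic rates with Nelder-Mead
#' refinement of `(n, dH)`. Candidate microscopic rates are drawn
#' log-uniformly within `search$rate_bounds`, the stoichiometry uniformly
#' on (0.05, 2); for each candidate `dH` is set to its weighted
#' least-squares value given the modelled isotherm (or to `init_dH` if
#' the model column is degenerate). The search stops at the first
#' candidate whose objective beats `search$break_norm` (by default the
#' supplied `wiseman_norm`), or after `max_draws` draws, keeping the best
#' candidate seen. The best candidate is then refined by Nelder-Mead over
#' `(n, dH)` with the rates held fixed (`refine = "ndh"`, the default);
#' `refine = "full"` additionally polishes all parameters and
#' `refine = "none"` skips refinement. Identical seeds and inputs give
#' identical results.
#'
#' Only ratios of the microscopic rates are identifiable: the objective
#' is invariant under joint rescaling of all rates (the macroscopic
#' `K_a` and hence the model heats are unchanged), so fitted rates are
#' relative quantities.
#'
#' @param heats a [heat_series()].
#' @param conc matching [total_concentrations()].
#' @param s valency of the model (ignored if `init_rates` given).
#' @param weights `NULL`, a [weight_spec()] or a numeric vector.
#' @param search a [search_config()].
#' @param wiseman_norm residual norm of a prior [fit_wiseman()] on the
#'   same data; used as the default break threshold.
#' @param init_dH starting heat of binding, typically the Wiseman fit's
#'   `dH`; used when the analytic update is unavailable.
#' @param init_rates optional [micro_rates()] evaluated as the first
#'   candidate (before any random draw).
#' @param refine `"ndh"`, `"full"` or `"none"`.
#' @param mode free-ligand iteration mode, see [free_ligand_series()].
#' @return An object of class `c("qc_fit", "mvitc_fit")`: list with
#'   `params` ([qc_params()]), `norm`, `n_evals`, `draws`, `converged`
#'   (`TRUE` if the break threshold was beaten), `K_series`
#'   (per-injection association constants at the fit) and `micro_K`
#'   (fitted `k_on[j]/k_off[j]` ratios).
#' @export
#' @examples
#' ex <- cona_example(2)
#' conc <- total_concentrations(ex$schedule)
#' h <- simulate_heats(simulation_spec(ex$schedule, ex$qc))
#' wf <- fit_wiseman(h, conc)
#' fit_qc(h, conc, s = 2, search = search_config(seed = 1, max_draws = 50),
#'        wiseman_norm = wf$norm, init_dH = wf$params$dH)
fit_qc <- function(heats, conc, s = 2L, weights = NULL,
                   search = search_config(), wiseman_norm = NULL,
                   init_dH = NULL, init_rates = NULL,
                   refine = c("ndh", "full", "none"), mode = "cumulative") {
  stopifnot(inherits(heats, "heat_series"), inherits(search, "search_config"))
  refine <- match.arg(refine)
  if (!is.null(init_rates)) {
    stopifnot(inherits(init_rates, "micro_rates"))
    s <- init_rates$s
  }
  s <- as.integer(s)
  w <- .resolve_weights(weights, conc)
  use <- setdiff(seq_len(nrow(conc)), heats$excluded)
  break_norm <- if (!is.null(search$break_norm)) search$break_norm
                else if (!is.null(wiseman_norm)) wiseman_norm else Inf
  if (is.null(init_dH)) init_dH <- heats$q[use][1L]

  n_evals <- 0L
  evaluate <- function(rates, n) {
    # analytic least-squares dH given the modelled isotherm
    lig <- suppressWarnings(free_ligand_series(rates, n, conc, mode = mode))
    Wcol <- vapply(seq_len(nrow(conc)), function(i)
      wiseman_function(lig$K[i], n, conc$l[i], conc$m[i]), 0)
    num <- sum((w[use] * Wcol[use]) * (w[use] * heats$q[use]))
    den <- sum((w[use] * Wcol[use])^2)
    dH <- if (den > 0) num / den else init_dH
    n_evals <<- n_evals + 1L
    norm <- sqrt(sum((w[use] * (heats$q[use] - Wcol[use] * dH))^2))
    list(params = qc_params(rates, n, dH), norm = norm)
  }

  lb <- log(search$rate_bounds[1L]); ub <- log(search$rate_bounds[2L])
  best <- NULL; draws <- 0L; converged <- FALSE
  .with_seed(search$seed, {
    if (!is.null(init_rates)) {
      best <- evaluate(init_rates, stats::runif(1, 0.05, 2))
      draws <- 1L
      if (best$norm < break_norm) converged <- TRUE
    }
    while (!converged && draws < search$max_draws) {
      rates <- micro_rates(exp(stats::runif(s, lb, ub)),
                           exp(stats::runif(s, lb, ub)))
      n_cand <- stats::runif(1, 0.05, 2)
      cand <- tryCatch(evaluate(rates, n_cand), error = function(e) NULL)
      draws <- draws + 1L
      if (!is.null(cand) && (is.null(best) || cand$norm < best$norm)) best <- cand
      if (!is.null(best) && best$norm < break_norm) converged <- TRUE
    }
  })
  if (is.null(best)) stop("no admissible candidate found in the random search")

  if (refine != "none") {
    p0 <- best$params
    obj_ndh <- function(par) {
      n_evals <<- n_evals + 1L
      tryCatch({
        p <- qc_params(p0$rates, exp(par[1L]), par[2L])
        qc_objective(p, heats, conc, weights = w, mode = mode)
      }, error = function(e) Inf)
    }
    o <- stats::optim(c(log(p0$n), p0$dH), obj_ndh, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
    if (o$value <= best$norm)
      best <- list(params = qc_params(p0$rates, exp(o$par[1L]), o$par[2L]),
                   norm = o$value)
    if (refine == "full") {
      p0 <- best$params
      obj_full <- function(par) {
        n_evals <<- n_evals + 1L
        tryCatch({
          rr <- micro_rates(exp(par[1:s]), exp(par[(s + 1):(2 * s)]))
          p <- qc_params(rr, exp(par[2 * s + 1L]), par[2 * s + 2L])
          qc_objective(p, heats, conc, weights = w, mode = mode)
        }, error = function(e) Inf)
      }
      par0 <- c(log(p0$rates$k_on), log(p0$rates$k_off), log(p0$n), p0$dH)
      o2 <- stats::optim(par0, obj_full, method = "Nelder-Mead",
                         control = list(reltol = 1e-10, maxit = 5000))
      if (o2$value <= best$norm) {
        rr <- micro_rates(exp(o2$par[1:s]), exp(o2$par[(s + 1):(2 * s)]))
        best <- list(params = qc_params(rr, exp(o2$par[2 * s + 1L]),
                                        o2$par[2 * s + 2L]),
                     norm = o2$value)
      }
    }
  }

  lig <- suppressWarnings(
    free_ligand_series(best$params$rates, best$params$n, conc, mode = mode))
  structure(list(params = best$params, norm = best$norm, n_evals = n_evals,
                 draws = draws, converged = converged, K_series = lig$K,
                 micro_K = micro_association_constants(best$params$rates)),
            class = c("qc_fit", "mvitc_fit"))
}
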