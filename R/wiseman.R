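#' Wiseman fit parameters
#'
#' The three parameters of the classical 1:1 binding isotherm: association
#' constant `K_a` (l/mmol, the reciprocal of the concentration unit used
#' for `l` and `m`), stoichiometry `n` and heat of binding `dH`
#' (kcal/mol).
#'
#' @param K_a association constant, positive.
#' @param n number of binding sites per macromolecule, positive.
#' @param dH heat of binding (kcal/mol), finite.
#' @return An object of class `wiseman_params`.
#' @export
wiseman_params <- function(K_a, n, dH) {
  stopifnot(is.numeric(K_a), is.numeric(n), is.numeric(dH))
  if (!is.finite(K_a) || K_a <= 0) stop("'K_a' must be positive and finite")
  if (!is.finite(n) || n <= 0) stop("'n' must be positive and finite")
  if (!is.finite(dH)) stop("'dH' must be finite")
  structure(list(K_a = K_a, n = n, dH = dH), class = "wiseman_params")
}

#' @export
print.wiseman_params <- function(x, ...) {
  cat(sprintf("Wiseman parameters: K_a = %.4f, n = %.4f, dH = %.4f kcal/mol\n",
              x$K_a, x$n, x$dH))
  invisible(x)
}

#' The Wiseman binding isotherm
#'
#' Fraction of injected ligand that binds at total ligand concentration
#' `l` and total macromolecule concentration `m`, for 1:1 binding with
#' `n` sites of association constant `K_a`:
#' \deqn{W = \frac{1}{2}\left(1 + \frac{n - l/m - 1/(m K_a)}
#'   {\sqrt{(n + l/m + 1/(m K_a))^2 - 4 n l/m}}\right).}
#' The value lies in \[0, 1\]; it tends to 1 at a saturating start
#' (`l = 0` with strong binding) and to 0 at full saturation
#' (`l/m` large). Rescaling `l` and `m` by a common factor `c` and `K_a`
#' by `1/c` leaves `W` unchanged (only the unit of `K_a` changes).
#'
#' @param K_a association constant (reciprocal concentration unit).
#' @param n stoichiometry.
#' @param l,m total ligand and macromolecule concentrations (same unit);
#'   vectorized over `l` and `m`.
#' @return The bound fraction(s), in \[0, 1\].
#' @export
#' @examples
#' wiseman_function(100, 1, l = 0.05, m = 0.07)
wiseman_function <- function(K_a, n, l, m) {
  stopifnot(K_a > 0, n > 0, all(m > 0), all(l >= 0))
  r <- l / m
  c0 <- 1 / (m * K_a)
  disc <- (n + r + c0)^2 - 4 * n * r
  if (any(disc <= 0))
    stop("non-positive discriminant in the Wiseman function (K_a finite ",
         "should prevent this); check inputs")
  0.5 * (1 + (n - r - c0) / sqrt(disc))
}

#' Residual norm of the Wiseman model
#'
#' Euclidean (Frobenius) norm of the weighted residual between measured
#' heats and the model `W(K_a, n; l, m) * dH`, taken over the injections
#' not excluded in `heats`.
#'
#' @param params a [wiseman_params()].
#' @param heats a [heat_series()].
#' @param conc a [total_concentrations()] series of matching length.
#' @param weights optional numeric weights per injection (default all
#'   ones); excluded injections are dropped regardless.
#' @return The residual norm (kcal/mol).
#' @export
wiseman_objective <- function(params, heats, conc, weights = NULL) {
  stopifnot(inherits(params, "wiseman_params"), inherits(heats, "heat_series"))
  if (length(heats$q) != nrow(conc))
    stop("heats and concentration series lengths differ")
  w <- if (is.null(weights)) rep(1, nrow(conc)) else as.numeric(weights)
  use <- setdiff(seq_len(nrow(conc)), heats$excluded)
  W <- wiseman_function(params$K_a, params$n, conc$l[use], conc$m[use])
  sqrt(sum((w[use] * (heats$q[use] - W * params$dH))^2))
}

# Default Nelder-Mead start: K_a from the macromolecule concentration at
# the injection whose heat is closest to half the first usable heat
# (midpoint heuristic), n from the molar ratio there, dH from the first
# usable heat.
.wiseman_init <- function(heats, conc) {
  use <- setdiff(seq_len(nrow(conc)), heats$excluded)
  q <- heats$q[use]
  mid <- use[which.min(abs(abs(q) - abs(q[1]) / 2))]
  K0 <- 1 / conc$m[mid]
  n0 <- max(conc$molar_ratio[mid], 1e-3)
  wiseman_params(K_a = K0, n = n0, dH = if (q[1] != 0) q[1] else -1)
}

#' Fit the classical Wiseman isotherm
#'
#' Nelder-Mead minimization of [wiseman_objective()] over
#' `(K_a, n, dH)`. `K_a` and `n` are optimized on the log scale to
#' enforce positivity; the simplex is restarted once from its own
#' solution to tighten convergence. Deterministic for a given start.
#'
#' @param heats a [heat_series()] with at least 4 usable injections.
#' @param conc matching [total_concentrations()].
#' @param init optional [wiseman_params()] starting point; by default a
#'   midpoint heuristic is used.
#' @param weights optional per-injection weights (see
#'   [gaussian_weights()]).
#' @param control passed to [stats::optim()]; defaults to
#'   `reltol = 1e-12`, `maxit = 1e5`.
#' @return An object of class `c("wiseman_fit", "mvitc_fit")`: a list
#'   with `params` ([wiseman_params()]), `norm`, `n_evals`, `converged`
#'   and `residuals`.
#' @export
#' @examples
#' ex <- cona_example(2)
#' conc <- total_concentrations(ex$schedule)
#' h <- simulate_heats(simulation_spec(ex$schedule, ex$wiseman))
#' fit_wiseman(h, conc)
fit_wiseman <- function(heats, conc, init = NULL, weights = NULL,
                        control = list()) {
  stopifnot(inherits(heats, "heat_series"))
  use <- setdiff(seq_len(nrow(conc)), heats$excluded)
  if (length(use) < 4L)
    stop("need at least 4 usable injections to fit 3 parameters")
  if (is.null(init)) init <- .wiseman_init(heats, conc)
  stopifnot(inherits(init, "wiseman_params"))
  ctrl <- utils::modifyList(list(reltol = 1e-12, maxit = 1e5), control)
  obj <- function(par) {
    p <- wiseman_params(exp(par[1]), exp(par[2]), par[3])
    wiseman_objective(p, heats, conc, weights)
  }
  par0 <- c(log(init$K_a), log(init$n), init$dH)
  o1 <- stats::optim(par0, obj, method = "Nelder-Mead", control = ctrl)
  o2 <- stats::optim(o1$par, obj, method = "Nelder-Mead", control = ctrl)
  best <- if (o2$value <= o1$value) o2 else o1
  params <- wiseman_params(exp(best$par[1]), exp(best$par[2]), best$par[3])
  W <- wiseman_function(params$K_a, params$n, conc$l, conc$m)
  structure(list(params = params, norm = best$value,
                 n_evals = o1$counts[["function"]] + o2$counts[["function"]],
                 converged = best$convergence == 0L,
                 residuals = heats$q - W * params$dH,
                 fitted = W * params$dH),
            class = c("wiseman_fit", "mvitc_fit"))
}

#' @export
print.mvitc_fit <- function(x, ...) {
  cat("mvitc fit (", class(x)[1], ")\n", sep = "")
  print(x$params)
  cat(sprintf("residual norm %.6g after %d objective evaluations%s\n",
              x$norm, x$n_evals,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Thermodynamic state from an association constant
#'
#' Computes the Gibbs free energy and entropy of binding from
#' \eqn{\Delta G^\circ = -R T \ln K_a = \Delta H^\circ - T \Delta S^\circ}.
#'
#' @param K_a association constant (must be dimensionless-consistent with
#'   the concentration unit used in fitting).
#' @param dH heat of binding (kcal/mol).
#' @param T_kelvin absolute temperature (K).
#' @param R gas constant (kcal/(mol K)); defaults to [R_KCAL].
#' @return An object of class `thermo_state`: list with `dG` (kcal/mol),
#'   `dS` (kcal/(mol K)), `T_kelvin`, `R`.
#' @export
#' @examples
#' thermo_from_Ka(93.3295, dH = -132.3069)
thermo_from_Ka <- function(K_a, dH, T_kelvin = 298.15, R = R_KCAL) {
  stopifnot(K_a > 0, T_kelvin > 0, R > 0)
  dG <- -R * T_kelvin * log(K_a)
  structure(list(dG = dG, dS = (dH - dG) / T_kelvin,
                 T_kelvin = T_kelvin, R = R),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("dG = %.4f kcal/mol, dS = %.6f kcal/(mol K) at T = %g K\n",
              x$dG, x$dS, x$T_kelvin))
  invisible(x)
}
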