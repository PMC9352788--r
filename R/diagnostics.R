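#' Timescale-separation diagnostics along a titration
#'
#' For each injection, builds the microscopic rate matrix at the
#' free-ligand concentration from [free_ligand_series()], computes its
#' eigenvalues sorted by magnitude of the real part ascending (the first
#' is always ~0), and reports the consecutive magnitude ratios
#' `ratio_2state = |lambda_3| / |lambda_2|` (adequacy of a one-step,
#' two-macrostate projection; values well above 1 indicate a clear gap)
#' and `ratio_3state = |lambda_4| / |lambda_3|` (adequacy of a two-step
#' binding description). For s = 1 the chain has a single nonzero
#' eigenvalue and the ratios are reported as `Inf`.
#'
#' @param rates a [micro_rates()].
#' @param n stoichiometry used in the free-ligand recursion.
#' @param conc a [total_concentrations()] series.
#' @param mode free-ligand iteration mode, see [free_ligand_series()].
#' @return A data frame of class `spectral_diagnostics` with columns
#'   `injection`, `L_free`, `lambda2`, `lambda3`, `lambda4`,
#'   `ratio_2state`, `ratio_3state`.
#' @export
#' @examples
#' ex <- cona_example(2)
#' d <- eigenvalue_ratio_series(ex$qc$rates, ex$qc$n,
#'                              total_concentrations(ex$schedule))
#' d$ratio_2state[c(1, 14)]
eigenvalue_ratio_series <- function(rates, n, conc, mode = "cumulative") {
  stopifnot(inherits(rates, "micro_rates"))
  lig <- suppressWarnings(free_ligand_series(rates, n, conc, mode = mode))
  rows <- lapply(seq_len(nrow(lig)), function(i) {
    Q <- build_rate_matrix(rates, lig$L_free[i])
    ev <- eigen(Q$QT, only.values = TRUE)$values
    if (max(abs(Im(ev))) > 1e-8 * max(abs(Re(ev)), 1))
      warning("significant imaginary eigenvalue parts at injection ", i,
              "; sorting by magnitude")
    lam <- abs(Re(ev))[order(abs(Re(ev)))]
    if (lam[1L] > 1e-8 * max(lam, 1))
      warning("no near-zero eigenvalue at injection ", i)
    g <- function(k) if (length(lam) >= k) lam[k] else NA_real_
    r23 <- if (length(lam) >= 3L) lam[3L] / lam[2L] else Inf
    r34 <- if (length(lam) >= 4L) lam[4L] / lam[3L] else Inf
    data.frame(injection = i, L_free = lig$L_free[i], lambda2 = -g(2L),
               lambda3 = -g(3L), lambda4 = -g(4L),
               ratio_2state = r23, ratio_3state = r34)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("spectral_diagnostics", "data.frame")
  out
}

#' Multiplicative perturbation of measured heats
#'
#' Multiplies every heat by an independent uniform draw from
#' `[1 - width, 1 + width]`, reproducibly for a given seed. Used by
#' [perturbation_study()] to probe the robustness of the fits against
#' measurement error of the stated relative size.
#'
#' @param heats a [heat_series()].
#' @param width half-width of the multiplicative band (e.g. `0.01` for
#'   up-to-1% perturbations).
#' @param seed RNG seed.
#' @return A [heat_series()] with the same exclusions.
#' @export
perturb_heats <- function(heats, width = 0.01, seed = 1L) {
  stopifnot(inherits(heats, "heat_series"), width >= 0)
  x <- .with_seed(seed, stats::runif(length(heats$q), 1 - width, 1 + width))
  heat_series(heats$q * x, excluded = heats$excluded)
}

#' Robustness of the fits under input perturbation
#'
#' Refits both the Wiseman and the Q_c model on heats perturbed by
#' [perturb_heats()] and reports the percentage change of each fitted
#' parameter and of the residual norm relative to the unperturbed fits.
#' A stable model shows small changes in `n` and `dH`; the microscopic
#' association constants can move substantially when the timescale
#' separation is poor.
#'
#' @param heats a [heat_series()].
#' @param conc matching [total_concentrations()].
#' @param s valency of the Q_c model.
#' @param weights `NULL`, a [weight_spec()] or numeric weights.
#' @param search a [search_config()] (the same seed is used for both the
#'   unperturbed and the perturbed Q_c search, so differences reflect the
#'   data perturbation only).
#' @param width,seed perturbation size and seed, see [perturb_heats()].
#' @param mode free-ligand iteration mode.
#' @return An object of class `perturbation_report`: list with
#'   `multipliers`, and data frames `wiseman` and `qc` with columns
#'   `param`, `base`, `perturbed`, `delta_pct`.
#' @export
perturbation_study <- function(heats, conc, s = 2L, weights = NULL,
                               search = search_config(), width = 0.01,
                               seed = 1L, mode = "cumulative") {
  q2 <- perturb_heats(heats, width, seed)
  mult <- q2$q / heats$q
  w0 <- fit_wiseman(heats, conc, weights = .resolve_weights(weights, conc))
  w1 <- fit_wiseman(q2, conc, weights = .resolve_weights(weights, conc))
  q0 <- fit_qc(heats, conc, s = s, weights = weights, search = search,
               wiseman_norm = w0$norm, init_dH = w0$params$dH, mode = mode)
  q1 <- fit_qc(q2, conc, s = s, weights = weights, search = search,
               wiseman_norm = w1$norm, init_dH = w1$params$dH, mode = mode)
  pct <- function(a, b) ifelse(a == 0, ifelse(b == 0, 0, Inf), 100 * (b - a) / a)
  wtab <- data.frame(
    param = c("K_a", "n", "dH", "norm"),
    base = c(w0$params$K_a, w0$params$n, w0$params$dH, w0$norm),
    perturbed = c(w1$params$K_a, w1$params$n, w1$params$dH, w1$norm))
  wtab$delta_pct <- pct(wtab$base, wtab$perturbed)
  qtab <- data.frame(
    param = c(paste0("K_", seq_len(s)), "n", "dH", "norm"),
    base = c(q0$micro_K, q0$params$n, q0$params$dH, q0$norm),
    perturbed = c(q1$micro_K, q1$params$n, q1$params$dH, q1$norm))
  qtab$delta_pct <- pct(qtab$base, qtab$perturbed)
  structure(list(multipliers = mult, width = width, wiseman = wtab, qc = qtab),
            class = "perturbation_report")
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat(sprintf("Perturbation study (up to %.3g%% multiplicative noise)\n",
              100 * x$width))
  cat("Wiseman fit:\n"); print(x$wiseman, row.names = FALSE, digits = 5)
  cat("Q_c fit:\n"); print(x$qc, row.names = FALSE, digits = 5)
  invisible(x)
}
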