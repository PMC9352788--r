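#' Stationary distribution of a rate matrix
#'
#' Solves `Q^T pi = 0` with `sum(pi) = 1` by a least-squares solve of the
#' stacked system. The chain must be irreducible, which for the binding
#' chain requires `L_free > 0`.
#'
#' @param Q a [build_rate_matrix()] result or a square transposed
#'   generator matrix.
#' @return Stationary probability vector `pi` (positive, sums to 1).
#' @export
#' @examples
#' Q <- build_rate_matrix(micro_rates(2, 1), L_free = 0.5)
#' stationary_distribution(Q)  # 2-state chain: (k_off, k_on * L) / sum
stationary_distribution <- function(Q) {
  QT <- .as_QT(Q)
  if (inherits(Q, "rate_matrix") && Q$L_free == 0)
    stop("chain is reducible at [L] = 0 (unbound state has no outflow); ",
         "the stationary distribution is not unique")
  n <- nrow(QT)
  A <- rbind(QT, rep(1, n))
  pi <- qr.solve(A, c(rep(0, n), 1))
  if (any(pi <= 0) || max(abs(QT %*% pi)) > 1e-8 * max(abs(QT)))
    stop("failed to find a positive stationary distribution; ",
         "is the chain irreducible?")
  pi / sum(pi)
}

# eigen-decomposition of the row-convention generator Q = t(QT), with
# eigenvalues sorted by |Re| ascending; complex parts below tolerance are
# discarded, larger ones are an error (warning + magnitude sort if only
# the ordering is affected).
.generator_eigen <- function(QT) {
  e <- eigen(t(QT))
  scale <- max(abs(Re(e$values)), 1)
  if (max(abs(Im(e$values))) > 1e-8 * scale)
    stop("rate matrix has eigenvalues with significant imaginary part; ",
         "cannot coarse grain reliably")
  vals <- Re(e$values)
  vecs <- Re(e$vectors)
  ord <- order(abs(vals))
  list(values = vals[ord], vectors = vecs[, ord, drop = FALSE])
}

#' PCCA+ fuzzy memberships for a two-state (bound/unbound) projection
#'
#' Computes right eigenvectors of the generator (the matrix acting on
#' observables, i.e. `t(Q^T)`), sorts eigenvalues by magnitude, and
#' applies the inner simplex algorithm to the invariant subspace spanned
#' by the stationary eigenvector and one slow eigenvector: the two
#' maximally separated entries of the slow eigenvector are taken as
#' simplex vertices and every state is expressed in barycentric
#' coordinates between them, giving memberships in \[0, 1\] whose rows
#' sum to 1.
#'
#' Site-permutation symmetry of the binding chain produces slow
#' eigenvectors that are antisymmetric among equivalent configurations
#' and have exactly zero weight on the unbound state; these modes carry
#' no bound/unbound kinetics. The slow eigenvector used is therefore the
#' one of smallest eigenvalue magnitude with non-vanishing weight on the
#' unbound state (for chains without such symmetry this is simply the
#' slowest relaxation).
#'
#' @param Q a [build_rate_matrix()] result or square transposed
#'   generator.
#' @param unbound index of the unbound micro state (1 for matrices built
#'   by [build_rate_matrix()]).
#' @return An object of class `memberships`: list with `chi` (n x 2,
#'   columns `"unbound"`, `"bound"`), `eigenvalues` (sorted by
#'   magnitude) and `selected` (index into the sorted eigenvalues of the
#'   slow mode used).
#' @export
pcca_memberships <- function(Q, unbound = 1L) {
  QT <- .as_QT(Q)
  n <- nrow(QT)
  if (n < 2L) stop("need at least 2 micro states")
  eg <- .generator_eigen(QT)
  isa_chi <- function(v) {
    i <- which.max(v); j <- which.min(v)
    if (v[i] == v[j]) return(NULL)
    chi1 <- (v - v[j]) / (v[i] - v[j])
    cbind(chi1, 1 - chi1)
  }
  sel <- NA_integer_; chi <- NULL
  for (k in 2:n) {
    v <- eg$vectors[, k]
    cand <- isa_chi(v)
    if (is.null(cand)) next
    # a usable slow mode either moves the unbound state directly or (for
    # degenerate spectra) clusters it crisply; antisymmetric
    # site-permutation modes have zero unbound weight and leave the
    # unbound state half-assigned, carrying no bound/unbound kinetics
    if (abs(v[unbound]) > 1e-8 * max(abs(v)) ||
        max(cand[unbound, ]) > 0.999) {
      sel <- k; chi <- cand; break
    }
  }
  if (is.na(sel))
    stop("no slow eigenvector exchanges probability with the unbound state")
  if (sel < n) {
    gap <- abs(abs(eg$values[sel]) - abs(eg$values[sel + 1L]))
    if (gap < 1e-12 * max(abs(eg$values)))
      warning("degenerate spectral gap at the selected slow mode; ",
              "the 2-state projection may be ill-determined")
  }
  chi[chi < 0] <- 0                      # guard against rounding
  chi <- chi / rowSums(chi)
  if (chi[unbound, 2L] > chi[unbound, 1L]) chi <- chi[, 2:1]
  colnames(chi) <- c("unbound", "bound")
  structure(list(chi = chi, eigenvalues = eg$values, selected = sel),
            class = "memberships")
}

#' Coarse grain a rate matrix to the two-state macro model
#'
#' Projects the generator onto the membership functions:
#' `Q_c = (chi^T Pi chi)^{-1} chi^T Pi Q chi` with `Pi = diag(pi)` and
#' `Q` the generator acting on observables; the returned `Qc_T` is its
#' transpose, matching the two-state template
#' \deqn{Q_c^T = \begin{pmatrix} -k_{on}[L] & k_{off} \\
#'   k_{on}[L] & -k_{off} \end{pmatrix},}
#' from which the macroscopic rates and `K_a = k_on/k_off` are read off.
#'
#' @param Q a [build_rate_matrix()] result, or square transposed
#'   generator (then `L_free` must be given).
#' @param chi a [pcca_memberships()] object or its `chi` matrix.
#' @param pi stationary distribution; computed from `Q` if omitted.
#' @param L_free free-ligand concentration used to split `k_on * [L]`
#'   into a rate constant; defaults to `Q$L_free`.
#' @return An object of class `coarse_grained`: list with `Qc_T` (2 x 2),
#'   `pi`, `chi`, `k_on_macro`, `k_off_macro`, `K_a_macro`, `L_free`.
#' @export
#' @examples
#' Q <- build_rate_matrix(cona_example(2)$qc$rates, L_free = 0.01)
#' coarse_grain(Q)$K_a_macro
coarse_grain <- function(Q, chi = NULL, pi = NULL, L_free = NULL) {
  QT <- .as_QT(Q)
  if (is.null(L_free)) {
    if (!inherits(Q, "rate_matrix"))
      stop("'L_free' must be supplied for a plain matrix")
    L_free <- Q$L_free
  }
  if (L_free <= 0) stop("coarse graining requires [L] > 0")
  if (is.null(chi)) chi <- pcca_memberships(Q)
  if (inherits(chi, "memberships")) chi <- chi$chi
  stopifnot(is.matrix(chi), nrow(chi) == nrow(QT), ncol(chi) == 2L)
  if (is.null(pi)) pi <- stationary_distribution(Q)
  M <- crossprod(chi, pi * chi)
  if (abs(det(M)) < 1e-14 * max(abs(M))^2)
    stop("collapsed clustering: chi^T Pi chi is singular")
  Qc <- solve(M, crossprod(chi, pi * (t(QT) %*% chi)))
  Qc_T <- t(Qc)
  k_on <- Qc_T[2L, 1L] / L_free
  k_off <- Qc_T[1L, 2L]
  if (k_on <= 0 || k_off <= 0)
    stop("coarse-grained off-diagonal rates are not positive; ",
         "the 2-state projection failed")
  dimnames(Qc_T) <- list(c("unbound", "bound"), c("unbound", "bound"))
  structure(list(Qc_T = Qc_T, pi = pi, chi = chi,
                 k_on_macro = k_on, k_off_macro = k_off,
                 K_a_macro = k_on / k_off, L_free = L_free),
            class = "coarse_grained")
}

#' @export
print.coarse_grained <- function(x, ...) {
  cat(sprintf(
    "Coarse-grained 2-state model at [L] = %g: k_on = %.4g, k_off = %.4g, K_a = %.4g\n",
    x$L_free, x$k_on_macro, x$k_off_macro, x$K_a_macro))
  invisible(x)
}

#' Per-injection macroscopic association constants
#'
#' For each free-ligand concentration, builds the microscopic rate
#' matrix, coarse grains it, and returns the macroscopic association
#' constant `K_i`. For s = 1 there are no intermediate states and every
#' `K_i` equals `k_on[1] / k_off[1]`.
#'
#' @param rates a [micro_rates()].
#' @param L_series positive free-ligand concentrations (mmol/l).
#' @return Numeric vector of association constants, one per entry of
#'   `L_series`.
#' @export
#' @examples
#' association_constants(cona_example(2)$qc$rates, c(0.001, 0.01, 0.1))
association_constants <- function(rates, L_series) {
  stopifnot(inherits(rates, "micro_rates"), all(L_series > 0))
  vapply(L_series, function(L)
    coarse_grain(build_rate_matrix(rates, L))$K_a_macro, 0)
}
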