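#' Microscopic binding rates
#'
#' On/off rates for each consecutive microscopic binding step of an
#' s-valent ligand-receptor pair: `k_on[1]`/`k_off[1]` for the first
#' bond, `k_on[j]`/`k_off[j]` for the j-th bond given j-1 existing bonds.
#' The rates are relative (the analysis only identifies their ratios, not
#' physical units); `k_on[1]` additionally carries a reciprocal
#' concentration so that `k_on[1] * [L]` is a rate.
#'
#' @param k_on,k_off positive numeric vectors of equal length s (1 to 4).
#' @return An object of class `micro_rates`.
#' @export
#' @examples
#' micro_rates(k_on = c(136.4185, 33.4088), k_off = c(2.3716, 18.5925))
micro_rates <- function(k_on, k_off) {
  stopifnot(is.numeric(k_on), is.numeric(k_off))
  if (length(k_on) != length(k_off))
    stop("'k_on' and 'k_off' must have the same length (the valency s)")
  s <- length(k_on)
  if (s < 1L || s > 4L) stop("valency s must be between 1 and 4")
  if (any(!is.finite(c(k_on, k_off))) || any(c(k_on, k_off) <= 0))
    stop("all rates must be positive and finite")
  structure(list(s = s, k_on = as.numeric(k_on), k_off = as.numeric(k_off)),
            class = "micro_rates")
}

#' @export
print.micro_rates <- function(x, ...) {
  cat("Microscopic rates, valency s =", x$s, "\n")
  for (j in seq_len(x$s))
    cat(sprintf("  step %d: k_on = %.4f, k_off = %.4f (K_%d = %.4f)\n",
                j, x$k_on[j], x$k_off[j], j, x$k_on[j] / x$k_off[j]))
  invisible(x)
}

#' Microscopic association constants
#'
#' The per-step association constants `K_j = k_on[j] / k_off[j]`.
#'
#' @param rates a [micro_rates()].
#' @return Numeric vector of length s.
#' @export
micro_association_constants <- function(rates) {
  stopifnot(inherits(rates, "micro_rates"))
  rates$k_on / rates$k_off
}

# canonical key of a bond set (rows sorted by ligand site)
.state_key <- function(bonds) {
  if (nrow(bonds) == 0L) return("")
  ord <- order(bonds[, 1L])
  paste(bonds[ord, 1L], bonds[ord, 2L], sep = "-", collapse = ";")
}

#' Enumerate the binding state space of an s-valent pair
#'
#' States are all partial matchings between the s ligand sites and the s
#' receptor sites: each state is a set of (ligand site, receptor site)
#' bonds in which no site is used twice. There are
#' `choose(s, b)^2 * factorial(b)` states with `b` bonds, e.g. 7 states
#' for s = 2 (1 unbound, 4 singly bound, 2 doubly bound) and 34 for
#' s = 3. States are ordered by bond count, then lexicographically, so
#' the fully unbound state is always first.
#'
#' @param s valency, 1 to 4.
#' @return An object of class `binding_state_space`: list with `states`
#'   (each a 2-column matrix of bonds), `n_states`, `bonds` (bond count
#'   per state) and `s`.
#' @export
#' @examples
#' enumerate_binding_states(2)$n_states  # 7
enumerate_binding_states <- function(s) {
  s <- as.integer(s)
  if (s < 1L || s > 4L) stop("valency s must be between 1 and 4")
  states <- list(matrix(integer(), 0L, 2L))
  level <- states
  for (b in seq_len(s)) {
    nxt <- list(); keys <- character()
    for (st in level) {
      free_l <- setdiff(seq_len(s), st[, 1L])
      free_r <- setdiff(seq_len(s), st[, 2L])
      for (i in free_l) for (j in free_r) {
        cand <- rbind(st, c(i, j))
        key <- .state_key(cand)
        if (!(key %in% keys)) {
          keys <- c(keys, key)
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
    }
    nxt <- nxt[order(keys)]
    states <- c(states, nxt)
    level <- nxt
  }
  structure(list(states = states, n_states = length(states),
                 bonds = vapply(states, nrow, 0L), s = s),
            class = "binding_state_space")
}

#' Build the microscopic transition-rate matrix at a free-ligand
#' concentration
#'
#' Constructs the transposed generator `Q^T` (columns sum to zero) of the
#' continuous-time Markov chain over [enumerate_binding_states()]:
#' the first bond forms from the unbound state at rate
#' `alpha = k_on[1] * L_free` (once per admissible single-bond state),
#' each additional bond of a b-bond state forms at `k_on[b+1]`, and each
#' bond of a b-bond state breaks at `k_off[b]`. Diagonals are minus the
#' off-diagonal column sums, which makes `Q^T` a proper generator: for
#' s = 2 the singly-bound diagonal is `-(k_off[1] + k_on[2])`.
#'
#' @param rates a [micro_rates()].
#' @param L_free free ligand concentration (mmol/l), non-negative. At
#'   `L_free = 0` the unbound state has no outflow and the chain is
#'   reducible.
#' @return An object of class `rate_matrix`: list with `QT` (n x n),
#'   `L_free`, `alpha`, `beta` (`k_off[1] + k_on[2]`, the magnitude of
#'   the singly-bound diagonal, `NA` for s = 1) and `space`.
#' @export
#' @examples
#' Q <- build_rate_matrix(cona_example(2)$qc$rates, L_free = 0.01)
#' round(colSums(Q$QT), 12)  # all zero
build_rate_matrix <- function(rates, L_free) {
  stopifnot(inherits(rates, "micro_rates"), is.numeric(L_free),
            length(L_free) == 1L, is.finite(L_free), L_free >= 0)
  space <- enumerate_binding_states(rates$s)
  keys <- vapply(space$states, .state_key, "")
  n <- space$n_states
  QT <- matrix(0, n, n)
  for (a in seq_len(n)) {
    st <- space$states[[a]]
    b <- nrow(st)
    free_l <- setdiff(seq_len(rates$s), st[, 1L])
    free_r <- setdiff(seq_len(rates$s), st[, 2L])
    for (i in free_l) for (j in free_r) {
      to <- match(.state_key(rbind(st, c(i, j))), keys)
      rate <- if (b == 0L) rates$k_on[1L] * L_free else rates$k_on[b + 1L]
      QT[to, a] <- QT[to, a] + rate
    }
    if (b >= 1L) for (k in seq_len(b)) {
      to <- match(.state_key(st[-k, , drop = FALSE]), keys)
      QT[to, a] <- QT[to, a] + rates$k_off[b]
    }
  }
  diag(QT) <- diag(QT) - colSums(QT)
  structure(list(QT = QT, L_free = L_free, alpha = rates$k_on[1L] * L_free,
                 beta = if (rates$s >= 2L) rates$k_off[1L] + rates$k_on[2L] else NA_real_,
                 space = space),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("Rate matrix Q^T: %d states (s = %d) at [L] = %g mmol/l\n",
              x$space$n_states, x$space$s, x$L_free))
  invisible(x)
}

# accept either a rate_matrix or a plain transposed-generator matrix
.as_QT <- function(Q) {
  if (inherits(Q, "rate_matrix")) Q$QT
  else if (is.matrix(Q) && nrow(Q) == ncol(Q)) Q
  else stop("expected a 'rate_matrix' or a square matrix")
}
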