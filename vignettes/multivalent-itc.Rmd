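---
title: "Multivalent binding kinetics from ITC: the models behind mvitc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivalent binding kinetics from ITC: the models behind mvitc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvitc)
```

## The problem

An isothermal titration calorimetry (ITC) experiment titrates a ligand
into a cell of macromolecule solution and records, for each injection,
the compensation heat needed to keep the cell at the reference
temperature. After integrating the power peaks, each injection yields
one number, the heat `q_i` per mole of injected ligand (kcal/mol). The
classical analysis fits these heats with a 1:1 binding isotherm and a
single association constant.

For multivalent ligand–receptor pairs — here the lectin Concanavalin A
binding precision glycomacromolecules with two or three mannose
ligands — the complex forms through intermediate states with one, two,
... bonds. A single constant cannot represent this: the apparent
association constant changes with the free-ligand concentration, and
therefore from injection to injection. `mvitc` implements both the
classical fit and a kinetic extension in which the per-injection
association constants derive from microscopic on/off rates of each
consecutive binding step.

## Concentration bookkeeping

A `titration_schedule` holds the cell volume `V0` (ml), the injection
volumes `V_i` (ml), and the syringe/cell concentrations `c_L`, `c_M`
(mmol/l). With cumulative injected volume $v_i = \sum_{k \le i} V_k$,
the displacement-corrected totals after injection $i$ are

$$l_i = c_L\, v_i \frac{2V_0 - v_i}{2V_0^2},\qquad
  m_i = c_M \frac{2V_0 - v_i}{2V_0 + v_i}.$$

Units are fixed package-wide (ml, mmol/l, kcal/mol, ucal/s) with a
single conversion constant where power integrals become molar heats, so
the unit of `q` is always the unit of $\Delta H^\circ$.

## The Wiseman model

The bound fraction for 1:1 binding with `n` sites and association
constant $K_a$ is

$$W(K_a, n; l, m) = \frac12\left(1 +
  \frac{n - l/m - 1/(mK_a)}{\sqrt{(n + l/m + 1/(mK_a))^2 - 4n\,l/m}}\right),$$

and the classical fit minimizes the Euclidean norm
$\lVert q - W(K_a, n; l, m)\,\Delta H^\circ\rVert$ over
$(K_a, n, \Delta H^\circ)$. `W` is dimensionless; only the product
$m K_a$ enters, so rescaling `l` and `m` by a common factor and $K_a$
reciprocally changes nothing but the unit of $K_a$. All fitted $K_a$
values reported by this package are in l/mmol, matching the mmol/l
concentration inputs.

`fit_wiseman()` uses Nelder–Mead on $(\log K_a, \log n, \Delta H^\circ)$
(positivity by construction), initialized from a midpoint heuristic:
$K_a \leftarrow 1/m$ at the injection whose heat is closest to half the
first usable heat, `n` from the molar ratio there, $\Delta H^\circ$ from
the first usable heat. The simplex runs with relative tolerance 1e-12,
up to 1e5 evaluations, and is restarted once from its own optimum. On
noise-free forward-model data the generating parameters are recovered to
better than 0.1% (this is part of the test suite).

The thermodynamic relations
$\Delta G^\circ = -RT\ln K_a = \Delta H^\circ - T\Delta S^\circ$ are
evaluated by `thermo_from_Ka()` with $R = 1.98720425\times10^{-3}$
kcal/(mol K) and a default temperature of 298.15 K; neither is dictated
by the data format, so both are explicit arguments.

## The microscopic rate model

For an s-valent pair, the binding states are all partial matchings
between the s ligand sites and the s receptor sites: $\binom{s}{b}^2 b!$
states with $b$ bonds, i.e. 7 states for $s=2$ and 34 for $s=3$
(`enumerate_binding_states()`). The transposed generator `Q^T`
(`build_rate_matrix()`) has, from a state with $b$ bonds:

* a transition at rate $k_{on,1}[L]$ from the unbound state to each
  single-bond state;
* a transition at rate $k_{on,b+1}$ to each state with one admissible
  additional bond, for $b \ge 1$;
* a transition at rate $k_{off,b}$ breaking each existing bond;
* a diagonal equal to minus the column sum, which is what makes the
  matrix a generator (every column of `Q^T` sums to zero). For $s = 2$
  the singly-bound diagonal is $-(k_{off,1} + k_{on,2})$.

Only the first on-rate carries the free-ligand concentration: once the
complex exists, further bonds close intramolecularly. The chain is
irreducible for $[L] > 0$ and reversible (all cycles balance), so it has
one zero eigenvalue and otherwise strictly negative real spectrum.

The rates are *relative* quantities. The coarse-grained association
constant is invariant under joint rescaling of all microscopic rates, so
only the per-step ratios $K_j = k_{on,j}/k_{off,j}$ and the shape of the
concentration dependence are identifiable — fitted rates carry no
physical unit, and `fit_qc()` reports the $K_j$ alongside them.

## PCCA+ coarse graining and one numerical subtlety

At a given $[L]$, the two-state (bound/unbound) macro model is obtained
by projecting the generator onto fuzzy memberships
$\chi \in [0,1]^{n \times 2}$:

$$Q_c = (\chi^T \Pi \chi)^{-1} \chi^T \Pi\, Q\, \chi,
  \qquad \Pi = \mathrm{diag}(\pi),$$

with $Q$ acting on observables and $\pi$ the stationary distribution.
The memberships come from the inner simplex algorithm applied to the
invariant subspace spanned by the constant eigenvector and one slow
eigenvector $v$: the most separated pair of entries of $v$ are the
simplex vertices and every state gets barycentric coordinates between
them. For two clusters this never produces negative memberships (every
entry lies between the vertices), so the clipping step is a pure
rounding guard. The projected $Q_c^T$ matches the template

$$Q_c^T = \begin{pmatrix} -k_{on}[L] & k_{off} \\
   k_{on}[L] & -k_{off}\end{pmatrix},$$

from which `coarse_grain()` reads off the macroscopic rates and
$K_a = k_{on}/k_{off}$. The macro state with the larger membership of
the unbound micro state is labelled "unbound".

**Which slow eigenvector?** The partial-matching state space carries an
exact site-permutation symmetry, and the generator therefore has
antisymmetric eigenmodes that (i) have exactly zero weight on the
unbound state and (ii) can be *slower* than the binding/unbinding mode.
For the bivalent reference rates the slowest nonzero eigenvalue belongs
to such a mode at every $[L]$. Running the inner simplex algorithm on it
would split equivalent bound configurations instead of bound from
unbound and silently yield $K_a \equiv 1/[L]$. `pcca_memberships()`
therefore selects the slowest eigenvector that actually exchanges
probability with the unbound state: a candidate is accepted if its
unbound entry is non-negligible or (for degenerate spectra, e.g.
disconnected chains) if its clustering assigns the unbound state
crisply. For chains without such symmetry this reduces to the standard
"first two eigenvectors" choice, as the test on two uncoupled two-state
chains confirms. A projection residual test verifies that $\chi$ stays
in the span of the eigenvectors used.

Two internal consistency checks are part of the test suite: the columns
of $Q_c^T$ sum to zero, and $K_a$ from the projection equals the
membership-weighted stationary occupancy ratio
$(\chi_{\cdot,2}^T\pi)/(\chi_{\cdot,1}^T\pi\,[L])$, an independent route
to the same number.

## Free-ligand tracking

The generator needs the *free* ligand concentration, which is not
observed. It is propagated across injections as

$$[L]_1 = l_1, \qquad [L]_i = [L]_{i-1} + l_i - (L_b)_{i-1},$$

where the bound-ligand concentration

$$L_b = \tfrac12\left(nm + l + 1/K_a -
  \sqrt{(nm + l + 1/K_a)^2 - 4nml}\right)$$

satisfies $0 \le L_b \le \min(nm, l)$. Two choices had to be fixed here:

* **Circularity.** $L_b$ needs a $K_a$, but $K_a$ depends on $[L]$. The
  recursion uses the coarse-grained constant evaluated at the *previous*
  injection's $[L]$ (lagged evaluation), which keeps every step explicit
  and the whole series deterministic.
* **Cumulative versus incremental.** In the default `"cumulative"` mode
  the recursion adds the total $l_i$ each step, as written above. Note
  that this reading lets $[L]$ exceed the total ligand concentration in
  the later injections — it is kept as the default because it is the
  literal published form of the recursion, and the package's diagnostic
  values are reported under it. The alternative `"increment"` mode adds
  only $l_i - l_{i-1}$; with strong binding it can drive $[L]$ to zero,
  where entries are floored at 0 with a warning and the lagged constant
  is evaluated at a small positive floor (1e-9 mmol/l) to keep the
  eigenproblem irreducible. Neither mode is a mass-balance solution;
  `free_ligand_series()` exposes both, and users wanting strict mass
  balance can compute $l_i - L_b(n, m_i, l_i, K_i)$ from the returned
  columns.

## The Q_c fit

`qc_objective()` evaluates, per injection, $W(K_i, n; l_i, m_i)\Delta
H^\circ$ with the per-injection constants $K_i$ from the coarse-grained
model along the free-ligand series, and returns the weighted Euclidean
norm of the residual. When the heat curve concentrates its information
in a narrow slope (the trivalent reference case, around molar ratio
0.3), the residuals are multiplied by a Gaussian kernel
$\exp(-(r-\mu)^2/2\sigma^2)$ with $\mu = 0.3$, $\sigma = 0.1758$, and
the first injection is excluded as an outlier; both are flags in
`weight_spec()` and default off for the bivalent configuration.

`fit_qc()` estimates the parameters by random search with a break
condition: microscopic rates are drawn log-uniformly (default bounds
$[10^{-2}, 10^4]$ per rate, spanning the plausible relative-rate range;
seeded), the stoichiometry uniformly on (0.05, 2), and $\Delta H^\circ$
is set to its analytic least-squares value given the modelled isotherm
column — a scalar projection, not an extra search dimension. The search
stops at the first candidate whose norm beats the Wiseman fit's norm
(the natural threshold: the extension should do at least as well as the
model it generalizes), or after `max_draws` draws keeping the best. The
selected candidate is then refined by Nelder–Mead over $(n, \Delta
H^\circ)$ with rates fixed (`refine = "ndh"`, the default). An optional
`refine = "full"` polish over all parameters is available; it is off by
default to keep the estimation procedure exactly the two-stage scheme
described above, but it is what you want for parameter recovery: on
noise-free bivalent synthetic data the full polish drives the norm to
~1e-8 and recovers the generating $K_1$, $K_2$ to several digits,
while the rates themselves are recovered only up to a common factor, as
the identifiability analysis predicts. No globally optimal algorithm is
claimed; the random search is restartable and deterministic per seed.

## Model-selection diagnostics

Whether a *two*-state projection is adequate is a question about
timescale separation. `eigenvalue_ratio_series()` builds the generator
at each injection's $[L]$, sorts eigenvalue magnitudes ascending
($\lambda_1 \approx 0$ always), and reports
$|\lambda_3|/|\lambda_2|$ (`ratio_2state`) and
$|\lambda_4|/|\lambda_3|$ (`ratio_3state`). Values near 1 mean the
next-faster process is as slow as the projected one and the 2-state
picture is doubtful; values well above 1 mean a clean gap.

Two structural facts of the partial-matching generator show up in these
diagnostics and are worth knowing when reading them. First, the
antisymmetric permutation modes are $[L]$-independent, so `ratio_2state`
saturates once the binding mode becomes faster than the slowest
antisymmetric mode (bivalent reference rates: at ~29). Second, for
$s = 3$ the third and fourth eigenvalue magnitudes sit in an exactly
degenerate antisymmetric multiplet at every $[L]$, so `ratio_3state` is
identically 1 for this model class — a three-macrostate projection
cannot be justified *from this generator's spectrum alone*, and a
published value above 1 for such a ratio implies a structurally
different trivalent matrix. The package reports what its own model
computes.

The perturbation protocol (`perturb_heats()`, `perturbation_study()`)
multiplies every heat by an independent uniform draw from
$[1-w, 1+w]$ (default $w = 0.01$), refits both models, and reports
percentage changes. Multiplicative uniform noise is also exactly the
simulator's noise model, so robustness statements and the noise model
coincide. On bivalent synthetic data the stoichiometry and heat of
binding move on the order of the input noise; the microscopic constants
of poorly separated (e.g. trivalent) configurations can move by orders
of magnitude more, which is reported, not asserted.

## Synthetic data

`simulate_heats()` evaluates the forward model of either truth
(constant $K_a$, or per-injection $K_i$ from the rate model) on a
schedule's concentration series and applies the multiplicative noise.
`simulate_power_trace()` re-expands heats into a sampled power trace
with exactly known per-window integrals: `"rectangular"` spreads each
injection's heat uniformly over its window (constant data — any
interpolating spline integrates it exactly), `"exponential"` uses a
decay $A_i e^{-(t-t_i)/\tau}$ with $A_i$ chosen so the sampled span
carries the window's heat in closed form.

What the simulator emulates: the heat-per-injection data model, its
dependence on the schedule, multiplicative measurement error, and
deconvolved power peaks with known integrals. What it does not emulate:
instrument response and deconvolution artifacts, baseline drift and
1/f noise, heats of dilution, injection-to-injection carryover, or any
deviation of the chemistry from the s-step binding model. Passing
recovery tests on these data therefore demonstrates correctness of the
estimation machinery, not validity of the binding model for a given
real system.

## Peak integration choices

`integrate_peaks()` fits an interpolating quintic (order-6 B-spline)
through each window's samples — averaged interior knots, collocation
solve, closed-form basis integrals — and integrates over the sampled
span. At least 6 samples per window are required. Interpolation (no
smoothing) is the default because it makes the closed-form oracles
exact; smoothing belongs upstream with the deconvolution. A linear
baseline anchored on the mean power of the first and last 5% of each
window's samples is available (`baseline = "edges"`) but off by
default: an edge-anchored baseline annihilates any window-spanning
rectangle, including genuine signal, and deconvolved traces are assumed
baseline-corrected already. Windows are half-open $[t_i, t_{i+1})$; the
last window ends at the final sample.

## Numerical conventions

* Eigenvalues with imaginary parts above 1e-8 of the spectral scale are
  an error in coarse graining and a warning (with magnitude sorting) in
  the diagnostics; the binding chains are reversible, so their spectra
  are real up to rounding.
* Stationary distributions come from a least-squares solve of the
  stacked system `rbind(Q^T, 1)`; the residual is checked at 1e-10.
* A degenerate spectral gap *at the selected slow mode* triggers a
  warning; degeneracies among the antisymmetric modes are expected and
  silent.
* The bound-ligand discriminant is clamped at zero within 1e-12
  relative, guarding rounding; a genuinely negative discriminant is an
  error.
* Random search and noise use R's RNG through a local-seed wrapper, so
  package calls never disturb the caller's RNG stream, and identical
  seeds give bit-identical results.

## Problem sizes used in the tests

The test suite runs entirely on synthetic data: the two reference
schedules (14 injections), state spaces up to 34 states, 1000 random
generator instances for the structural checks, and a single
300-draw + full-polish recovery run for the Q_c fit. These sizes keep
the whole suite in the minutes range while exercising every code path;
nothing in the methods limits them.

## Known limitations

* The projection is two-macrostate only; a 3x3 projection for trivalent
  data is not implemented (and, per the spectral argument above, would
  need a structurally richer generator to be justified).
* The random search offers no optimality guarantee, and with the
  default `(n, dH)`-only refinement the microscopic rates are only as
  good as the best draw; use `refine = "full"` when rate ratios matter.
* Free-ligand tracking is a modelling convention, not mass-balance
  accounting (see above); conclusions that hinge on late-titration
  $[L]$ values inherit this convention.
* Only 1:1 ligand:receptor complexes are modelled — no cross-linking,
  no ligand bridging two receptors — and valencies above 4 are rejected
  rather than attempted.
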