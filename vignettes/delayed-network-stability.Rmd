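---
title: "Stability of layered networks with delayed feedback: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability of layered networks with delayed feedback: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netstab)
```

## Model

`netstab` analyzes the discrete-time linear dynamics of a chain of `N`
layers driven at layer 1:

$$h_t = x\,e_1 + M_{FF}\,h_{t-\Delta} + M_{FB}\,h_{t-1}.$$

Connections are encoded with the convention that entry `(i, j)` of a
connectivity matrix is the weight of the connection *from layer `j` to
layer `i`*. `M_FF` is strictly subdiagonal (feedforward, `j -> j + 1`
only); `M_FB` occupies the upper triangle including the diagonal
(feedback `j -> i` with `i <= j`; diagonal entries are self-loops, i.e.
feedback of distance 0). Connections skipping layers in the feedforward
direction are rejected by `layered_network_spec()`.

Two timing schemes are compared:

* **biological** (`Δ = 1`): every connection takes one step. One linear
  map per step, with effective matrix `M_B = M_FF + M_FB`.
* **artificial** (`Δ = 0`): the feedforward sweep is instantaneous within
  a step, feedback is delayed. Solving the within-step recursion gives the
  effective matrix `M_A = (Id − M_FF)^{-1} M_FB`; the inverse always
  exists because `Id − M_FF` is unit lower triangular (its inverse is the
  finite Neumann series in the nilpotent `M_FF`).

Both schemes share the fixed point
`h* = x (Id − M_FF − M_FB)^{-1} e_1` (`fixed_point_linear()`); stability
— spectral radius of the effective matrix below 1 — is what differs.
`classify_stability()` reports `stable` / `marginal` / `unstable`, with a
marginality band `|rho − 1| <= 1e-8` by default.

## Network generators

`layered_network_spec()` takes an explicit weight table. On top of it:

* `canonical_family()` / `from_family()` instantiate named structures:
  `single_q` (uniform chain plus feedback at a single distance `q`),
  `fully_connected` (dense, diagonal `w_i`, off-diagonal `w_e`; carried
  entirely in `M_FB` and flagged `non_layered` so both schemes see the
  same matrix), `chain_time_decay` (per-layer leak on the diagonal), and
  the two-parameter slices `fig5a` (N = 2), `fig5b` (N = 3) and `fig5c`
  (N = 5) used for boundary maps.
* `random_network()` draws seeded uniform weights on the admissible
  structure at chosen feedback distances. The defaults
  (`weight_distribution = list(min = -1, max = 1)`) are study conditions:
  weights of order 1 put the generated ensembles astride the stability
  boundary instead of trivially inside or outside it.
* `expand_units()` replaces each scalar layer by a population of
  identical units (Kronecker product with an all-ones block). The block
  is rank 1, so the nonzero spectrum — and every stability conclusion —
  is unchanged; this is the sense in which the scalar model "stands in"
  for populations, and it is tested, not assumed.

In the two-parameter slices the feedforward chain is pinned at 1 and the
slice parameters multiply feedback weights. This is a deliberate
parameterization choice: redistributing weight around a loop by a
diagonal similarity leaves the spectrum unchanged (tested in the suite),
so only loop products matter and placing them on the feedback side loses
no generality.

## Analytical results implemented

* **Characteristic polynomials** (`char_poly()`, via `pracma::charpoly`)
  with closed-form coefficient checks for `N = 2, 3` under both schemes.
* **Unit-circle conditions** (`unit_circle_condition()`): a root
  `e^{i theta}` exists iff two real residuals built from Chebyshev
  polynomials of the second kind vanish (one residual at
  `theta = 0, pi`, where the condition degenerates to `p(±1) = 0`).
* **Scheme equivalence** (`verify_equivalence()`): for feedback at a
  single distance `q`, `p_A(λ) = λ^{k1} g(λ)` and
  `p_B(λ) = λ^{k2} g(λ^{q+1})`, so every nonzero root of `p_B` is a
  `(q+1)`-th root of a root of `p_A` and the bifurcation boundaries of
  the two schemes coincide.
* **Closed forms** for single-distance networks: loop gain
  `g_q = w_fb w_ff^q`, dominant eigenvalue `g_q (N − q)` exact when
  `N/2 − 1 < q`, a trace identity for smaller `q`, and a zero root of
  multiplicity at least `2q`. For fully connected networks the spectrum
  is `{w_i − w_e` (multiplicity `N − 1`), `w_i + (N − 1) w_e}`.
* **Thresholds** (`feedback_threshold()`): bisection on the spectral
  radius. Monotonicity in the loop distance `q` holds in the *per-link*
  parameterization (all `q + 1` links of the loop carry weight `w`;
  closed form `(1/(N − q))^{1/(q+1)}` in the exact regime). The same
  thresholds expressed on the raw feedback weight with the chain pinned
  at 1 are *not* monotone at small `q` (for `N = 6`:
  0.308, 0.268, 0.333, 0.5, 1); the sweep artifacts report both columns.

## The containment result and its validity domain

The headline qualitative claim is that the artificial scheme's stable
region is contained in the biological one: making the feedforward sweep
instantaneous cannot stabilize a circuit that the fully delayed version
cannot stabilize. Numerically mapping both regions shows this containment
**holds in the cortical sign regime — nonnegative feedforward with
nonpositive feedback — and fails outside it**: with excitatory feedback
or inhibitory feedforward links, parameter points exist that are
artificial-stable yet biological-unstable (e.g. the `fig5a` slice at
`w_i = 0.5, w_p = −1`). The package therefore states and tests
containment on the inhibitory-feedback quadrant of the slices
(`[−2, 0]^2`) and on sign-constrained random ensembles (feedforward in
`[0, 1]`, feedback in `[−1, 0]`); `trace_boundary()` over wider windows
will readily exhibit the violations outside this domain. On the slice
axes the two schemes' refined boundary points coincide to `1e-6`, as the
equivalence theorem requires.

## Numerical choices

* **Eigenvalues** come from dense `eigen()`; problem sizes here
  (`N <= ~12` layers, a few hundred units after expansion) make dense
  solvers the robust choice.
* **Zero roots are deflated, never thresholded.** Both effective matrices
  are typically defective at zero, so eigensolvers and `polyroot()`
  scatter a multiplicity-`m` zero root by as much as `eps^{1/m}` — up to
  `~1e-3` for `m = 6` — which no magnitude cutoff can distinguish from a
  genuine small root. Root-matching code instead drops trailing
  characteristic coefficients below `1e-9 * max|c|` and factors the
  remaining polynomial. For the equivalence check this is self-consistent
  across schemes because `p_A` and `p_B` share the nonzero coefficient
  values of `g`.
* **Convergence of simulations** (`iterate_dynamics()`) is declared from
  a geometric error estimate `2 d_t r/(1 − r)` with
  `r = (d_t/d_{t-5})^{1/5}` (sup-norm steps `d_t`), held below `tol` for
  3 consecutive steps. A raw step-size test would stop
  `~ tol/(1 − rho)` short of the fixed point near criticality.
  Divergence is declared at state sup-norm `1e6`; caps default to
  10000 steps and `tol = 1e-10`.
* **Boundary tracing** (`trace_boundary()`) classifies a parameter grid,
  then refines every stability flip along grid edges by bisection on
  `rho − 1` (30 iterations, `~1e-9` parameter resolution).
* **Nonlinear fixed points** use damped iteration
  `h <- (1 − eta) h + eta F(x e_1 + M h)` with `eta` adapted by
  doubling/halving on the residual — plain iteration can cycle for steep
  sigmoids. Only the fixed point reachable from `h = 0` (the dynamics'
  initial state) is found. Jacobian stability uses
  `D = Diag[F'(I*)]` with `M_B` or `(Id − D M_FF)^{-1} D M_FB`.
* **Activation ranges**: `make_activation()` records the conventional
  stated ranges (loose for some entries); `derivative_range()` computes
  tight extremes by grid scan plus local optimization. The ReLU
  derivative at 0 is taken as 1 (right limit); GELU uses the exact
  Gaussian-CDF form. Note that the scaled-Jacobian bound
  `rho(D M_B) <= rho(M_B)` for nonnegative `M_B` requires
  `max |F'| <= 1`; silu (max slope `~1.0998`) genuinely violates it, and
  the test suite asserts the existence of such counterexamples rather
  than the bound.

## Problem sizes

The package's own study sizes — chosen to keep every experiment
dense-solver exact and reproducible on a laptop — are `N` up to 12
layers for spectral checks, `200 x 200` parameter grids per slice,
`10^3`–`10^4` random networks per property sweep, and populations up to
a few hundred units via `expand_units()`.

## Limitations

* Linear analysis is exact only for the linear model; nonlinear results
  concern a single fixed point and its local Jacobian — no limit cycles,
  basins, or global dynamics.
* The artificial/biological dichotomy brackets real circuits; mixed or
  heterogeneous conduction delays are not modeled beyond the two schemes.
* Containment of stability regions is established empirically on the
  sign-constrained domain described above, not proven in the package; the
  suite documents counterexamples outside that domain.
* Random ensembles use independent uniform weights — a study condition,
  not a fitted model of cortical connectivity statistics.
* The closed forms for single-distance feedback assume the uniform-chain
  structure generated by `canonical_family("single_q")`.
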