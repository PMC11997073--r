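---
title: "Modelling protocell evolution in enantiomeric excess and inherited information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling protocell evolution in enantiomeric excess and inherited information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(protocell2d)
```

## The model

`protocell2d` simulates a closed population of pre-biological protocells
distributed over a two-dimensional trait space: the total enantiomeric excess
$\eta \in [-1, 1]$ of a protocell's chiral building blocks ($\eta = 0$ is
racemic, $\eta = \pm 1$ homochiral) and the amount of information
$\zeta \in [0, L]$ passed from parent to offspring (read as the natural log of
bits). Three reactions drive the dynamics:

* **Replication with mutation.** A protocell at $(\eta', \zeta')$ consumes one
  unit of food $X$ and produces an offspring at $(\eta, \zeta)$ at rate density
  $\rho_X\, K(\eta, \zeta, \eta', \zeta')$. The kernel factorizes as
  $K = k_0\, k_a(\eta', \zeta')\, p(\eta, \zeta \mid \eta', \zeta')$: a global
  rate $k_0$, a normalized per-trait replication rate $k_a$, and a mutation
  probability density $p$ — a product of independent truncated Gaussians of
  scales $\varepsilon_\eta, \varepsilon_\zeta$ centred on the parent, with an
  erf-based edge normalization so $p$ integrates to exactly 1 for every parent,
  including parents at the domain edges.
* **Death.** Protocells decay to waste $W$ at rate
  $\gamma_0\,\gamma(\eta, \zeta)$.
* **Recycling.** Waste returns to food at rate $s$, closing the system: the
  total matter $\rho_X + \rho_W + \int\!\!\int U$ is an exact invariant, which
  every stepper in the package preserves to round-off (real mode) or exactly
  (integer mode).

The rate shapes used throughout are separable quadratic forms,
$$k_a(\eta,\zeta) = \Big(1 + \tfrac{b_\eta}{2}\eta^2\Big)
 \Big(1 + a_\zeta x + \tfrac{b_\zeta}{2} x^2\Big), \qquad
 \gamma(\eta,\zeta) = (1 - g\,\eta)\Big(1 + \tfrac{f}{8!} x^8\Big),
 \qquad x = c\,\zeta,$$
with $\gamma(0,0) = 1$ by construction. Both quadratic coefficients must be
positive for evolution toward homochirality and higher information content to
be favoured; $k_a$ is even in $\eta$ by L/D mirror symmetry, so the only
symmetry-breaking bias is the small factor $g$ in the *decay* rate — a global
chiral asymmetry that shortens the lifespan of one handedness. The
eighth-power factor $f$ is an explicit model limitation that keeps the
stationary point off the $\zeta = L$ boundary; without it the population runs
to the edge of the domain.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `k0` | 0.1 | replication rate at the origin, per step per unit food |
| `gamma0` | 0.01 | decay rate at the origin, per step (mean lifespan $1/\gamma_0 = 100$ steps) |
| `s` | 1 | recycling rate per step |
| `b_eta`, `b_zeta` | 1 | quadratic trait-dependence of $k_a$ |
| `a_zeta` | 0 | linear information drift of $k_a$ (0 or 1 in the reference scenarios) |
| `eps_eta`, `eps_zeta` | 0.005 | mutation scales; must be $\ll 1$ and $\ll L$ |
| `g` | 0.002 | global chiral asymmetry in $\gamma$ |
| `f` | 1000 | information-limiting factor |
| `c` | $3/(2L)$ | information scaling, so $\zeta = \tfrac{2}{3}L$ maps to $x = 1$ |
| `z` | $10^{-5}$ | kernel sparsification threshold |
| `rho0` | $10^{18}$ | total molecule count (the conserved invariant) |
| `U00` | $10^3$ | founding protocells at the origin |
| `dt` | 1 | step size, treated as one evolution epoch |

One step is one "epoch"; with a one-day epoch, `gamma0 = 0.01` means a
100-day mean protocell lifespan. The domain bound `L = 25`, read as log-bits,
corresponds to $e^{25}/8 \approx 10^{10}$ bytes per generation — far beyond
anything a protocell could plausibly transmit, so the domain does not limit
the biology.

## Discretization and the sparse kernel

The trait domain is discretized on a node-centred $d \times d$ grid that
includes the endpoints, so the homochiral states $\eta = \pm 1$ are
representable — necessary because the stationary distribution peaks there.
Double integrals use trapezoid weights (halved on edges, quartered at
corners), which reproduce the domain area $2L$ exactly.

For each source node the mutation density is converted to per-node masses
(density × target weight, normalized to 1), masses below `z` are zeroed, and
the survivors renormalized — the threshold is applied to the *discrete mass*,
which is what the kernel stores, and the double normalization makes every
stored column sum to exactly 1. At the reference configuration ($d = 500$,
$\varepsilon = 0.01$, $z = 10^{-5}$) an interior source keeps a few tens of
targets out of 250,000 nodes, the sparsity that makes the whole approach
tractable. Kernels also carry an explicit source-iteration order and
order-preserving per-column target lists; `pc_mirror_kernel()` permutes all
three consistently, which is what makes a mirrored simulation consume the RNG
stream in matched positions and reproduce the mirrored trajectory *exactly*
when the rates are symmetric ($g = 0$) — a strong discrete test of the
model's statistical mirror symmetry.

## Dynamics

Two steppers share the kernel:

* `pc_step_euler()` advances the integrodifferential equations by explicit
  forward Euler on concentrations. Explicit stepping can overshoot below
  zero; negative values are clamped to zero and the clamped mass debited from
  the food pool, so the conservation invariant survives clamping exactly.
  The choice of *food* as the debit account keeps the closed model closed;
  the clamp fires only under artificially harsh step sizes.
* `pc_step_tau()` is a fixed-step tau-leaping stepper in integer molecule
  counts. All propensities are evaluated at the leap start; births are
  Poisson per source (one draw per source, multinomial placement of offspring
  — fewer RNG calls than per-target draws, identical law), deaths are Poisson
  capped at the available count, recycling is Poisson capped at the waste
  count. If the drawn births exceed the food present, birth events are
  thinned uniformly at random (a multivariate hypergeometric across sources)
  so the leap consumes exactly the food available and no more. The integer
  representation exists because continuous stepping lets machine-noise-level
  mass leak into high-fitness regions and grow exponentially into artefacts;
  integer counts cannot.

Counts are stored as doubles and kept exact; `rho0` is validated against the
$2^{53}$ exact-integer limit (so the reference scenarios' $\rho_0 = 10^{18}$
runs exactly only in Euler mode — integer runs use a scaled-down total), and
Poisson draws with mean above $2^{30}$ use the Gaussian limit (R's integer
Poisson sampler would overflow). As the
total molecule count grows, the per-step mean changes of the tau-leaping
dynamics converge to the Euler update; the test-suite verifies < 1% deviation
of the ensemble-mean population trajectory at $\rho_0 = 10^{12}$.

While the population is still a single point at the origin, the full dynamics
collapse to three scalar ODEs (`pc_reduced_step()`), giving the stage-1 time
estimate `pc_estimate_t0()`: with the log ratio capped by Earth-scale
molecule counts and even a one-e-fold-per-year replication rate, the initial
exponential-growth stage is over within a century.

## Stationary analysis and the diffusion picture

Stationarity turns the dynamics into a Fredholm eigenproblem for the operator
$u \mapsto \int k_a\, p\, u / \gamma$; its leading eigenvalue fixes the
stationary food concentration $\rho_X^* = \gamma_0/(k_0 \lambda)$ and its
eigenvector is the stationary trait distribution. `pc_stationary()` uses
power iteration with a uniform positive start (guaranteed overlap with the
nonnegative leading eigenvector), L2 renormalization each sweep, and a
Rayleigh-quotient convergence test (default tolerance $10^{-10}$). For small
mutation scales $\lambda \approx \max k_a/\gamma$ and the eigenvector peaks
at the fitness maximum; under the reference parameters that maximum sits at
$\eta = 1$, $\zeta \approx 20.3$ — the homochiral, high-information corner
carved out by the limiting factor $f$.

When the population is much wider than the mutation scale, the dynamics are
approximately a convection–diffusion equation with creation term
$\alpha - \gamma$, drift $\beta \propto \nabla k_a$ and diagonal diffusion
$\delta = \tfrac{1}{2} r\, k_a\, \varepsilon^2$. `pc_diffusion_full()`
evaluates the defining moment integrals by per-axis fine trapezoid
quadrature of the continuous truncated-normal density (the integrals
factorize; resolution follows the mutation scale, not the grid), while
`pc_diffusion_approx()` evaluates the closed forms with analytic derivatives
of the separable rate shape — hard-coded rather than differenced, so the
dual-route agreement test is exact about what it compares. Edge nodes
(within $6\varepsilon$ of the boundary) are excluded from agreement
assertions; there the truncated normal is genuinely biased. The cross
diffusion $\delta_{\eta\zeta}$ is $O(\varepsilon^4)$ — zero exactly when
either rate gradient vanishes — and the drift component $\beta_\eta$
vanishes at the racemic origin by symmetry.

## Stages, species and summary statistics

`pc_summarize()` reports the total population and the means and standard
deviations of the trait distribution (quadrature-weighted in real mode, plain
counts in integer mode). An empty field reports `NA` moments rather than
zeros — a zero mean excess would masquerade as a racemic reading.

The food fraction traces up to four evolution stages: a fast tanh-like
initial drop, then plateaus separated by sustained drops as more efficient
protocells take over. The published account identifies the stages visually,
so `pc_detect_stages()` is an explicitly heuristic change-point detector:
a smoothed slope is classified drop/plateau against a threshold (default 10%
of the peak slope magnitude), runs shorter than `min_run` are ignored, and
each drop-to-plateau transition is a boundary. All thresholds are arguments;
detected boundaries are not comparable to any published number.

`pc_detect_species()` implements the species-splitting observation: when
favourable mutations place a subpopulation ahead of the advancing fitness
boundary it can grow into a disconnected bump. Components are 4-neighbor
connected regions above a threshold (default $10^{-3}$ of the field maximum —
separates bumps while ignoring the single-protocell mutation halo).

## Numerical choices and scaled study conditions

The reference runs of record use $d = 500$, $\rho_0 = 10^{18}$ and
$2 \times 10^5$ steps. The package's own stochastic test ensembles reproduce
the phenomenology at desk scale, which forces three linked choices:

* **Grid resolution vs mutation scale.** The discrete kernel can only move
  mass if the mutation scale is comparable to the node spacing
  ($h_\eta = 2/(d-1)$). At $d = 100$ the reference
  $\varepsilon = 0.005$–$0.01$ is sub-resolution, so scaled ensembles use
  resolvable scales: $\varepsilon_\eta = 0.1$, $\varepsilon_\zeta = 0.3$ for
  the symmetry-breaking ensemble ($d = 100$, $g = 0.02$, $\rho_0 = 10^9$,
  2,000 steps, ten seeds), with the asymmetry likewise scaled to stay above
  the grid's resolution limit $g \gtrsim 1/d$.
* **Kernel storage threshold.** The scaled ensembles use $z = 10^{-3}$; this
  trims only the far tail of the mutation law and roughly halves the stored
  kernel, a storage choice, not a model change. All headline sparsity
  computations use the reference $z = 10^{-5}$.
* **Stage-1 transient vs diffusive scaling.** The drift-free spreading
  ensembles (flat rates, $d = 101$, $L = 2$, $\rho_0 = 10^8$) verify the
  $\sigma \sim \varepsilon\sqrt{t}$ law and its corollary that halving
  $\varepsilon$ requires $4\times$ the time for equal widths. The stage-1
  exponential transient deposits an initial width of roughly
  $2.7\varepsilon$ (about 15 replacement generations), which at short runs
  contaminates the raw-width comparison, so these ensembles start from a
  large inoculum ($U_{00} = 10^7$ of $\rho_0 = 10^8$), shortening stage 1 to
  a few generations. The pair ($\varepsilon = 0.04$, $T = 1500$) vs
  ($\varepsilon = 0.02$, $T = 6000$) then matches within the stated 10%.

What the scaled ensembles show is that the mechanisms — directed symmetry
breaking under a resolvable bias, random breaking without one, diffusive
spreading with the $\varepsilon^2 t$ clock — operate as the theory says at
$10^9$ molecules on a $100^2$ grid. They do not reproduce the reference
runs' quantitative trajectories (narrower peaks, longer plateaus, rarer
species splitting at $10^{18}$ molecules), and no test here claims they do.

Other conventions: ties in the fitness map are reported in full, in
row-major node order (with $g = 0$ the maximum is an exactly mirrored pair);
downstream consumers take the first. The mutation scales are treated as
constants over the domain. `n > 1` simultaneous-food stoichiometry is
supported only in the reduced scalar system, as printed; the full-grid
bookkeeping for `n > 1` is not defined by the model and is not implemented.

## Limitations

* The stage detector is heuristic by design; its boundaries depend on the
  smoothing window and thresholds.
* The convection–diffusion fields are interpretive: the package computes the
  coefficients but deliberately does not integrate that PDE — dynamics always
  run through the kernel (Euler) or the reaction network (tau-leaping).
* Only the leading eigenpair is computed; subleading structure of the
  stationary operator is out of scope.
* A fixed leap of one epoch is used throughout (stability is handled by
  clamping and food-exact thinning, not adaptive step control), matching the
  model's convention; no exact per-event stochastic simulation mode is
  provided.
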