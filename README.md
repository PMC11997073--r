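# protocell2d

Simulation and analysis of pre-biological protocell evolution over a
two-dimensional trait space: the **enantiomeric excess** η ∈ [−1, 1] of a
protocell's chiral building blocks (0 = racemic, ±1 = homochiral) and the
**inherited information** ζ ∈ [0, L] passed per generation (read as the
natural log of bits). It is aimed at researchers studying chiral symmetry
breaking and information accumulation at the origin of life, and more
generally at anyone who needs mutation–selection kernel dynamics on a 2-D
trait grid with exact matter conservation.

## The model

A closed reaction network in three species — protocells U(η, ζ), food X and
waste W:

    X + U  →  U + U′        replication with a small trait mutation
        U  →  W             death
        W  →  X             recycling (closes the system)

so the total matter ρ_X + ρ_W + ∫∫U is an exact invariant. The replication
kernel factorizes as K = k₀ · k_a(η′, ζ′) · p(η, ζ | η′, ζ′): a normalized
replication rate

    k_a(η, ζ) = (1 + b_η η²/2)(1 + a_ζ x + b_ζ x²/2),   x = c ζ,

a decay rate γ(η, ζ) = (1 − g η)(1 + f x⁸/8!) carrying a small global chiral
asymmetry g and an information-limiting factor f, and a truncated-Gaussian
mutation density p with scales ε_η, ε_ζ (erf-normalized so each parent's
offspring distribution integrates to exactly 1). The package provides:

* a sparse discretized kernel on a d × d trait grid (`pc_kernel`),
* deterministic forward-Euler dynamics (`pc_step_euler`) and stochastic
  fixed-step tau-leaping in integer molecule counts (`pc_step_tau`,
  `pc_simulate`) with the invariant conserved **exactly** at every step,
* the stationary Fredholm eigenproblem by sparse power iteration
  (`pc_stationary`) and the fitness map k_a/γ whose global maximum locates
  the stationary peak (`pc_fitness_map`, `pc_fitness_argmax`),
* convection–diffusion coefficient fields, both as full moment integrals and
  small-mutation closed forms (`pc_diffusion_full`, `pc_diffusion_approx`),
* summary statistics, evolution-stage segmentation and species (connected
  component) detection (`pc_summarize`, `pc_detect_stages`,
  `pc_detect_species`), with `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

A scaled-down run (d = 60 grid, ρ₀ = 10⁹ molecules, resolvable mutation
scales) from the founding state of 10³ protocells at the racemic origin:

```r
library(protocell2d)

grid   <- pc_grid(60, 25)
params <- pc_params(eps_eta = 0.05, eps_zeta = 0.6, g = 0.002,
                    rho0 = 1e9, z = 1e-4, seed = 1)
kernel <- pc_kernel(grid, params)
traj   <- pc_simulate(kernel, params, T_max = 1000, record_every = 100)
tidy(traj)
#> # A tibble: 11 × 8
#>       t        U0  mu_eta sigma_eta mu_zeta sigma_zeta food_pct waste_pct
#>   <dbl>     <dbl>   <dbl>     <dbl>   <dbl>      <dbl>    <dbl>     <dbl>
#> 1     0      1000 -0.0169     0        0         0       100.0    0
#> 2   100   5725819 -0.0192     0.110    1.14      0.814    99.4    0.00528
#> 3   200 877564163 -0.0215     0.145    1.47      1.04     11.4    0.876
#> 4   300 892818682 -0.0220     0.152    1.52      1.08      9.83   0.893
#> # …
```

Between t = 100 and t = 200 the population explodes from 10⁶ to ~9 × 10⁸
protocells and the food share collapses from 99% to ~10% — stage 1, the
initial exponential growth, ends when k₀ρ_X drops to the break-even decay
rate. Afterwards the bump spreads diffusively (σ_η, σ_ζ grow slowly) while
the mean information μ_ζ creeps upward. The stationary analysis of the same
kernel:

```r
pc_stationary(kernel)
#> <pc_stationary> lam = 2.1219284 (rho_X* = 0.0471269), peak at (0.9322, 19.92)
#>   1801 sweeps, residual 9.96e-11
pc_fitness_argmax(params)[c("eta", "zeta")]
#> $eta   [1] 1
#> $zeta  [1] 20.27528
```

The leading eigenvalue 2.12 implies a stationary food concentration
γ₀/(k₀λ) ≈ 4.7%, and the stationary distribution peaks near the fitness
maximum — the homochiral (η ≈ 1), high-information (ζ ≈ 20) corner where the
limiting factor f halts further information growth. On the continuous domain
the fitness maximum sits at exactly η = 1, ζ ≈ 20.3.

Four reference scenario configurations are shipped in
`inst/extdata/scenario_{a,b,c,d}.yaml`, and `inst/cli/protocell2d.R` is a
thin command-line front-end (`simulate`, `stationary`, `diffusion`,
`stages`) over the same functions.

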