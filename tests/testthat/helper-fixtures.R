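# Shared fixtures, built lazily once per test run.
.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

# small grid + resolvable kernel, moderate sparsity
fx_tiny <- function() fx_get("tiny", function() {
  grid <- pc_grid(20, 25)
  params <- pc_params(eps_eta = 0.3, eps_zeta = 2.4, rho0 = 1e9, z = 1e-3)
  list(grid = grid, params = params, kernel = pc_kernel(grid, params))
})

# flat-rate kernel: ka = gamma = 1 everywhere
fx_flat <- function() fx_get("flat", function() {
  grid <- pc_grid(20, 25)
  params <- pc_params(b_eta = 0, a_zeta = 0, b_zeta = 0, g = 0, f = 0,
                      eps_eta = 0.3, eps_zeta = 2.4, rho0 = 1e9, z = 1e-3)
  list(grid = grid, params = params, kernel = pc_kernel(grid, params))
})

# fine grid that resolves the mutation scale (for discrete-kernel moments)
fx_resolved <- function() fx_get("resolved", function() {
  grid <- pc_grid(201, 2)
  params <- pc_params(eps_eta = 0.02, eps_zeta = 0.02, L = 2)
  list(grid = grid, params = params, kernel = pc_kernel(grid, params))
})

# reference-parameter kernel at d = 50 for stationary checks
fx_d50 <- function() fx_get("d50", function() {
  grid <- pc_grid(50, 25)
  params <- pc_params(eps_eta = 0.01, eps_zeta = 0.01)
  list(grid = grid, params = params, kernel = pc_kernel(grid, params))
})

# trapezoid integral of f over [lo, hi] with m panels (independent oracle)
trap_int <- function(f, lo, hi, m = 4000) {
  x <- seq(lo, hi, length.out = m + 1)
  y <- f(x)
  (hi - lo) / m * (sum(y) - (y[1] + y[m + 1]) / 2)
}
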