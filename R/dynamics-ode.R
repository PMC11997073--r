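#' Continuous (real-valued) system state
#'
#' Holds the protocell concentration field over the trait grid plus the food
#' and waste concentrations, all in protocell units. In the closed recycling
#' model the total matter `rho_X + rho_W + sum(U * w)` is an invariant of the
#' dynamics (for stoichiometry `n = 1`).
#'
#' @param grid A [pc_grid()] object.
#' @param params A [pc_params()] object; `U00 / rho0` of total matter is
#'   placed (as concentration) at the node nearest the trait origin, the rest
#'   is food. Total concentration is normalized to 1.
#' @return A `pc_real_state`: `U` (per-node concentration vector), `rho_X`,
#'   `rho_W`, `t`.
#' @export
pc_real_state <- function(grid, params) {
  stopifnot(inherits(grid, "pc_grid"), inherits(params, "pc_params"))
  n <- grid$d^2
  U <- numeric(n)
  k <- pc_nearest_node(grid, 0, 0)
  u0 <- params$U00 / params$rho0
  U[k] <- u0 / grid$w[k] # concentration: integral over the cell equals u0
  structure(list(U = U, rho_X = 1 - u0, rho_W = 0, t = 0),
            class = "pc_real_state")
}

#' One forward-Euler step of the continuous dynamics
#'
#' Advances the integrodifferential model one step: the birth term feeds the
#' population through the sparse mutation kernel at rate
#' `k0 * rho_X * ka(source)`, protocells decay into waste at rate
#' `gamma0 * gamma(node)`, and waste recycles into food at rate `s`. Any
#' field driven negative by the explicit step is clamped to zero and the
#' clamped mass debited from the food pool, so the closed-model invariant is
#' preserved exactly (to round-off) at every step.
#'
#' @param state A `pc_real_state`.
#' @param kernel A [pc_kernel()] built on the same grid.
#' @param params A [pc_params()] object.
#' @param dt Step size (default `params$dt`).
#' @return The updated `pc_real_state`.
#' @export
pc_step_euler <- function(state, kernel, params, dt = params$dt) {
  stopifnot(inherits(state, "pc_real_state"), inherits(kernel, "pc_kernel"))
  grid <- kernel$grid
  if (length(state$U) != grid$d^2)
    pc_stop("state and kernel grids do not match", "pc_invalid_argument")
  w <- grid$w
  U <- state$U
  birth_flux <- params$k0 * state$rho_X * sum(kernel$ka * U * w)
  inflow <- params$k0 * state$rho_X *
    as.vector(kernel$M %*% (kernel$ka * w * U)) / w
  death <- params$gamma0 * kernel$gamma * U
  death_flux <- params$gamma0 * sum(kernel$gamma * U * w)
  U2 <- U + dt * (inflow - death)
  rho_W2 <- state$rho_W + dt * (-params$s * state$rho_W + death_flux)
  rho_X2 <- state$rho_X + dt * (-birth_flux + params$s * state$rho_W)
  # clamp-and-restore: deficits are debited from food (then waste) so the
  # invariant survives clamping exactly
  neg <- U2 < 0
  if (any(neg)) {
    rho_X2 <- rho_X2 + sum(U2[neg] * w[neg])
    U2[neg] <- 0
  }
  if (rho_W2 < 0) {
    rho_X2 <- rho_X2 + rho_W2
    rho_W2 <- 0
  }
  if (rho_X2 < 0) {
    rho_W2 <- rho_W2 + rho_X2
    rho_X2 <- 0
  }
  structure(list(U = U2, rho_X = rho_X2, rho_W = rho_W2, t = state$t + dt),
            class = "pc_real_state")
}

#' One step of the delta-peak reduced system
#'
#' While the whole population sits in a single narrow peak at the trait
#' origin, the full dynamics collapse to three scalar ODEs for the total
#' protocell amount, food and waste. This performs one forward-Euler step of
#' that reduced system (with the stoichiometry prefactor `n` on the food
#' equation).
#'
#' @param U0,rho_X,rho_W Nonnegative scalars.
#' @param params A [pc_params()] object.
#' @param dt Step size (default `params$dt`).
#' @return A named list `U0`, `rho_X`, `rho_W`.
#' @export
pc_reduced_step <- function(U0, rho_X, rho_W, params, dt = params$dt) {
  stopifnot(U0 >= 0, rho_X >= 0, rho_W >= 0)
  dU0 <- (params$k0 * rho_X - params$gamma0) * U0
  dX <- params$n * (-params$k0 * rho_X * U0 + params$s * rho_W)
  dW <- -params$s * rho_W + params$gamma0 * U0
  list(U0 = U0 + dt * dU0, rho_X = rho_X + dt * dX, rho_W = rho_W + dt * dW)
}

#' Duration of the initial exponential-growth stage
#'
#' Estimates the time for the initial protocell count to grow exponentially
#' to the order of the available food:
#' `t0 = ln(rho_X0 / U00) / (k0 * rho_X0 - gamma0)`. With the log ratio
#' capped by Earth-scale molecule counts and even a slow one-e-fold-per-year
#' replication rate, this stage is over in under a century - negligible on
#' geological time scales.
#'
#' @param rho_X0 Initial food amount (same units as `U00`).
#' @param U00 Initial protocell amount, `0 < U00 <= rho_X0`.
#' @param k0 Replication rate per unit food.
#' @param gamma0 Decay rate; must satisfy `k0 * rho_X0 > gamma0` for growth.
#' @return Estimated stage duration (in steps, or whatever time unit `k0` and
#'   `gamma0` are expressed in).
#' @examples
#' pc_estimate_t0(1e9, 1e3, 0.1, 0.01)
#' @export
pc_estimate_t0 <- function(rho_X0, U00, k0, gamma0) {
  stopifnot(rho_X0 >= U00, U00 > 0)
  denom <- k0 * rho_X0 - gamma0
  if (denom <= 0)
    pc_stop("no growth: k0 * rho_X0 <= gamma0", "pc_no_growth")
  log(rho_X0 / U00) / denom
}

#' Mean protocell lifespan implied by the decay rate
#'
#' With decay treated as a Poisson process at rate `gamma0` per step, the
#' mean lifespan is `dt / gamma0` time units.
#'
#' @param gamma0 Baseline decay rate per step.
#' @param dt Duration of one step in the interpreting time unit (default 1).
#' @return Mean lifespan in the same unit as `dt`.
#' @examples
#' pc_mean_lifespan(0.01) # 100 (days, if one step is one day)
#' @export
pc_mean_lifespan <- function(gamma0, dt = 1) {
  stopifnot(gamma0 > 0, dt > 0)
  dt / gamma0
}

#' Information capacity implied by the domain bound
#'
#' If the information coordinate is read as the natural logarithm of the
#' number of bits passed per generation, the upper bound `L` corresponds to
#' `exp(L)` bits, i.e. `exp(L)/8` bytes.
#'
#' @param L Upper bound of the information coordinate.
#' @return Capacity in bytes.
#' @examples
#' pc_info_capacity(25) # about 1e10 bytes
#' @export
pc_info_capacity <- function(L) {
  stopifnot(L > 0)
  exp(L) / 8
}

# closed-model invariant of a real-valued state
pc_total_matter <- function(state, grid) {
  state$rho_X + state$rho_W + sum(state$U * grid$w)
}
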