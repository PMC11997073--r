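#' Initialize the integer-count state
#'
#' Places `U00` protocells at the node nearest the trait origin; all
#' remaining matter (`rho0 - U00` units) starts as food, no waste. Counts are
#' stored as doubles and kept exact; `rho0` must not exceed 2^53.
#'
#' @param grid A [pc_grid()] object.
#' @param params A [pc_params()] object (`rho0`, `U00` used).
#' @return A `pc_int_state`: `N_U` (per-node counts), `N_X`, `N_W`, `step`.
#' @export
pc_init_state <- function(grid, params) {
  stopifnot(inherits(grid, "pc_grid"), inherits(params, "pc_params"))
  if (params$rho0 <= params$U00)
    pc_stop("need rho0 > U00", "pc_invalid_argument")
  if (params$rho0 > 2^53)
    pc_stop("rho0 exceeds exact integer range of double precision (2^53)",
            "pc_invalid_argument")
  N_U <- numeric(grid$d^2)
  N_U[pc_nearest_node(grid, 0, 0)] <- round(params$U00)
  structure(list(N_U = N_U, N_X = round(params$rho0) - round(params$U00),
                 N_W = 0, step = 0L),
            class = "pc_int_state")
}

#' One tau-leap of the integer-count dynamics
#'
#' Fires one fixed-length leap of the reaction network (replication with
#' mutation, decay to waste, waste recycling) with all propensities evaluated
#' at the leap start:
#' \itemize{
#' \item births per source node: Poisson with mean
#'   `(k0 / rho0^n) * N_X^n * ka(src) * N_U(src) * dt`; each birth places one
#'   offspring at a target node drawn from the source's mutation masses
#'   (multinomial) and consumes one food unit;
#' \item deaths per node: Poisson with mean `gamma0 * gamma(node) * N_U * dt`,
#'   capped at the available count, moving protocells to waste;
#' \item recycling: Poisson with mean `s * N_W * dt`, capped at `N_W`, moving
#'   waste back to food.
#' }
#' If the drawn births exceed the available food, birth events are thinned
#' uniformly at random (multivariate hypergeometric across sources) to
#' consume exactly the food present and no more. The total count
#' `N_X + N_W + sum(N_U)` is conserved exactly at every step.
#'
#' @param state A `pc_int_state`.
#' @param kernel A [pc_kernel()] on the matching grid.
#' @param params A [pc_params()] object.
#' @return The updated `pc_int_state`.
#' @export
pc_step_tau <- function(state, kernel, params) {
  stopifnot(inherits(state, "pc_int_state"), inherits(kernel, "pc_kernel"))
  n <- kernel$grid$d^2
  if (length(state$N_U) != n)
    pc_stop("state and kernel grids do not match", "pc_invalid_argument")
  res <- pc_tau_leap_cpp(state$N_U, state$N_X, state$N_W,
                         kernel$ka, kernel$gamma, kernel$src_order,
                         kernel$targets, kernel$masses,
                         params$k0, params$rho0, params$n,
                         params$gamma0, params$s, params$dt)
  structure(list(N_U = res$N_U, N_X = res$N_X, N_W = res$N_W,
                 step = state$step + 1L),
            class = "pc_int_state")
}

#' Run a full simulation
#'
#' Repeatedly applies the stochastic tau-leaping stepper (or the
#' deterministic Euler stepper) from the standard initial state, recording
#' summary statistics (total population, trait means/widths, food and waste
#' percentages) at fixed intervals and full population snapshots on demand.
#' Runs are exactly reproducible: the trajectory is a deterministic function
#' of the kernel, parameters and seed.
#'
#' @param kernel A [pc_kernel()] object.
#' @param params A [pc_params()] object.
#' @param T_max Number of steps to run.
#' @param record_every Record summary statistics every this many steps.
#' @param snapshot_every Store a full population snapshot every this many
#'   steps (`Inf` = none; the final state is always kept).
#' @param seed RNG seed (default `params$seed`).
#' @param method `"tau"` (integer counts) or `"euler"` (real concentrations).
#' @return A `pc_trajectory`: `series` (a tibble with columns `t`, `U0`,
#'   `mu_eta`, `sigma_eta`, `mu_zeta`, `sigma_zeta`, `food_pct`,
#'   `waste_pct`), `snapshots` (list of `t` + sparse count/concentration
#'   fields), `final` (final state), and `manifest` (parameters, label, seed,
#'   method, conservation check).
#' @export
pc_simulate <- function(kernel, params, T_max,
                        record_every = 1L, snapshot_every = Inf,
                        seed = params$seed, method = c("tau", "euler")) {
  stopifnot(inherits(kernel, "pc_kernel"), inherits(params, "pc_params"),
            T_max >= 1)
  method <- match.arg(method)
  grid <- kernel$grid
  n <- grid$d^2
  coords <- pc_node_coords(grid, seq_len(n))
  eta_n <- coords[, "eta"]
  zeta_n <- coords[, "zeta"]
  set.seed(seed)

  tau <- method == "tau"
  state <- if (tau) pc_init_state(grid, params) else
    pc_real_state(grid, params)
  total0 <- if (tau) params$rho0 else 1

  nrec <- floor(T_max / record_every) + 1L
  rec <- matrix(NA_real_, nrec, 8L,
                dimnames = list(NULL, c("t", "U0", "mu_eta", "sigma_eta",
                                        "mu_zeta", "sigma_zeta",
                                        "food_pct", "waste_pct")))
  snapshots <- list()
  max_dev <- 0
  ri <- 0L

  record <- function(state) {
    if (tau) {
      mass <- state$N_U
      food <- state$N_X; waste <- state$N_W; tt <- state$step
    } else {
      mass <- state$U * grid$w
      food <- state$rho_X; waste <- state$rho_W; tt <- state$t
    }
    U0 <- sum(mass)
    if (U0 > 0) {
      mu_e <- sum(eta_n * mass) / U0
      mu_z <- sum(zeta_n * mass) / U0
      s_e <- sqrt(max(0, sum(eta_n^2 * mass) / U0 - mu_e^2))
      s_z <- sqrt(max(0, sum(zeta_n^2 * mass) / U0 - mu_z^2))
    } else mu_e <- mu_z <- s_e <- s_z <- NA_real_
    dev <- abs(food + waste + U0 - total0) / total0
    max_dev <<- max(max_dev, dev)
    ri <<- ri + 1L
    rec[ri, ] <<- c(tt, U0, mu_e, s_e, mu_z, s_z,
                    100 * food / total0, 100 * waste / total0)
  }

  sparse_field <- function(state) {
    v <- if (tau) state$N_U else state$U
    idx <- which(v > 0)
    list(t = if (tau) state$step else state$t, nodes = idx, values = v[idx])
  }

  record(state)
  for (step in seq_len(T_max)) {
    state <- if (tau) pc_step_tau(state, kernel, params) else
      pc_step_euler(state, kernel, params)
    if (step %% record_every == 0) record(state)
    if (is.finite(snapshot_every) && step %% snapshot_every == 0)
      snapshots[[length(snapshots) + 1L]] <- sparse_field(state)
  }

  structure(
    list(series = as_tibble(as.data.frame(rec[seq_len(ri), , drop = FALSE])),
         snapshots = snapshots,
         final = state,
         manifest = list(params = unclass(params), d = grid$d, L = grid$L,
                         T_max = T_max, record_every = record_every,
                         snapshot_every = snapshot_every,
                         label = pc_run_label(params, grid$d),
                         seed = seed, method = method,
                         invariant_check = list(
                           exact = max_dev == 0,
                           max_deviation = max_dev))),
    class = "pc_trajectory")
}

#' @export
print.pc_trajectory <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<pc_trajectory> %s run '%s', %d steps, seed %d\n",
              m$method, m$label, m$T_max, m$seed))
  fin <- x$series[nrow(x$series), ]
  cat(sprintf("  final: U0 = %.4g, mu_eta = %.3f, food = %.2f%%\n",
              fin$U0, fin$mu_eta, fin$food_pct))
  invisible(x)
}
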