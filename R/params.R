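#' Model parameters
#'
#' Collects and validates every rate, shape, mutation and asymmetry parameter
#' of the protocell evolution model. Defaults are the reference parameter set
#' used throughout: one time step is treated as one evolution epoch
#' (`dt = 1`), so e.g. `gamma0 = 0.01` with a one-day epoch means a mean
#' protocell lifespan of `1/gamma0 = 100` days.
#'
#' @param k0 Total replication rate at the trait origin, per step per unit
#'   food concentration. In integer-count (tau-leaping) mode the propensities
#'   use `k0 / rho0^n` so that the same value works on counts.
#' @param gamma0 Baseline decay rate at the origin, per step.
#' @param s Waste-recycling rate, per step.
#' @param n Food-stoichiometry exponent (integer >= 1); number of food units
#'   consumed simultaneously per replication. Default 1.
#' @param b_eta Second derivative of the normalized replication rate with
#'   respect to enantiomeric excess at the origin.
#' @param a_zeta First derivative of the normalized replication rate with
#'   respect to the scaled information coordinate at the origin (0 = no
#'   deterministic information drift).
#' @param b_zeta Second derivative of the normalized replication rate with
#'   respect to the scaled information coordinate at the origin.
#' @param eps_eta,eps_zeta Mutation scales (standard widths of the
#'   truncated-Gaussian offspring displacement) in the two trait directions.
#'   Must be small: `eps_eta < 0.5` and `eps_zeta < L/10`.
#' @param g Global chiral asymmetry factor, a small linear bias in the decay
#'   rate favoring one handedness; must satisfy `0 <= g < 1`.
#' @param f Information-limiting factor keeping the stationary point off the
#'   upper information boundary (an eighth-power penalty in the decay rate).
#' @param c Scaling coefficient for the information coordinate,
#'   `x = c * zeta`; defaults to `3 / (2 L)` so that `zeta = 2L/3` maps to
#'   `x = 1`.
#' @param z Kernel sparsification threshold in `(0, 1)`: discrete mutation
#'   masses below `z` are dropped (and the rest renormalized).
#' @param rho0 Total number of molecules in the closed system (the exact
#'   invariant of the integer-count dynamics). Must exceed `U00` and, for
#'   integer runs, stay within exact double-precision integer range (2^53).
#' @param U00 Initial number of protocells placed at the node nearest the
#'   trait origin.
#' @param dt Step size; fixed at 1 epoch by convention.
#' @param seed Integer RNG seed recorded with every run.
#' @param L Upper bound of the information coordinate (used to default `c`
#'   and to validate `eps_zeta`).
#' @return A validated `pc_params` object (a named list).
#' @examples
#' p <- pc_params()
#' p$k0
#' @export
pc_params <- function(k0 = 0.1, gamma0 = 0.01, s = 1, n = 1,
                      b_eta = 1, a_zeta = 0, b_zeta = 1,
                      eps_eta = 0.005, eps_zeta = 0.005,
                      g = 0.002, f = 1000, c = NULL, z = 1e-5,
                      rho0 = 1e18, U00 = 1e3, dt = 1, seed = 1L,
                      L = 25) {
  if (is.null(c)) c <- 3 / (2 * L)
  num1 <- function(x, nm) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
      pc_stop(sprintf("`%s` must be a single finite number", nm),
              "pc_invalid_argument")
    as.numeric(x)
  }
  for (nm in c("k0", "gamma0", "s", "n", "b_eta", "a_zeta", "b_zeta",
               "eps_eta", "eps_zeta", "g", "f", "c", "z", "rho0", "U00",
               "dt", "L"))
    assign(nm, num1(get(nm), nm))
  if (eps_eta <= 0 || eps_eta >= 0.5)
    pc_stop("`eps_eta` must be in (0, 0.5): mutations must be small",
            "pc_invalid_argument")
  if (eps_zeta <= 0 || eps_zeta >= L / 10)
    pc_stop("`eps_zeta` must be in (0, L/10): mutations must be small",
            "pc_invalid_argument")
  if (gamma0 <= 0) pc_stop("`gamma0` must be > 0", "pc_invalid_argument")
  if (k0 <= 0) pc_stop("`k0` must be > 0", "pc_invalid_argument")
  if (s <= 0) pc_stop("`s` must be > 0", "pc_invalid_argument")
  if (!(rho0 > U00 && U00 >= 1))
    pc_stop("need rho0 > U00 >= 1", "pc_invalid_argument")
  if (z <= 0 || z >= 1)
    pc_stop("`z` must be in (0, 1)", "pc_invalid_argument")
  if (n != round(n) || n < 1)
    pc_stop("`n` must be an integer >= 1", "pc_invalid_argument")
  if (g < 0 || g >= 1)
    pc_stop("`g` must be in [0, 1): decay rate must stay positive",
            "pc_invalid_argument")
  if (f < 0) pc_stop("`f` must be >= 0", "pc_invalid_argument")
  structure(
    list(k0 = k0, gamma0 = gamma0, s = s, n = n,
         b_eta = b_eta, a_zeta = a_zeta, b_zeta = b_zeta,
         eps_eta = eps_eta, eps_zeta = eps_zeta,
         g = g, f = f, c = c, z = z,
         rho0 = rho0, U00 = U00, dt = dt, seed = as.integer(seed), L = L),
    class = "pc_params")
}

#' @export
print.pc_params <- function(x, ...) {
  cat("<pc_params>\n")
  flds <- setdiff(names(x), "seed")
  cat(paste0("  ", flds, " = ", vapply(x[flds], function(v) sprintf("%g", v),
                                       character(1)), collapse = "\n"), "\n")
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
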