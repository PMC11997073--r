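# Fine 1-D trapezoid quadrature of g(src) * density(target | src) over the
# mutation window around a target coordinate, clipped to [lo, hi].
pc_axis_integral <- function(target, g, dens, eps, lo, hi, nsub = 20) {
  a <- max(lo, target - 10 * eps)
  b <- min(hi, target + 10 * eps)
  src <- seq(a, b, length.out = max(51L, ceiling((b - a) / (eps / nsub)) + 1L))
  h <- src[2] - src[1]
  f <- g(src) * dens(src)
  h * (sum(f) - (f[1] + f[length(f)]) / 2)
}

pc_diffusion_tibble <- function(grid, vals) {
  coords <- pc_node_coords(grid, seq_len(grid$d^2))
  tibble(eta = coords[, "eta"], zeta = coords[, "zeta"], !!!vals)
}

#' Convection-diffusion coefficients from the full moment integrals
#'
#' In the small-mutation regime the integrodifferential dynamics reduce to a
#' convection-diffusion equation (in rescaled time `tau = gamma0 * t`) with a
#' creation/destruction term `alpha - gamma`, drift vector
#' `(beta_eta, beta_zeta)` and diffusion tensor `delta`. This computes the
#' defining moment integrals of `ka(src) * p(target | src)` over the source
#' coordinates, per target node, at food factor \eqn{r = (k_0/\gamma_0)\rho_X}.
#'
#' The mutation density and the rate forms are separable, so each
#' two-dimensional moment factorizes into per-axis integrals; these are
#' evaluated by fine trapezoid quadrature of the continuous truncated-normal
#' density over the mutation window (resolution set by the mutation scale,
#' independent of the grid spacing).
#'
#' @param kernel A [pc_kernel()] object (its grid and parameters are used).
#' @param rho_X Food concentration (protocell units, total normalized to 1).
#' @return A tibble with one row per grid node: `eta`, `zeta`, `alpha`,
#'   `beta_eta`, `beta_zeta`, `delta_ee`, `delta_ez`, `delta_zz`, and the
#'   plain second moments of the mutation density `eps2_eta`, `eps2_zeta`
#'   (which equal `eps^2/2` away from the edges). The food factor `r` is
#'   attached as an attribute.
#' @export
pc_diffusion_full <- function(kernel, rho_X) {
  stopifnot(inherits(kernel, "pc_kernel"), rho_X >= 0)
  grid <- kernel$grid
  p <- kernel$params
  r <- (p$k0 / p$gamma0) * rho_X
  k_eta <- function(e) 1 + p$b_eta * e^2 / 2
  k_zeta <- function(zz) {
    x <- p$c * zz
    1 + p$a_zeta * x + p$b_zeta * x^2 / 2
  }
  one <- function(src) rep(1, length(src))
  # per-axis moment integrals at each node of the axis
  mom_axis <- function(nodes, eps, lo, hi, gfun, dens) {
    s0 <- s1 <- s2 <- p0 <- p2 <- numeric(length(nodes))
    for (i in seq_along(nodes)) {
      tg <- nodes[i]
      dn <- function(src) dens(tg, src)
      s0[i] <- pc_axis_integral(tg, gfun, dn, eps, lo, hi)
      s1[i] <- pc_axis_integral(tg, function(s) (s - tg) * gfun(s), dn,
                                eps, lo, hi)
      s2[i] <- pc_axis_integral(tg, function(s) (s - tg)^2 * gfun(s), dn,
                                eps, lo, hi)
      p0[i] <- pc_axis_integral(tg, one, dn, eps, lo, hi)
      p2[i] <- pc_axis_integral(tg, function(s) (s - tg)^2, dn, eps, lo, hi)
    }
    list(s0 = s0, s1 = s1, s2 = s2, p0 = p0, p2 = p2)
  }
  de <- function(t, s) pc_density_eta(t, s, p$eps_eta)
  dz <- function(t, s) pc_density_zeta(t, s, p$eps_zeta, grid$L)
  E <- mom_axis(grid$eta, p$eps_eta, -1, 1, k_eta, de)
  Z <- mom_axis(grid$zeta, p$eps_zeta, 0, grid$L, k_zeta, dz)
  ij <- pc_node_ij(seq_len(grid$d^2), grid$d)
  i <- ij[, "i"]; j <- ij[, "j"]
  out <- pc_diffusion_tibble(grid, list(
    alpha = r * E$s0[i] * Z$s0[j],
    beta_eta = r * E$s1[i] * Z$s0[j],
    beta_zeta = r * E$s0[i] * Z$s1[j],
    delta_ee = r * E$s2[i] * Z$s0[j],
    delta_ez = r * E$s1[i] * Z$s1[j],
    delta_zz = r * E$s0[i] * Z$s2[j],
    eps2_eta = E$p2[i] * Z$p0[j],
    eps2_zeta = E$p0[i] * Z$p2[j]))
  attr(out, "r") <- r
  out
}

#' Convection-diffusion coefficients in small-mutation closed form
#'
#' The leading-order closed forms of the coefficient fields:
#' `alpha = r * ka`, drift `beta = (r/2) * grad(ka) * eps^2` (the drift
#' points along the local fitness-rate gradient), diagonal diffusion
#' `delta = (r/2) * ka * eps^2`, zero cross term. Derivatives of the
#' separable rate form are analytic.
#'
#' @param grid A [pc_grid()] object.
#' @param params A [pc_params()] object.
#' @param rho_X Food concentration.
#' @return A tibble shaped like [pc_diffusion_full()] (without the plain
#'   second-moment columns).
#' @export
pc_diffusion_approx <- function(grid, params, rho_X) {
  stopifnot(inherits(grid, "pc_grid"), inherits(params, "pc_params"),
            rho_X >= 0)
  p <- params
  r <- (p$k0 / p$gamma0) * rho_X
  coords <- pc_node_coords(grid, seq_len(grid$d^2))
  eta <- coords[, "eta"]; zeta <- coords[, "zeta"]
  x <- p$c * zeta
  ke <- 1 + p$b_eta * eta^2 / 2
  kz <- 1 + p$a_zeta * x + p$b_zeta * x^2 / 2
  dke <- p$b_eta * eta
  dkz <- p$c * (p$a_zeta + p$b_zeta * x)
  out <- pc_diffusion_tibble(grid, list(
    alpha = r * ke * kz,
    beta_eta = 0.5 * r * dke * kz * p$eps_eta^2,
    beta_zeta = 0.5 * r * ke * dkz * p$eps_zeta^2,
    delta_ee = 0.5 * r * ke * kz * p$eps_eta^2,
    delta_ez = rep(0, length(eta)),
    delta_zz = 0.5 * r * ke * kz * p$eps_zeta^2))
  attr(out, "r") <- r
  out
}

#' Moments of the discrete mutation kernel
#'
#' First and second moments of the stored (thresholded, renormalized)
#' per-source mutation masses, per source node. For sources deeper than
#' about six mutation scales from the edges on a grid that resolves the
#' mutation scale, the mean displacement vanishes and the second moments
#' approach `eps^2 / 2`.
#'
#' @param kernel A [pc_kernel()] object.
#' @return A tibble with one row per source node: `eta`, `zeta`, `m1_eta`,
#'   `m1_zeta` (mean offspring displacement) and `m2_eta`, `m2_zeta`
#'   (second moments of the displacement).
#' @export
pc_kernel_moments <- function(kernel) {
  stopifnot(inherits(kernel, "pc_kernel"))
  grid <- kernel$grid
  n <- grid$d^2
  coords <- pc_node_coords(grid, seq_len(n))
  m1e <- m1z <- m2e <- m2z <- numeric(n)
  for (s in seq_len(n)) {
    tg <- kernel$targets[[s]]
    m <- kernel$masses[[s]]
    de <- coords[tg, "eta"] - coords[s, "eta"]
    dz <- coords[tg, "zeta"] - coords[s, "zeta"]
    m1e[s] <- sum(de * m); m1z[s] <- sum(dz * m)
    m2e[s] <- sum(de^2 * m); m2z[s] <- sum(dz^2 * m)
  }
  tibble(eta = coords[, "eta"], zeta = coords[, "zeta"],
         m1_eta = m1e, m1_zeta = m1z, m2_eta = m2e, m2_zeta = m2z)
}
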