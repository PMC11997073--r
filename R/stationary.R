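#' Leading eigenpair of the stationary operator
#'
#' At a stationary point the trait distribution solves a Fredholm integral
#' eigenproblem: the operator that sends a distribution `u` through the
#' replication kernel weighted by `ka(source)` and divides by the local decay
#' rate `gamma(target)` must return `lambda * u`, where
#' `lambda = gamma0 / (k0 * rho_X)` fixes the stationary food concentration.
#' The leading eigenpair is computed by power iteration on the discretized
#' operator (the operator is sparse; a dense eigendecomposition at
#' `d^2 x d^2` would be prohibitive), starting from a uniform positive vector
#' that is guaranteed to overlap the nonnegative leading eigenvector.
#'
#' Under small mutation scales the leading eigenvalue is well approximated by
#' the maximum of the fitness map `ka/gamma`, and the eigenvector peaks near
#' the fitness maximum (see [pc_fitness_map()]).
#'
#' @param kernel A [pc_kernel()] object.
#' @param tol Convergence tolerance on the change of the eigenvalue estimate
#'   between sweeps.
#' @param max_iter Maximum number of sweeps; exceeding it raises a
#'   `pc_no_convergence` error carrying the last iterate.
#' @param v0 Optional nonnegative starting vector (length `d^2`).
#' @return A `pc_stationary` object: `u` (leading eigenvector, nonnegative,
#'   L2-normalized over the domain), `lam` (leading eigenvalue of the
#'   `ka p / gamma` operator), `lam_tilde` (`k0 * lam`, the `gamma0 / rho_X`
#'   scaling), `rho_X_star` (implied stationary food concentration
#'   `gamma0 / (k0 lam)`), `peak` (coordinates of the eigenvector maximum),
#'   `iterations`, `residual`.
#' @export
pc_stationary <- function(kernel, tol = 1e-10, max_iter = 1e5, v0 = NULL) {
  stopifnot(inherits(kernel, "pc_kernel"), tol > 0)
  grid <- kernel$grid
  n <- grid$d^2
  w <- grid$w
  p <- kernel$params
  kaw <- kernel$ka * w
  inv_gw <- 1 / (kernel$gamma * w)
  l2 <- function(v) sqrt(sum(v^2 * w))
  v <- if (is.null(v0)) rep(1, n) else {
    stopifnot(length(v0) == n, all(v0 >= 0), any(v0 > 0))
    v0
  }
  v <- v / l2(v)
  lam_prev <- NA_real_
  res <- Inf
  for (it in seq_len(max_iter)) {
    Av <- inv_gw * as.vector(kernel$M %*% (kaw * v))
    lam <- sum(v * Av * w) # weighted Rayleigh quotient
    v <- Av / l2(Av)
    res <- if (is.na(lam_prev)) Inf else abs(lam - lam_prev)
    if (res <= tol) {
      peak_node <- which.max(v)
      return(structure(
        list(u = v, lam = lam, lam_tilde = p$k0 * lam,
             rho_X_star = p$gamma0 / (p$k0 * lam),
             peak = pc_node_coords(grid, peak_node),
             peak_node = peak_node,
             iterations = it, residual = res),
        class = "pc_stationary"))
    }
    lam_prev <- lam
  }
  pc_stop(sprintf("power iteration did not converge in %d sweeps", max_iter),
          "pc_no_convergence", last_u = v, last_lam = lam_prev,
          residual = res)
}

#' @export
print.pc_stationary <- function(x, ...) {
  cat(sprintf(
    "<pc_stationary> lam = %.8g (rho_X* = %.6g), peak at (%.4g, %.4g)\n",
    x$lam, x$rho_X_star, x$peak[1, "eta"], x$peak[1, "zeta"]))
  cat(sprintf("  %d sweeps, residual %.3g\n", x$iterations, x$residual))
  invisible(x)
}
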