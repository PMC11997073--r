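#' Discretize the two-trait domain
#'
#' Builds a node-centered `d` x `d` grid over the protocell trait domain
#' \eqn{[-1, 1] \times [0, L]}, where the first coordinate is the enantiomeric
#' excess \eqn{\eta} (\eqn{-1} = pure D, \eqn{+1} = pure L, 0 = racemic) and
#' the second is the inherited-information coordinate \eqn{\zeta}. Nodes
#' include the domain endpoints so that the homochiral states \eqn{\eta = \pm 1}
#' are representable. Trapezoidal quadrature weights are attached per node;
#' they reproduce the domain area \eqn{2L} exactly.
#'
#' Nodes are indexed column-major with \eqn{\eta} varying fastest: node
#' \eqn{k = (j - 1) d + i} holds \eqn{(\eta_i, \zeta_j)}.
#'
#' @param d Integer number of nodes per axis (at least 2).
#' @param L Positive upper bound of the information coordinate.
#' @return A `pc_grid` object: node coordinates `eta`, `zeta` (length `d`
#'   each), spacings `d_eta`, `d_zeta`, per-axis trapezoid weights `w_eta`,
#'   `w_zeta`, and the flattened per-node weight vector `w` (length `d^2`).
#' @examples
#' g <- pc_grid(20, 25)
#' sum(g$w) # domain area 2 * L = 50
#' @export
pc_grid <- function(d, L) {
  if (length(d) != 1L || !is.finite(d) || d != round(d) || d < 2)
    pc_stop("`d` must be a single integer >= 2", "pc_invalid_argument")
  if (length(L) != 1L || !is.finite(L) || L <= 0)
    pc_stop("`L` must be a single positive number", "pc_invalid_argument")
  d <- as.integer(d)
  # integer numerators make eta bitwise mirror-symmetric: eta[i] == -eta[d+1-i]
  eta <- (2 * (0:(d - 1)) - (d - 1)) / (d - 1)
  zeta <- (0:(d - 1)) * L / (d - 1)
  d_eta <- 2 / (d - 1)
  d_zeta <- L / (d - 1)
  trap <- function(h, n) h * c(0.5, rep(1, n - 2L), 0.5)
  w_eta <- trap(d_eta, d)
  w_zeta <- trap(d_zeta, d)
  structure(
    list(d = d, L = L, eta = eta, zeta = zeta,
         d_eta = d_eta, d_zeta = d_zeta,
         w_eta = w_eta, w_zeta = w_zeta,
         w = as.vector(outer(w_eta, w_zeta))),
    class = "pc_grid")
}

#' @export
print.pc_grid <- function(x, ...) {
  cat(sprintf("<pc_grid> %d x %d nodes on [-1, 1] x [0, %g]\n", x$d, x$d, x$L))
  cat(sprintf("  spacings: d_eta = %.6g, d_zeta = %.6g\n", x$d_eta, x$d_zeta))
  invisible(x)
}

# node index <-> (i, j) helpers; column-major, eta fastest
pc_node_ij <- function(k, d) {
  i <- (k - 1L) %% d + 1L
  j <- (k - 1L) %/% d + 1L
  cbind(i = i, j = j)
}

pc_node_index <- function(i, j, d) (j - 1L) * d + i

# coordinates of node(s) k
pc_node_coords <- function(grid, k) {
  ij <- pc_node_ij(as.integer(k), grid$d)
  cbind(eta = grid$eta[ij[, "i"]], zeta = grid$zeta[ij[, "j"]])
}

# index of the node nearest a point
pc_nearest_node <- function(grid, eta, zeta) {
  i <- which.min(abs(grid$eta - eta))
  j <- which.min(abs(grid$zeta - zeta))
  pc_node_index(i, j, grid$d)
}

# eta-mirror permutation of node labels (involution)
pc_mirror_perm <- function(d) {
  ij <- pc_node_ij(seq_len(d * d), d)
  pc_node_index(d + 1L - ij[, "i"], ij[, "j"], d)
}

#' Deterministic run label
#'
#' Formats a compact run identifier from the model parameters and grid size,
#' following the scheme `d{d}k{b_eta}e{..}g{..}a{..}[i{10 a_zeta}]f{..}E`
#' where `e`, `g` and `a` carry the fractional digits of the mutation scale,
#' baseline decay rate and global asymmetry factor. The label is an opaque
#' identifier for bookkeeping; it is never parsed back into parameters.
#'
#' @param params A [pc_params()] object.
#' @param d Grid size used for the run.
#' @return A single string.
#' @examples
#' pc_run_label(pc_params(eps_eta = 0.005, eps_zeta = 0.005), d = 500)
#' @export
pc_run_label <- function(params, d) {
  stopifnot(inherits(params, "pc_params"))
  fd <- function(x) sub("^0\\.", "", sprintf("%g", x))
  paste0(
    "d", d,
    "k", sprintf("%g", params$b_eta),
    "e", fd(params$eps_eta),
    "g", fd(params$gamma0),
    "a", fd(params$g),
    if (params$a_zeta > 0) paste0("i", round(10 * params$a_zeta)),
    "f", sprintf("%g", params$f / 1000), "E")
}
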