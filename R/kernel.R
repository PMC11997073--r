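#' Truncated-Gaussian mutation density
#'
#' Probability density that a parent protocell at trait coordinates
#' `(eta_src, zeta_src)` produces offspring at `(eta, zeta)`. Mutations in
#' the two trait directions are independent; each factor is a normal density
#' truncated to its domain interval with an erf-based edge normalization, so
#' the density integrates to exactly 1 over the domain for every source,
#' including sources at or near the edges.
#'
#' @param eta,zeta Offspring coordinates (vectorized).
#' @param eta_src,zeta_src Parent coordinates (scalars).
#' @param eps_eta,eps_zeta Positive mutation scales.
#' @param L Upper bound of the information coordinate.
#' @return Nonnegative density values.
#' @examples
#' # at an interior source the peak density is 1 / (eps_eta * eps_zeta * pi)
#' pc_mutation_density(0, 12.5, 0, 12.5, 0.01, 0.01, 25)
#' @export
pc_mutation_density <- function(eta, zeta, eta_src, zeta_src,
                                eps_eta, eps_zeta, L) {
  if (eps_eta <= 0 || eps_zeta <= 0)
    pc_stop("mutation scales must be positive", "pc_invalid_argument")
  pe <- 2 * exp(-(eta - eta_src)^2 / eps_eta^2) /
    (eps_eta * sqrt(pi) *
       (erf((1 - eta_src) / eps_eta) + erf((1 + eta_src) / eps_eta)))
  pz <- 2 * exp(-(zeta - zeta_src)^2 / eps_zeta^2) /
    (eps_zeta * sqrt(pi) *
       (erf((L - zeta_src) / eps_zeta) + erf(zeta_src / eps_zeta)))
  pe * pz
}

# per-axis density factors (internal)
pc_density_eta <- function(eta, eta_src, eps) {
  2 * exp(-(eta - eta_src)^2 / eps^2) /
    (eps * sqrt(pi) * (erf((1 - eta_src) / eps) + erf((1 + eta_src) / eps)))
}
pc_density_zeta <- function(zeta, zeta_src, eps, L) {
  2 * exp(-(zeta - zeta_src)^2 / eps^2) /
    (eps * sqrt(pi) * (erf((L - zeta_src) / eps) + erf(zeta_src / eps)))
}

#' Normalized replication rate
#'
#' The separable normalized replication rate
#' \eqn{k_a(\eta, \zeta) = (1 + b_\eta \eta^2 / 2)(1 + a_\zeta x + b_\zeta x^2/2)}
#' with \eqn{x = c\,\zeta}. Even in \eqn{\eta} by L/D mirror symmetry and
#' equal to 1 at the origin.
#'
#' @param eta,zeta Trait coordinates (vectorized).
#' @param params A [pc_params()] object.
#' @return Replication rate values.
#' @export
pc_ka <- function(eta, zeta, params) {
  x <- params$c * zeta
  (1 + params$b_eta * eta^2 / 2) *
    (1 + params$a_zeta * x + params$b_zeta * x^2 / 2)
}

#' Normalized decay rate
#'
#' \eqn{\gamma(\eta, \zeta) = (1 - g\,\eta)(1 + f x^8 / 8!)} with
#' \eqn{x = c\,\zeta}; normalized so \eqn{\gamma(0, 0) = 1}. The small
#' linear factor `g` is the global chiral asymmetry (it shortens the lifespan
#' of one handedness); the eighth-power factor `f` penalizes very high
#' information content and keeps the stationary point off the upper boundary.
#'
#' @inheritParams pc_ka
#' @return Decay rate values (positive for `g < 1`).
#' @export
pc_gamma <- function(eta, zeta, params) {
  if (params$g >= 1)
    pc_stop("`g` must be < 1 for a positive decay rate", "pc_invalid_argument")
  x <- params$c * zeta
  (1 - params$g * eta) * (1 + params$f * x^8 / factorial(8))
}

# per-axis discrete mass matrices: column s = masses over targets for source s,
# each column normalized to sum 1 (trapezoid target weights times density).
pc_axis_masses <- function(nodes, w, src_nodes, eps, lower, upper, L = NULL,
                           axis = c("eta", "zeta")) {
  axis <- match.arg(axis)
  dens <- if (axis == "eta")
    outer(nodes, src_nodes, function(t, s) pc_density_eta(t, s, eps))
  else
    outer(nodes, src_nodes, function(t, s) pc_density_zeta(t, s, eps, L))
  m <- dens * w
  sweep(m, 2, colSums(m), "/")
}

#' Thresholded mutation masses for one source node
#'
#' Discretizes the mutation density for a single parent node: density at all
#' grid nodes times quadrature weights, normalized to total mass 1, entries
#' below the sparsification threshold `z` zeroed, and the survivors
#' renormalized to 1.
#'
#' @param grid A [pc_grid()] object.
#' @param params A [pc_params()] object (`eps_eta`, `eps_zeta`, `z` used).
#' @param eta_src,zeta_src Parent coordinates; snapped to the nearest node.
#' @return A list with `node` (source node index), `targets` (indices of
#'   surviving target nodes), `masses` (their probabilities, summing to 1).
#' @examples
#' g <- pc_grid(50, 25)
#' sm <- pc_source_masses(g, pc_params(eps_eta = 0.05, eps_zeta = 0.6), 0, 12.5)
#' sum(sm$masses)
#' @export
pc_source_masses <- function(grid, params, eta_src, zeta_src) {
  stopifnot(inherits(grid, "pc_grid"), inherits(params, "pc_params"))
  k <- pc_nearest_node(grid, eta_src, zeta_src)
  ij <- pc_node_ij(k, grid$d)
  me <- pc_density_eta(grid$eta, grid$eta[ij[, "i"]], params$eps_eta) *
    grid$w_eta
  mz <- pc_density_zeta(grid$zeta, grid$zeta[ij[, "j"]], params$eps_zeta,
                        grid$L) * grid$w_zeta
  me <- me / sum(me)
  mz <- mz / sum(mz)
  mass <- as.vector(outer(me, mz)) # node order: eta fastest, matches grid
  keep <- which(mass >= params$z)
  if (length(keep) == 0L)
    pc_stop("sparsification threshold removed all mutation mass for a source",
            "pc_degenerate_kernel")
  list(node = k, targets = keep, masses = mass[keep] / sum(mass[keep]))
}

#' Build the discretized sparse replication kernel
#'
#' For every source node, the mutation density is discretized into per-node
#' masses (density times trapezoid weight, normalized to 1), masses below the
#' threshold `z` are zeroed, and the survivors renormalized, guaranteeing
#' column-stochasticity of the stored kernel exactly. The normalized
#' replication rate and decay rate are evaluated at every node. The full
#' replication kernel is `k0 * ka(source) * p(target | source)`.
#'
#' Per-source target lists are stored in a fixed deterministic order alongside
#' a sparse matrix form; the explicit `src_order` iteration order is what
#' makes mirrored-kernel runs reproduce mirrored trajectories exactly (see
#' [pc_mirror_kernel()]).
#'
#' @param grid A [pc_grid()] object.
#' @param params A [pc_params()] object.
#' @return A `pc_kernel` object with fields `grid`, `params`, `targets`,
#'   `masses` (per-source lists), `M` (sparse `d^2 x d^2` matrix, columns =
#'   sources, columns sum to 1), `ka`, `gamma` (per-node vectors), `k0`,
#'   `nnz` (retained targets per source), `src_order`.
#' @examples
#' g <- pc_grid(20, 25)
#' k <- pc_kernel(g, pc_params(eps_eta = 0.2, eps_zeta = 2))
#' range(Matrix::colSums(k$M))
#' @export
pc_kernel <- function(grid, params) {
  stopifnot(inherits(grid, "pc_grid"), inherits(params, "pc_params"))
  d <- grid$d
  n <- d * d
  me <- pc_axis_masses(grid$eta, grid$w_eta, grid$eta, params$eps_eta,
                       axis = "eta")
  mz <- pc_axis_masses(grid$zeta, grid$w_zeta, grid$zeta, params$eps_zeta,
                       L = grid$L, axis = "zeta")
  z <- params$z
  max_me <- apply(me, 2, max)
  max_mz <- apply(mz, 2, max)
  targets <- vector("list", n)
  masses <- vector("list", n)
  for (sj in seq_len(d)) {
    mzc <- mz[, sj]
    cand_j <- which(mzc >= z / max(max_me))
    for (si in seq_len(d)) {
      mec <- me[, si]
      cand_i <- which(mec >= z / max_mz[sj])
      mm <- outer(mec[cand_i], mzc[cand_j]) # eta fastest
      keep <- mm >= z
      if (!any(keep))
        pc_stop("sparsification threshold removed all mutation mass",
                "pc_degenerate_kernel")
      tg <- pc_node_index(rep(cand_i, times = length(cand_j)),
                          rep(cand_j, each = length(cand_i)), d)
      s <- pc_node_index(si, sj, d)
      kp <- which(as.vector(keep))
      v <- as.vector(mm)[kp]
      targets[[s]] <- tg[kp]
      masses[[s]] <- v / sum(v)
    }
  }
  nnz <- lengths(targets)
  M <- sparseMatrix(i = unlist(targets),
                    j = rep.int(seq_len(n), nnz),
                    x = unlist(masses), dims = c(n, n))
  coords <- pc_node_coords(grid, seq_len(n))
  structure(
    list(grid = grid, params = params,
         targets = targets, masses = masses, M = M,
         ka = pc_ka(coords[, "eta"], coords[, "zeta"], params),
         gamma = pc_gamma(coords[, "eta"], coords[, "zeta"], params),
         k0 = params$k0, nnz = nnz,
         src_order = seq_len(n)),
    class = "pc_kernel")
}

#' @export
print.pc_kernel <- function(x, ...) {
  cat(sprintf("<pc_kernel> %d nodes, nnz/source in [%d, %d], z = %g\n",
              length(x$ka), min(x$nnz), max(x$nnz), x$params$z))
  invisible(x)
}

#' Mirror a kernel in the enantiomeric-excess direction
#'
#' Relabels every node by \eqn{\eta \mapsto -\eta} while preserving the
#' per-source storage order and permuting the source iteration order
#' accordingly. Running the tau-leaping stepper with the mirrored kernel and
#' the same seed consumes the RNG stream in matched positions, so (for
#' mirror-symmetric rates, `g = 0`) the resulting trajectory is the exact
#' mirror of the original - the discrete analogue of the statistical mirror
#' symmetry of the racemic model.
#'
#' @param kernel A [pc_kernel()] object.
#' @return A `pc_kernel` with permuted labels and iteration order.
#' @export
pc_mirror_kernel <- function(kernel) {
  stopifnot(inherits(kernel, "pc_kernel"))
  d <- kernel$grid$d
  n <- d * d
  perm <- pc_mirror_perm(d)
  k2 <- kernel
  # node m(s) of the mirrored kernel carries source s's data, targets relabeled
  k2$targets[perm] <- lapply(kernel$targets, function(t) perm[t])
  k2$masses[perm] <- kernel$masses
  k2$ka[perm] <- kernel$ka
  k2$gamma[perm] <- kernel$gamma
  k2$nnz[perm] <- kernel$nnz
  k2$M <- sparseMatrix(i = unlist(k2$targets),
                       j = rep.int(seq_len(n), k2$nnz[seq_len(n)]),
                       x = unlist(k2$masses), dims = c(n, n))
  k2$src_order <- perm[kernel$src_order]
  k2
}

#' Fitness map and its global maximum
#'
#' The fitness of a trait point is the replication-to-decay ratio
#' \eqn{f(\eta, \zeta) = k_a / \gamma}; its global maximum locates the
#' stationary trait peak and estimates the leading eigenvalue of the
#' stationary operator.
#'
#' @param kernel A [pc_kernel()] object.
#' @return A `pc_fitness_map`: per-node `values`, `argmax_nodes` (all tied
#'   maxima, in row-major node order), their coordinates `argmax_coords`, and
#'   `lambda_est` (the maximum value).
#' @export
pc_fitness_map <- function(kernel) {
  stopifnot(inherits(kernel, "pc_kernel"))
  values <- kernel$ka / kernel$gamma
  mx <- max(values)
  am <- which(values == mx)
  structure(
    list(values = values,
         argmax_nodes = am,
         argmax_coords = pc_node_coords(kernel$grid, am),
         lambda_est = mx),
    class = "pc_fitness_map")
}

#' Continuous maximizer of the fitness function
#'
#' Maximizes \eqn{k_a/\gamma} over the continuous domain
#' \eqn{[-1,1]\times[0,L]}. The model's rate forms are separable, so each
#' axis factor is maximized independently by golden-section search refined
#' over subintervals, with endpoints checked.
#'
#' @param params A [pc_params()] object.
#' @param L Domain bound for the information coordinate.
#' @return A list `eta`, `zeta`, `value`.
#' @examples
#' pc_fitness_argmax(pc_params()) # peak at eta = 1, zeta about 20.3
#' @export
pc_fitness_argmax <- function(params, L = params$L) {
  f_eta <- function(e) (1 + params$b_eta * e^2 / 2) / (1 - params$g * e)
  f_zeta <- function(zz) {
    x <- params$c * zz
    (1 + params$a_zeta * x + params$b_zeta * x^2 / 2) /
      (1 + params$f * x^8 / factorial(8))
  }
  max1d <- function(f, lo, hi) {
    # scan subintervals so local optima cannot hide from optimize()
    br <- seq(lo, hi, length.out = 65)
    best <- list(x = lo, y = f(lo))
    for (i in seq_len(length(br) - 1L)) {
      o <- optimize(f, c(br[i], br[i + 1L]), maximum = TRUE,
                    tol = .Machine$double.eps^0.5)
      if (o$objective > best$y) best <- list(x = o$maximum, y = o$objective)
    }
    for (xx in c(lo, hi)) if (f(xx) >= best$y) best <- list(x = xx, y = f(xx))
    best
  }
  be <- max1d(f_eta, -1, 1)
  bz <- max1d(f_zeta, 0, L)
  list(eta = be$x, zeta = bz$x, value = be$y * bz$y)
}
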