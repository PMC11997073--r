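#' Summary statistics of a population field
#'
#' Total population plus means and standard deviations of the trait
#' distribution. In `"quadrature"` mode `x` is a concentration field and
#' node masses are `x * w` (trapezoid weights); in `"counts"` mode `x` holds
#' integer counts used as-is. When the field is empty the moments are
#' undefined and reported as `NA` (not zero, to avoid spurious racemic
#' readings).
#'
#' @param x Nonnegative per-node field (length `d^2`).
#' @param grid A [pc_grid()] object.
#' @param mode `"quadrature"` (real concentrations) or `"counts"`.
#' @param rho_X,rho_W Optional food and waste amounts; if supplied,
#'   `food_pct` and `waste_pct` columns (percent of total matter) are added.
#' @param total Total matter used to express the percentages (defaults to
#'   `rho_X + rho_W + U0`).
#' @return A one-row tibble: `U0`, `mu_eta`, `sigma_eta`, `mu_zeta`,
#'   `sigma_zeta` (and optionally `food_pct`, `waste_pct`).
#' @export
pc_summarize <- function(x, grid, mode = c("quadrature", "counts"),
                         rho_X = NULL, rho_W = NULL, total = NULL) {
  stopifnot(inherits(grid, "pc_grid"), length(x) == grid$d^2)
  if (any(x < 0)) pc_stop("field must be nonnegative", "pc_invalid_argument")
  mode <- match.arg(mode)
  mass <- if (mode == "quadrature") x * grid$w else x
  coords <- pc_node_coords(grid, seq_len(grid$d^2))
  U0 <- sum(mass)
  if (U0 > 0) {
    mu_e <- sum(coords[, "eta"] * mass) / U0
    mu_z <- sum(coords[, "zeta"] * mass) / U0
    s_e <- sqrt(max(0, sum((coords[, "eta"] - mu_e)^2 * mass) / U0))
    s_z <- sqrt(max(0, sum((coords[, "zeta"] - mu_z)^2 * mass) / U0))
  } else mu_e <- mu_z <- s_e <- s_z <- NA_real_
  out <- tibble(U0 = U0, mu_eta = mu_e, sigma_eta = s_e,
                mu_zeta = mu_z, sigma_zeta = s_z)
  if (!is.null(rho_X) && !is.null(rho_W)) {
    if (is.null(total)) total <- rho_X + rho_W + U0
    out$food_pct <- 100 * rho_X / total
    out$waste_pct <- 100 * rho_W / total
  }
  out
}

#' Segment a food trajectory into evolution stages
#'
#' The closed model passes through up to four stages, visible in the food
#' fraction: a fast initial (hyperbolic-tangent-like) drop, then plateaus
#' separated by sustained drops as successively more efficient protocells
#' take over. Stage boundaries are detected heuristically as the steps where
#' a sustained drop ends and a plateau begins: the smoothed slope is
#' classified as "dropping" wherever it falls below `-drop_thresh`, runs
#' shorter than `min_run` are ignored, and each drop-to-plateau transition is
#' reported.
#'
#' @param food Numeric food series (percent or fraction), length >= 10.
#' @param window Half-width (in steps) of the centered smoothing window for
#'   the slope estimate.
#' @param drop_thresh Absolute slope threshold separating "drop" from
#'   "plateau"; defaults to 10% of the largest observed slope magnitude (so
#'   a perfectly flat series yields no boundaries).
#' @param min_run Minimum length of a sustained drop, in steps.
#' @return Integer vector of boundary indices (positions in `food`), sorted;
#'   empty if the series has no sustained drops.
#' @export
pc_detect_stages <- function(food, window = 3L, drop_thresh = NULL,
                             min_run = 3L) {
  if (length(food) < 10L)
    pc_stop("food series must have at least 10 points", "pc_invalid_argument")
  n <- length(food)
  # centered slope over +/- window steps
  lo <- pmax(1L, seq_len(n) - window)
  hi <- pmin(n, seq_len(n) + window)
  slope <- (food[hi] - food[lo]) / (hi - lo)
  if (is.null(drop_thresh)) drop_thresh <- 0.1 * max(abs(slope))
  dropping <- slope < -drop_thresh & drop_thresh > 0
  r <- rle(dropping)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  # boundary = last index of each sustained drop (the plateau starts next)
  bounds <- ends[keep]
  bounds <- bounds[bounds < n] # a drop still running at the end is no boundary
  as.integer(bounds)
}

#' Detect species as connected components of the population field
#'
#' As evolution proceeds, the single founding "bump" can split into several
#' non-connected groups in trait space - distinct species. Components are
#' found among nodes whose field value exceeds `threshold_frac` times the
#' field maximum, with 4-neighbor grid adjacency.
#'
#' @param x Nonnegative per-node field (length `d^2`).
#' @param grid A [pc_grid()] object.
#' @param threshold_frac Fraction of the field maximum below which nodes are
#'   treated as empty. The default `1e-3` separates bumps while ignoring the
#'   thin mutation halo.
#' @param mode Mass accounting as in [pc_summarize()].
#' @return A tibble with one row per component: `component`, `n_nodes`,
#'   `mass`, `centroid_eta`, `centroid_zeta`, `eta_min`, `eta_max`,
#'   `zeta_min`, `zeta_max`, ordered by decreasing mass.
#' @export
pc_detect_species <- function(x, grid, threshold_frac = 1e-3,
                              mode = c("quadrature", "counts")) {
  stopifnot(inherits(grid, "pc_grid"), length(x) == grid$d^2)
  if (any(x < 0)) pc_stop("field must be nonnegative", "pc_invalid_argument")
  mode <- match.arg(mode)
  d <- grid$d
  keep <- x > threshold_frac * max(x)
  if (!any(keep))
    return(tibble(component = integer(), n_nodes = integer(), mass = numeric(),
                  centroid_eta = numeric(), centroid_zeta = numeric(),
                  eta_min = numeric(), eta_max = numeric(),
                  zeta_min = numeric(), zeta_max = numeric()))
  idx <- which(keep)
  ij <- pc_node_ij(idx, d)
  # 4-neighbor edges among retained nodes
  in_mask <- logical(d * d); in_mask[idx] <- TRUE
  right <- idx[ij[, "i"] < d]
  right <- cbind(right, right + 1L)
  up <- idx[ij[, "j"] < d]
  up <- cbind(up, up + d)
  edges <- rbind(right[in_mask[right[, 2]], , drop = FALSE],
                 up[in_mask[up[, 2]], , drop = FALSE])
  gr <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx)))
  comp <- igraph::components(gr)
  memb <- comp$membership[as.character(idx)]
  mass <- if (mode == "quadrature") (x * grid$w)[idx] else x[idx]
  coords <- pc_node_coords(grid, idx)
  rows <- lapply(seq_len(comp$no), function(ci) {
    sel <- memb == ci
    m <- mass[sel]
    tibble(component = ci, n_nodes = sum(sel), mass = sum(m),
           centroid_eta = sum(coords[sel, "eta"] * m) / sum(m),
           centroid_zeta = sum(coords[sel, "zeta"] * m) / sum(m),
           eta_min = min(coords[sel, "eta"]),
           eta_max = max(coords[sel, "eta"]),
           zeta_min = min(coords[sel, "zeta"]),
           zeta_max = max(coords[sel, "zeta"]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mass), ]
  out$component <- seq_len(nrow(out))
  out
}
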