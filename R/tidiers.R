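#' Tidy a simulated trajectory
#'
#' Returns the per-step summary series as a tibble (`t`, `U0`, trait means
#' and widths, food and waste percentages).
#'
#' @param x A `pc_trajectory`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pc_trajectory <- function(x, ...) x$series

#' One-row summary of a simulated trajectory
#'
#' @param x A `pc_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: run label, seed, method, steps, final population
#'   and trait statistics, and the maximum deviation of the conserved total.
#' @export
glance.pc_trajectory <- function(x, ...) {
  fin <- x$series[nrow(x$series), ]
  tibble(label = x$manifest$label, seed = x$manifest$seed,
         method = x$manifest$method, steps = x$manifest$T_max,
         U0 = fin$U0, mu_eta = fin$mu_eta, sigma_eta = fin$sigma_eta,
         mu_zeta = fin$mu_zeta, sigma_zeta = fin$sigma_zeta,
         food_pct = fin$food_pct, waste_pct = fin$waste_pct,
         max_conservation_dev = x$manifest$invariant_check$max_deviation)
}

#' Tidy a stationary eigenpair
#'
#' Per-node leading-eigenvector values with trait coordinates.
#'
#' @param x A `pc_stationary` result.
#' @param grid The [pc_grid()] the kernel was built on.
#' @param ... Unused.
#' @return A tibble: `eta`, `zeta`, `u`.
#' @export
tidy.pc_stationary <- function(x, grid, ...) {
  coords <- pc_node_coords(grid, seq_along(x$u))
  tibble(eta = coords[, "eta"], zeta = coords[, "zeta"], u = x$u)
}

#' One-row summary of a stationary eigenpair
#'
#' @param x A `pc_stationary` result.
#' @param ... Unused.
#' @return A one-row tibble: eigenvalue, implied stationary food
#'   concentration, peak coordinates, iteration count and residual.
#' @export
glance.pc_stationary <- function(x, ...) {
  tibble(lam = x$lam, lam_tilde = x$lam_tilde, rho_X_star = x$rho_X_star,
         peak_eta = x$peak[1, "eta"], peak_zeta = x$peak[1, "zeta"],
         iterations = x$iterations, residual = x$residual)
}

#' Plot a trajectory
#'
#' Time series of the food/waste percentages and of the trait means and
#' widths, faceted by statistic.
#'
#' @param object A `pc_trajectory`.
#' @param stats Character vector of series columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pc_trajectory <- function(object,
                                   stats = c("food_pct", "mu_eta",
                                             "sigma_eta", "mu_zeta"), ...) {
  s <- object$series
  long <- do.call(rbind, lapply(stats, function(nm)
    data.frame(t = s$t, statistic = nm, value = s[[nm]])))
  long$statistic <- factor(long$statistic, levels = stats)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "step", y = NULL,
                  title = object$manifest$label)
}

#' Plot a stationary eigenvector
#'
#' Raster of the leading eigenvector over the trait domain.
#'
#' @param object A `pc_stationary` result.
#' @param grid The [pc_grid()] the kernel was built on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pc_stationary <- function(object, grid, ...) {
  df <- tidy.pc_stationary(object, grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eta, y = .data$zeta,
                                   fill = .data$u)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "enantiomeric excess", y = "inherited information",
                  fill = "u")
}

#' @importFrom rlang .data
NULL
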