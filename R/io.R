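pc_config_keys <- c(
  "k0", "gamma0", "s", "n", "b_eta", "a_zeta", "b_zeta",
  "eps_eta", "eps_zeta", "g", "f", "c", "z", "rho0", "U00", "dt", "seed", "L",
  "d", "T_max", "record_every", "snapshot_every", "out_dir")

#' Load a run configuration
#'
#' Reads a YAML configuration holding model parameters and run options. Every
#' key is optional; omitted parameters take the reference defaults of
#' [pc_params()] (an empty file yields the full default parameter set).
#' Unknown keys are an error, listed by name.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A list: `params` (a [pc_params()] object), `d`, `T_max`,
#'   `record_every`, `snapshot_every`, `out_dir`.
#' @examples
#' cfg <- pc_load_config(system.file("extdata", "scenario_a.yaml",
#'                                   package = "protocell2d"))
#' cfg$params$eps_eta
#' @export
pc_load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path))
      pc_stop(sprintf("config file not found: %s", path), "pc_config_error")
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), pc_config_keys)
  if (length(bad))
    pc_stop(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
            "pc_config_error")
  pargs <- raw[intersect(names(raw), names(formals(pc_params)))]
  params <- tryCatch(do.call(pc_params, pargs), error = function(e)
    pc_stop(paste0("invalid parameter in config: ", conditionMessage(e)),
            "pc_config_error"))
  grab <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else
    default
  list(params = params,
       d = as.integer(grab("d", 500L)),
       T_max = grab("T_max", 2e5),
       record_every = grab("record_every", 1L),
       snapshot_every = grab("snapshot_every", Inf),
       out_dir = grab("out_dir", "."))
}

#' Write and read a run manifest
#'
#' The manifest of a [pc_simulate()] trajectory (parameters, label, seed,
#' conservation check) serialized as JSON; round-trips losslessly.
#'
#' @param trajectory A `pc_trajectory` (for writing) .
#' @param path Destination / source file path.
#' @return `pc_write_manifest` returns `path` invisibly; `pc_read_manifest`
#'   the manifest list.
#' @export
pc_write_manifest <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "pc_trajectory"))
  jsonlite::write_json(trajectory$manifest, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pc_write_manifest
#' @export
pc_read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a trajectory series to CSV
#'
#' @param trajectory A `pc_trajectory`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
pc_write_series <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "pc_trajectory"))
  utils::write.csv(trajectory$series, path, row.names = FALSE)
  invisible(path)
}

#' Deterministic test fixtures
#'
#' Small, fully reproducible objects used by the test-suite and examples:
#' \describe{
#' \item{`"tiny-grid"`}{a 20 x 20 grid with a resolvable mutation kernel
#'   (list: `grid`, `params`, `kernel`).}
#' \item{`"two-bump"`}{a 40 x 40 grid carrying two Gaussian population bumps
#'   with known centers (list: `grid`, `U`, `centers`).}
#' \item{`"plateau-series"`}{a piecewise food-percentage series with known
#'   stage-change points (list: `food`, `change_points`).}
#' }
#'
#' @param kind One of `"tiny-grid"`, `"two-bump"`, `"plateau-series"`.
#' @param seed RNG seed controlling the (small) stochastic parts.
#' @return A list as described above.
#' @export
pc_fixture <- function(kind = c("tiny-grid", "two-bump", "plateau-series"),
                       seed = 1L) {
  if (!is.character(kind) || !kind[1] %in%
      c("tiny-grid", "two-bump", "plateau-series"))
    pc_stop(sprintf("unknown fixture kind: %s", kind[1]),
            "pc_invalid_argument")
  kind <- kind[1]
  set.seed(seed)
  if (kind == "tiny-grid") {
    grid <- pc_grid(20, 25)
    params <- pc_params(eps_eta = 0.3, eps_zeta = 2.4, rho0 = 1e9,
                        seed = seed)
    list(grid = grid, params = params, kernel = pc_kernel(grid, params))
  } else if (kind == "two-bump") {
    grid <- pc_grid(40, 25)
    coords <- pc_node_coords(grid, seq_len(grid$d^2))
    centers <- list(c(eta = -0.5, zeta = 10), c(eta = 0.5, zeta = 10))
    U <- numeric(grid$d^2)
    for (ct in centers)
      U <- U + exp(-((coords[, "eta"] - ct["eta"])^2 / (2 * 0.1^2) +
                       (coords[, "zeta"] - ct["zeta"])^2 / (2 * 1.5^2)))
    U[U < 1e-8 * max(U)] <- 0
    list(grid = grid, U = U, centers = centers)
  } else {
    # piecewise food series: initial drop, then two plateau/drop cycles
    seg <- function(from, to, len) seq(from, to, length.out = len)
    food <- c(seg(100, 40, 30), rep(40, 40), seg(40, 20, 20), rep(20, 40),
              seg(20, 8, 20), rep(8, 30))
    food <- food + 0.01 * rnorm(length(food))
    list(food = food, change_points = c(30L, 90L, 150L))
  }
}
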