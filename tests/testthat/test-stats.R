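test_that("moments of point masses and symmetric fields are exact", {
  g <- pc_grid(41, 25)
  U <- numeric(g$d^2)
  k <- protocell2d:::pc_nearest_node(g, 0.5, 10)
  U[k] <- 3
  s <- pc_summarize(U, g)
  expect_equal(s$mu_eta, 0.5)
  expect_equal(s$mu_zeta, 10)
  expect_equal(s$sigma_eta, 0)
  expect_equal(s$sigma_zeta, 0)

  # eta-symmetric field: zero mean excess
  coords <- protocell2d:::pc_node_coords(g, seq_len(g$d^2))
  Us <- exp(-coords[, "eta"]^2 - (coords[, "zeta"] - 12)^2)
  expect_lt(abs(pc_summarize(Us, g)$mu_eta), 1e-12)

  # two equal point masses at eta = +/-1: mu = 0, sigma = 1
  U2 <- numeric(g$d^2)
  U2[protocell2d:::pc_nearest_node(g, -1, 10)] <- 2
  U2[protocell2d:::pc_nearest_node(g, 1, 10)] <- 2
  s2 <- pc_summarize(U2, g, mode = "counts")
  expect_equal(s2$mu_eta, 0)
  expect_equal(s2$sigma_eta, 1)
})

test_that("a discretized Gaussian bump is summarized to its own parameters", {
  g <- pc_grid(101, 25)
  coords <- protocell2d:::pc_node_coords(g, seq_len(g$d^2))
  mu <- c(0.21, 9.4); sd <- c(0.15, 1.2)
  U <- exp(-(coords[, "eta"] - mu[1])^2 / (2 * sd[1]^2) -
             (coords[, "zeta"] - mu[2])^2 / (2 * sd[2]^2))
  s <- pc_summarize(U, g)
  expect_lt(abs(s$mu_eta - mu[1]), g$d_eta / 2)
  expect_lt(abs(s$mu_zeta - mu[2]), g$d_zeta / 2)
  expect_lt(abs(s$sigma_eta / sd[1] - 1), 0.02)
  expect_lt(abs(s$sigma_zeta / sd[2] - 1), 0.02)
})

test_that("an empty field yields absent moments, not zeros", {
  g <- pc_grid(20, 25)
  s <- pc_summarize(numeric(400), g)
  expect_identical(s$U0, 0)
  expect_true(is.na(s$mu_eta) && is.na(s$sigma_eta))
  expect_error(pc_summarize(rep(-1, 400), g), class = "pc_invalid_argument")
})

test_that("stage detection finds drop ends and ignores flat series", {
  # tanh-like single drop then plateau: exactly one boundary
  t <- 0:199
  food <- 50 + 50 * tanh((60 - t) / 15)
  b <- pc_detect_stages(food)
  expect_length(b, 1L)
  expect_lt(abs(b - 75), 20) # the drop flattens out around t ~ 75

  expect_length(pc_detect_stages(rep(42, 100)), 0L)
  expect_error(pc_detect_stages(c(1, 2, 3)), class = "pc_invalid_argument")

  fx <- pc_fixture("plateau-series")
  b3 <- pc_detect_stages(fx$food)
  expect_length(b3, 3L)
  expect_true(all(abs(b3 - fx$change_points) <= 2))
})

test_that("species detection separates bumps and respects the threshold", {
  fx <- pc_fixture("two-bump")
  sp <- pc_detect_species(fx$U, fx$grid)
  expect_identical(nrow(sp), 2L)
  expect_equal(sort(sp$centroid_eta), c(-0.5, 0.5), tolerance = 0.01)
  expect_equal(sp$centroid_zeta, c(10, 10), tolerance = 0.01)

  # a single bump is one component
  g <- fx$grid
  coords <- protocell2d:::pc_node_coords(g, seq_len(g$d^2))
  U1 <- exp(-(coords[, "eta"]^2 / 0.02) - (coords[, "zeta"] - 10)^2 / 4)
  expect_identical(nrow(pc_detect_species(U1, g)), 1L)

  # zero threshold on a strictly positive field: the whole grid connects
  sp0 <- pc_detect_species(U1 + 1e-9, g, threshold_frac = 0)
  expect_identical(nrow(sp0), 1L)
  expect_equal(sp0$n_nodes, g$d^2)
})

pure_diffusion_run <- function(eps, T_max, seed, grid) {
  p <- pc_params(eps_eta = eps, eps_zeta = eps, a_zeta = 0, b_eta = 0,
                 b_zeta = 0, g = 0, f = 0, L = 2, rho0 = 1e8, U00 = 1e7,
                 z = 1e-3, seed = seed)
  k <- pc_kernel(grid, p)
  pc_simulate(k, p, T_max = T_max, record_every = 50)$series
}

test_that("drift-free spreading is diffusive and scales as eps^2 * t", {
  grid <- pc_grid(101, 2)
  runs_fast <- lapply(1:10, function(s) pure_diffusion_run(0.04, 1500, s,
                                                          grid))
  runs_slow <- lapply(1:10, function(s) pure_diffusion_run(0.02, 6000, s,
                                                          grid))
  # halving the mutation scale requires 4x the time for equal widths
  w_fast <- mean(sapply(runs_fast, function(s) tail(s$sigma_eta, 1)))
  w_slow <- mean(sapply(runs_slow, function(s) tail(s$sigma_eta, 1)))
  expect_lt(abs(w_fast / w_slow - 1), 0.10)
  # log-log width growth has slope ~ 1/2 over the diffusive window
  slopes <- sapply(runs_slow, function(s) {
    win <- s$t >= 1000
    unname(coef(lm(log(s$sigma_eta[win]) ~ log(s$t[win])))[2])
  })
  expect_gt(mean(slopes), 0.4)
  expect_lt(mean(slopes), 0.6)
})
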