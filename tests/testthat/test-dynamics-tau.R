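test_that("the initial integer state splits matter as specified", {
  g <- pc_grid(20, 25)
  p <- pc_params(rho0 = 1e9, U00 = 1000)
  st <- pc_init_state(g, p)
  expect_identical(st$N_X, 999999000)
  expect_identical(sum(st$N_U), 1000)
  expect_identical(st$N_W, 0)
  expect_identical(st$N_X + st$N_W + sum(st$N_U), 1e9)
  # counts beyond the exact-integer range of doubles are refused
  expect_error(pc_init_state(g, pc_params(rho0 = 1e18, U00 = 1e3)),
               class = "pc_invalid_argument")
  p_bad <- pc_params(rho0 = 2000, U00 = 1000)
  p_bad$U00 <- 3000 # bypass constructor to hit the state check
  expect_error(pc_init_state(g, p_bad), class = "pc_invalid_argument")
})

test_that("total molecule count is conserved exactly over 10^4 leaps", {
  fx <- fx_tiny()
  tr <- pc_simulate(fx$kernel, fx$params, T_max = 1e4, record_every = 100)
  expect_true(tr$manifest$invariant_check$exact)
  expect_identical(tr$manifest$invariant_check$max_deviation, 0)
  st <- tr$final
  expect_identical(st$N_X + st$N_W + sum(st$N_U), fx$params$rho0)
  expect_true(all(st$N_U >= 0) && st$N_X >= 0 && st$N_W >= 0)
})

test_that("trajectories are bit-reproducible from the seed", {
  fx <- fx_tiny()
  t1 <- pc_simulate(fx$kernel, fx$params, T_max = 200, record_every = 20,
                    seed = 42)
  t2 <- pc_simulate(fx$kernel, fx$params, T_max = 200, record_every = 20,
                    seed = 42)
  t3 <- pc_simulate(fx$kernel, fx$params, T_max = 200, record_every = 20,
                    seed = 43)
  expect_identical(t1$series, t2$series)
  expect_identical(t1$final$N_U, t2$final$N_U)
  expect_false(identical(t1$series, t3$series))
})

test_that("an empty population only recycles waste into food", {
  fx <- fx_tiny()
  st <- pc_init_state(fx$grid, fx$params)
  st$N_U[] <- 0
  st$N_X <- 1e6
  st$N_W <- fx$params$rho0 - 1e6
  set.seed(5)
  st2 <- pc_step_tau(st, fx$kernel, fx$params)
  expect_true(all(st2$N_U == 0))
  expect_identical(st2$N_X + st2$N_W, st$N_X + st$N_W)
  expect_gte(st2$N_X, st$N_X) # recycling can only add food
})

test_that("the mean tau-leaping dynamics converge to the Euler limit at large counts", {
  g <- pc_grid(20, 25)
  p <- pc_params(eps_eta = 0.3, eps_zeta = 2.4, rho0 = 1e12, U00 = 1e6,
                 z = 1e-3)
  k <- pc_kernel(g, p)
  euler <- pc_simulate(k, p, T_max = 100, method = "euler")$series$U0
  taus <- sapply(1:20, function(s)
    pc_simulate(k, p, T_max = 100, seed = s)$series$U0 / p$rho0)
  rel_dev <- abs(rowMeans(taus) - euler) / euler
  expect_lt(max(rel_dev), 0.01)
})

test_that("mirrored kernels give exactly mirrored trajectories when rates are symmetric", {
  g <- pc_grid(21, 25) # odd: the racemic state eta = 0 is a node
  p <- pc_params(eps_eta = 0.2, eps_zeta = 2, g = 0, rho0 = 1e7, z = 1e-4,
                 seed = 11)
  k <- pc_kernel(g, p)
  km <- pc_mirror_kernel(k)
  trA <- pc_simulate(k, p, T_max = 300, record_every = 50)
  trB <- pc_simulate(km, p, T_max = 300, record_every = 50)
  perm <- protocell2d:::pc_mirror_perm(g$d)
  expect_identical(trA$final$N_U, trB$final$N_U[perm])
  expect_identical(trA$final$N_X, trB$final$N_X)
  expect_identical(trA$final$N_W, trB$final$N_W)
  expect_equal(trA$series$mu_eta, -trB$series$mu_eta)
})

test_that("stage 1 consumes food along a tanh-like drop down to the break-even point", {
  fx <- fx_tiny()
  p <- fx$params
  tr <- pc_simulate(fx$kernel, p, T_max = 600, record_every = 5)
  food <- tr$series$food_pct
  # monotone-ish fall from ~100% toward the break-even concentration
  # rho_X* ~ gamma0 / (k0 ka_max); with ka up to 2.3 that is below 10%
  expect_gt(food[1], 99.9)
  expect_lt(tail(food, 1), 11)
  # steepest consumption happens in the middle of the drop, not at the start
  slope <- diff(food)
  expect_gt(which.min(slope), 3)
  # one clear stage boundary: the end of the initial drop
  bounds <- pc_detect_stages(food)
  expect_length(bounds, 1L)
})

test_that("a resolvable global asymmetry directs symmetry breaking to positive mu_eta", {
  g <- pc_grid(100, 25)
  p <- pc_params(eps_eta = 0.1, eps_zeta = 0.3, g = 0.02, rho0 = 1e9,
                 z = 1e-3)
  k <- pc_kernel(g, p)
  finals <- sapply(1:10, function(s) {
    tr <- pc_simulate(k, p, T_max = 2000, record_every = 500, seed = s)
    tail(tr$series$mu_eta, 1)
  })
  expect_gte(sum(finals > 0), 9)
})

test_that("without global asymmetry the sign of the final mean excess varies", {
  g <- pc_grid(101, 25) # odd: start exactly racemic
  p <- pc_params(eps_eta = 0.1, eps_zeta = 0.3, g = 0, rho0 = 1e6,
                 z = 1e-3)
  k <- pc_kernel(g, p)
  finals <- sapply(1:10, function(s) {
    tr <- pc_simulate(k, p, T_max = 1500, record_every = 500, seed = s)
    tail(tr$series$mu_eta, 1)
  })
  expect_true(any(finals > 0) && any(finals < 0))
})
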