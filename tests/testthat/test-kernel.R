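test_that("mutation density integrates to 1 for interior and edge sources", {
  L <- 25
  for (src in list(c(0, L / 2), c(-1, 0), c(0.98, L), c(-0.5, 0.01))) {
    # the density factorizes, so integrate each axis factor separately
    fe <- function(e) pc_mutation_density(e, src[2], src[1], src[2],
                                          0.01, 0.01, L)
    fz <- function(z) pc_mutation_density(src[1], z, src[1], src[2],
                                          0.01, 0.01, L)
    at_src <- pc_mutation_density(src[1], src[2], src[1], src[2],
                                  0.01, 0.01, L)
    ie <- trap_int(fe, max(-1, src[1] - 0.2), min(1, src[1] + 0.2), 8000)
    iz <- trap_int(fz, max(0, src[2] - 0.2), min(L, src[2] + 0.2), 8000)
    expect_equal(ie * iz / at_src, 1, tolerance = 1e-6)
  }
})

test_that("mutation density peaks at 1/(eps_eta eps_zeta pi) for interior sources", {
  expect_equal(pc_mutation_density(0, 12.5, 0, 12.5, 0.01, 0.01, 25),
               1 / (0.01 * 0.01 * pi), tolerance = 1e-6)
  # symmetric about the source away from edges
  a <- 0.007
  expect_equal(pc_mutation_density(0.2 + a, 10, 0.2, 10, 0.01, 0.01, 25),
               pc_mutation_density(0.2 - a, 10, 0.2, 10, 0.01, 0.01, 25))
  expect_error(pc_mutation_density(0, 1, 0, 1, -0.01, 0.01, 25),
               class = "pc_invalid_argument")
})

test_that("replication and decay rate forms evaluate to their closed values", {
  p <- pc_params()
  expect_identical(pc_ka(0, 0, p), 1)
  expect_identical(pc_gamma(0, 0, p), 1)
  expect_equal(pc_ka(1, 0, p), 1.5)
  p2 <- pc_params(a_zeta = 1, b_zeta = 1)
  expect_equal(pc_ka(0, 25, p2), 3.625) # x = 1.5: 1 + 1.5 + 1.125
  expect_equal(pc_gamma(1, 0, p), 0.998)
  expect_equal(pc_gamma(0, 25, p), 1 + 1000 * 1.5^8 / factorial(8),
               tolerance = 1e-12)
  # evenness in eta, exactly
  eta <- seq(-1, 1, by = 0.125)
  expect_identical(pc_ka(eta, 7, p2), pc_ka(-eta, 7, p2))
})

test_that("discretized source masses are normalized and thresholding is monotone", {
  g <- pc_grid(101, 25)
  nnz <- sapply(c(1e-6, 1e-5, 1e-4, 1e-3), function(z) {
    sm <- pc_source_masses(g, pc_params(eps_eta = 0.05, eps_zeta = 0.6,
                                        z = z), 0.3, 10)
    expect_equal(sum(sm$masses), 1, tolerance = 1e-12)
    expect_true(all(sm$masses > 0))
    length(sm$targets)
  })
  expect_true(all(diff(nnz) <= 0))
})

test_that("full-size interior source keeps between 10 and 100 nodes at the reference threshold", {
  g <- pc_grid(500, 25)
  sm <- pc_source_masses(g, pc_params(eps_eta = 0.01, eps_zeta = 0.01,
                                      z = 1e-5), 0, 12.5)
  expect_gte(length(sm$targets), 10)
  expect_lte(length(sm$targets), 100)
})

test_that("kernel columns are stochastic and a too-high threshold degenerates", {
  fx <- fx_tiny()
  cs <- Matrix::colSums(fx$kernel$M)
  expect_equal(max(abs(cs - 1)), 0, tolerance = 1e-12)
  expect_true(all(unlist(fx$kernel$masses) > 0))
  # ka stored on the grid is even in eta
  ka_m <- matrix(fx$kernel$ka, fx$grid$d)
  expect_identical(ka_m, ka_m[fx$grid$d:1, ])
  expect_error(pc_kernel(fx$grid, pc_params(eps_eta = 0.3, eps_zeta = 2.4,
                                            z = 0.99)),
               class = "pc_degenerate_kernel")
})

test_that("discrete mutation mean sits on the source for interior sources", {
  fx <- fx_resolved()
  mom <- pc_kernel_moments(fx$kernel)
  eps <- fx$params$eps_eta
  interior <- abs(mom$eta) < 1 - 6 * eps & mom$zeta > 6 * eps &
    mom$zeta < fx$grid$L - 6 * eps
  expect_lt(max(abs(mom$m1_eta[interior])), 1e-6)
  expect_lt(max(abs(mom$m1_zeta[interior])), 1e-6)
})

test_that("fitness map locates the stationary peak and honors symmetry", {
  # reference parameters: peak at eta = 1, zeta in [20, 21]
  am <- pc_fitness_argmax(pc_params())
  expect_equal(am$eta, 1, tolerance = 1e-8)
  expect_gte(am$zeta, 20)
  expect_lte(am$zeta, 21)

  fx <- fx_d50()
  fm <- pc_fitness_map(fx$kernel)
  expect_equal(fm$argmax_coords[1, "eta"], c(eta = 1))
  expect_gte(fm$argmax_coords[1, "zeta"], 20)
  expect_lte(fm$argmax_coords[1, "zeta"], 21)

  # g = 0: eta-mirrored pair of maxima
  g0 <- pc_kernel(pc_grid(21, 25), pc_params(eps_eta = 0.2, eps_zeta = 2,
                                             g = 0, z = 1e-3))
  fm0 <- pc_fitness_map(g0)
  expect_length(fm0$argmax_nodes, 2L)
  expect_equal(sort(fm0$argmax_coords[, "eta"]), c(-1, 1))
  expect_equal(fm0$argmax_coords[1, "zeta"], fm0$argmax_coords[2, "zeta"])

  # no limiting factor + positive drift: information peak runs to the boundary
  amL <- pc_fitness_argmax(pc_params(f = 0, a_zeta = 1))
  expect_equal(amL$zeta, 25, tolerance = 1e-6)
})

test_that("mirrored kernels relabel rates consistently and stay stochastic", {
  fx <- fx_tiny()
  km <- pc_mirror_kernel(fx$kernel)
  perm <- protocell2d:::pc_mirror_perm(fx$grid$d)
  expect_equal(km$ka, fx$kernel$ka[perm])
  expect_equal(km$gamma, fx$kernel$gamma[perm])
  expect_equal(max(abs(Matrix::colSums(km$M) - 1)), 0, tolerance = 1e-12)
})
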