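test_that("topology generator seeds a clique and hits the target density", {
  set.seed(1)
  full <- klemm_eguiluz_topology(5, density_target = 1, clique_size = 5)
  expect_true(all(full[upper.tri(full)] == 1L))
  expect_true(all(diag(full) == 0L))

  for (s in 1:5) {
    set.seed(s)
    n <- 40
    target <- 0.05
    adj <- klemm_eguiluz_topology(n, target)
    expect_true(isSymmetric(adj))
    expect_true(all(diag(adj) == 0L))
    got <- sum(adj[upper.tri(adj)])
    expect_lte(abs(got - target * n * (n - 1) / 2), 1)
  }
  expect_error(klemm_eguiluz_topology(4, 1, clique_size = 5), "clique")
  expect_error(klemm_eguiluz_topology(10, 2), "unreachable")
})

test_that("topology has a heavier degree tail than Erdos-Renyi", {
  # compare max degree at matched density over seeded runs
  n <- 200
  dens <- 0.05
  max_ke <- max_er <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    ke <- klemm_eguiluz_topology(n, dens)
    max_ke[s] <- max(rowSums(ke))
    set.seed(s + 1000)
    m <- round(dens * n * (n - 1) / 2)
    er <- matrix(0L, n, n)
    idx <- which(upper.tri(er))
    on <- sample(idx, m)
    er[on] <- 1L
    er <- er + t(er)
    max_er[s] <- max(rowSums(er))
  }
  expect_gt(mean(max_ke), mean(max_er))
})

test_that("interaction matrix encodes signs, diagonal and the internal factor", {
  cfg <- sim_config(n_taxa = 30)
  set.seed(4)
  empty <- build_interaction_matrix(matrix(0L, 30, 30), cfg)
  expect_equal(dim(empty), c(31L, 31L))
  expect_true(all(diag(empty) == -0.5))
  off <- empty[1:30, 1:30]; diag(off) <- 0
  expect_true(all(off == 0))
  # internal factor column nonzero, its row zero off-diagonal
  expect_true(all(empty[31, 1:30] == 0))
  expect_true(all(abs(empty[1:30, 31]) >= 0.2 & abs(empty[1:30, 31]) <= 0.8))
  expect_equal(sum(empty[1:30, 31] > 0), 15L)

  # realized positive fraction stays within 5 points of 30%
  fracs <- replicate(50, {
    adj <- klemm_eguiluz_topology(50, 0.01)
    A <- build_interaction_matrix(adj, sim_config())[1:50, 1:50]
    diag(A) <- 0
    nz <- A[A != 0]
    if (length(nz)) mean(nz > 0) else NA
  })
  expect_lt(abs(mean(fracs, na.rm = TRUE) - 0.30), 0.05)

  # no reciprocal mutualistic pair exceeds the self-limitation bound
  set.seed(9)
  for (i in 1:10) {
    adj <- klemm_eguiluz_topology(50, 0.01)
    A <- build_interaction_matrix(adj, sim_config())[1:50, 1:50]
    prods <- A[upper.tri(A)] * t(A)[upper.tri(A)]
    both_pos <- A[upper.tri(A)] > 0 & t(A)[upper.tri(A)] > 0
    if (any(both_pos)) expect_lte(max(prods[both_pos]), 0.9 * 0.25 + 1e-12)
  }
})

test_that("the external signal is a rounded sinusoid with period T", {
  expect_equal(environmental_signal(0), 0)
  expect_equal(environmental_signal(3, T = 12), -1)
  expect_equal(environmental_signal(9, T = 12), 1)
  grid <- seq(0, 49.5, by = 0.5)
  eps <- environmental_signal(grid)
  expect_true(all(eps >= -1 & eps <= 1))
  expect_equal(eps[1:24], eps[25:48])   # one period at dt = 0.5, T = 12
  expect_equal(eps, round(sin(-2 * pi / 12 * grid), 3))
})

test_that("the niche response peaks at the optimum with amplitude gmax^2", {
  expect_equal(growth_rate(0.5, gmax = 0.8, eopt = 0.5, sigma = 0.5), 0.64)
  expect_equal(growth_rate(1, gmax = 0.9, eopt = 0.6, sigma = 0.4),
               0.81 * exp(-0.5))
  g <- growth_rate(seq(0, 1, 0.1), gmax = 0.8, eopt = 0, sigma = 0.3)
  expect_true(all(diff(g) < 0))
  expect_equal(growth_rate(0.5, 0.8, 0.5, 0.5, gmax_squared = FALSE), 0.8)
  expect_error(growth_rate(0, gmax = 0.8, eopt = 0, sigma = 0), "sigma")
})

test_that("broken-stick abundances are positive and sum to one", {
  expect_equal(stick_breaking_abundances(1), 1)
  set.seed(8)
  for (i in 1:50) {
    a <- stick_breaking_abundances(50)
    expect_equal(sum(a), 1, tolerance = 1e-12)
    expect_true(all(a > 0))
  }
  # uneven: far from the flat 1/n profile
  set.seed(9)
  a <- stick_breaking_abundances(50)
  expect_gt(max(a) / min(a), 5)
})

test_that("single-taxon dynamics reach the closed-form equilibrium 2g", {
  # flat niche (huge sigma), fixed gmax, internal factor silenced at 0
  cfg <- sim_config(n_taxa = 1, gmax_range = c(0.8, 0.8),
                    sigma_range = c(200, 200),
                    internal_env = list(gmax = 0.8, eopt = 0.5, sigma = 0.5,
                                        init = 0),
                    seed = 3)
  sim <- simulate_community(cfg)
  g <- 0.8^2
  tail_vals <- sim$abundances[1, 80:100]
  expect_equal(unname(tail_vals), rep(2 * g, 21), tolerance = 1e-3)
  expect_true(all(sim$internal_env == 0))
})

test_that("interaction-free communities grow exponentially", {
  cfg <- sim_config(n_taxa = 5, interaction_probability = 1e-6,
                    diagonal = 0, gmax_range = c(0.8, 0.8),
                    sigma_range = c(200, 200),
                    internal_env = list(gmax = 0.8, eopt = 0.5, sigma = 0.5,
                                        init = 0),
                    t_end = 9.5, seed = 6)
  sim <- simulate_community(cfg)
  g <- 0.8^2
  t10 <- sim$times[20]
  ratio <- sim$abundances[, 20] / sim$abundances[, 1]
  expect_equal(unname(ratio), rep(exp(g * t10), 5), tolerance = 1e-3)
  # abundances at t = 0 equal the broken-stick draw
  expect_equal(sum(sim$abundances[, 1]), 1, tolerance = 1e-12)
})

test_that("default communities have the documented shape and stay sane", {
  sim <- simulate_community(sim_config(seed = 42))
  expect_equal(dim(sim$abundances), c(50L, 100L))
  expect_equal(length(sim$internal_env), 100L)
  expect_equal(length(sim$external_env), 100L)
  expect_true(all(is.finite(sim$abundances)))
  expect_true(all(sim$abundances >= 0))
  expect_true(all(sim$truth_edges$v != sim$truth_edges$w))
  # truth edge count tracks the interaction probability
  expect_equal(nrow(sim$truth_edges), round(0.01 * 50 * 49 / 2))

  # determinism: identical config and seed give an identical community
  sim2 <- simulate_community(sim_config(seed = 42))
  expect_identical(sim$abundances, sim2$abundances)
  expect_identical(sim$A, sim2$A)
  expect_identical(sim$internal_env, sim2$internal_env)

  # non-negativity and finiteness across further seeds
  for (s in c(101, 202, 303, 404, 505)) {
    x <- simulate_community(sim_config(seed = s))$abundances
    expect_true(all(is.finite(x)) && all(x >= 0), info = paste("seed", s))
  }
})

test_that("poisson noise preserves zeros, means and determinism", {
  m <- matrix(c(0, 1, 2, 4), 2)
  set.seed(1)
  zeroes <- add_poisson_noise(matrix(0, 3, 3))
  expect_true(all(zeroes == 0))

  set.seed(2)
  draws <- add_poisson_noise(matrix(4, 1, 1e5))
  expect_equal(mean(draws), 4, tolerance = 0.05 / 4)

  set.seed(3); a <- add_poisson_noise(m, scale = 10)
  set.seed(3); b <- add_poisson_noise(m, scale = 10)
  expect_identical(a, b)
  expect_error(add_poisson_noise(m, scale = 0), "scale")
})
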