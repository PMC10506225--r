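test_that("beta prior density matches closed forms and integrates to one", {
  # Beta(1,1) is the uniform density
  expect_equal(beta_prior_density(0.3, mu = 0.5, kappa = 2), 1)
  # Beta(2,2): 6 * eta * (1 - eta)
  expect_equal(beta_prior_density(0.5, mu = 0.5, kappa = 4), 1.5)
  # Beta(2,8) against the stats::dbeta log-gamma implementation
  expect_equal(beta_prior_density(0.2, mu = 0.2, kappa = 10),
               dbeta(0.2, 2, 8), tolerance = 1e-12)
  expect_equal(beta_prior_density(0.2, mu = 0.2, kappa = 10), 3.0199,
               tolerance = 1e-4)
  # midpoint-rule integral of the density is ~1 even for peaked shapes
  for (prm in list(c(0.5, 2), c(0.2, 10), c(0.9, 50))) {
    dens <- beta_prior_density(grid_4096$midpoints, prm[1], prm[2])
    expect_equal(mean(dens), 1, tolerance = 1e-6)
  }
  expect_error(beta_prior_density(0, 0.5, 2), "strictly in")
  expect_error(beta_prior_density(1, 0.5, 2), "strictly in")
  expect_error(beta_prior_density(0.5, 1.2, 2), "mu")
  expect_error(beta_prior_density(0.5, 0.5, -1), "kappa")
})

test_that("poisson likelihood is the standard pmf in y with mean eta * n", {
  expect_equal(poisson_likelihood(0, eta = 0.5, n = 4), exp(-2))
  expect_equal(poisson_likelihood(5, eta = 1, n = 5), 5^5 * exp(-5) / 120)
  expect_equal(poisson_likelihood(2, eta = 0.25, n = 8), 2^2 * exp(-2) / 2)
  expect_error(poisson_likelihood(-1, 0.5, 1), "nonnegative integer")
  expect_error(poisson_likelihood(2.5, 0.5, 1), "nonnegative integer")
})

test_that("quadrature grid has midpoints strictly inside (0,1), weights 1/K", {
  g2 <- make_quadrature_grid(2)
  expect_equal(g2$midpoints, c(0.25, 0.75))
  expect_equal(g2$weight, 0.5)
  g4 <- make_quadrature_grid(4)
  expect_equal(g4$midpoints, c(0.125, 0.375, 0.625, 0.875))
  for (K in c(2, 7, 1024)) {
    g <- make_quadrature_grid(K)
    expect_true(all(g$midpoints > 0 & g$midpoints < 1))
    expect_equal(g$weight * g$K, 1)
  }
  expect_error(make_quadrature_grid(1), ">= 2")
})

test_that("marginal likelihood matches truncated-gamma closed forms", {
  # uniform prior, y = 0: int_0^1 exp(-n eta) = (1 - e^-n)/n, here n = 1
  expect_equal(marginal_likelihood(0, 1, 0.5, 2, grid_4096), 1 - exp(-1),
               tolerance = 1e-7)
  # uniform prior, y = 1: int eta e^-eta = 1 - 2/e
  expect_equal(marginal_likelihood(1, 1, 0.5, 2, grid_4096), 1 - 2 * exp(-1),
               tolerance = 1e-7)
  expect_true(marginal_likelihood(10, 20, 0.3, 5, grid_4096) > 0)
})

test_that("a sharply concentrated prior collapses the marginal to a Poisson", {
  # prior sd ~ sqrt(1/(4 kappa)) must stay wider than the grid spacing for
  # the midpoint rule to resolve it: kappa = 1e5 at K = 4096, 1e8 at 2^17
  expect_equal(marginal_likelihood(3, 6, 0.5, 1e5, grid_4096),
               dpois(3, 3), tolerance = 2e-5)
  expect_equal(
    marginal_likelihood(3, 6, 0.5, 1e8, make_quadrature_grid(131072L)),
    dpois(3, 3), tolerance = 1e-6)
})

test_that("posterior density is nonnegative and midpoint-normalized", {
  d <- posterior_density_on_grid(2, 4, 0.5, 2, grid_4096)
  expect_true(all(d >= 0))
  expect_equal(mean(d), 1, tolerance = 1e-10)
  # uniform prior: posterior proportional to eta^2 exp(-4 eta), pointwise
  ref <- grid_4096$midpoints^2 * exp(-4 * grid_4096$midpoints)
  ref <- ref / mean(ref)
  expect_equal(d, ref, tolerance = 1e-10)
  # near-zero expected count: likelihood flat, posterior returns the prior
  d0 <- posterior_density_on_grid(0, 1e-8, 0.5, 2, grid_4096)
  expect_equal(d0, rep(1, grid_4096$K), tolerance = 1e-6)
})

test_that("posterior mean matches the uniform-prior conjugate oracle", {
  lattice <- expand.grid(y = 0:20, n = c(0.1, 1, 5, 10, 50))
  pm <- posterior_mean(lattice$y, lattice$n, 0.5, 2, grid_4096)
  oracle <- uniform_prior_posterior_mean(lattice$y, lattice$n)
  expect_lt(max(abs(pm - oracle)), 1e-6)
})

test_that("doubling the grid shrinks the log-marginal error fourfold", {
  # composite midpoint error is O(h^2), so successive doubling differences
  # drop by ~4 when the boundary-derivative term dominates
  lattice <- expand.grid(y = c(0, 1, 5, 20), n = c(0.1, 1, 10, 50))
  lm_k <- function(K) {
    marginal_likelihood(lattice$y, lattice$n, 0.5, 2,
                        make_quadrature_grid(K), log = TRUE)
  }
  l1 <- lm_k(4096); l2 <- lm_k(8192); l3 <- lm_k(16384)
  d1 <- abs(l1 - l2)
  d2 <- abs(l2 - l3)
  big <- d1 > 1e-9
  expect_true(any(big))
  expect_true(all(d2[big] < d1[big] / 3))
  # interior-peaked integrands (negligible boundary mass) converge far
  # below the boundary-dominated ones
  interior <- expand.grid(y = 3:20, n = 50)
  li1 <- marginal_likelihood(interior$y, interior$n, 0.5, 2, grid_4096,
                             log = TRUE)
  li2 <- marginal_likelihood(interior$y, interior$n, 0.5, 2,
                             make_quadrature_grid(8192), log = TRUE)
  expect_lt(max(abs(li1 - li2)), 1e-8)
})

test_that("posterior mean has the right limits and monotonicity", {
  # n -> 0: the prior wins
  expect_equal(posterior_mean(0, 1e-8, 0.5, 2, grid_4096), 0.5,
               tolerance = 1e-4)
  expect_equal(posterior_mean(0, 1e-8, 0.3, 10, grid_4096), 0.3,
               tolerance = 1e-4)
  # n -> infinity with y/n fixed: the data win
  expect_equal(posterior_mean(3000, 1e4, 0.5, 2, make_quadrature_grid(8192L)),
               0.3, tolerance = 0.005)
  # nondecreasing in y at fixed n and prior
  pm <- posterior_mean(0:15, rep(8, 16), 0.4, 3, grid_2048)
  expect_true(all(diff(pm) >= 0))
  expect_true(all(pm > 0 & pm < 1))
})

test_that("deeplof score is the exact complement of the posterior mean", {
  expect_equal(deeplof_score(0.3), 0.7)
  expect_equal(deeplof_score(1.0), 0.0)
  pm <- posterior_mean(2, 4, 0.5, 2, grid_4096)
  expect_equal(pm, 0.55768, tolerance = 1e-5)
  expect_equal(deeplof_score(pm), 0.44232, tolerance = 1e-5)
  expect_identical(deeplof_score(pm) + pm, 1)
  expect_error(deeplof_score(1.5), "\\[0, 1\\]")
})

test_that("batch loss is the mean negative log marginal, order-invariant", {
  expect_equal(batch_loss(0, 1, 0.5, 2, grid_4096), -log(1 - exp(-1)),
               tolerance = 1e-6)
  # duplicating a gene leaves the mean unchanged
  expect_equal(batch_loss(c(0, 0), c(1, 1), 0.5, 2, grid_4096),
               batch_loss(0, 1, 0.5, 2, grid_4096))
  y <- c(0, 3, 7, 1); n <- c(1, 5, 12, 2)
  mu <- c(0.2, 0.5, 0.7, 0.4); k <- c(2, 5, 1, 8)
  o <- sample(4)
  expect_equal(batch_loss(y, n, mu, k, grid_2048),
               batch_loss(y[o], n[o], mu[o], k[o], grid_2048))
  expect_error(batch_loss(numeric(0), numeric(0), 0.5, 2, grid_2048),
               "empty")
})
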