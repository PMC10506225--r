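#' Midpoint quadrature grid on (0, 1)
#'
#' The relative LOF rate eta is integrated over (0, 1) with the midpoint
#' Riemann sum: K equally weighted abscissae (k - 0.5) / K. Because every
#' midpoint lies strictly inside the unit interval, beta prior densities with
#' boundary singularities (shape parameters below 1) are never evaluated at
#' 0 or 1.
#'
#' @param K number of midpoints (at least 2). The default 4096 keeps the
#'   quadrature error well below the statistical uncertainty of any gene's
#'   posterior in practice; see the methods vignette for the error analysis.
#' @return an object of class `quadrature_grid` with elements `midpoints`
#'   (length K), `weight` (the common weight 1/K) and `K`.
#' @examples
#' g <- make_quadrature_grid(4)
#' g$midpoints  # 0.125 0.375 0.625 0.875
#' @export
make_quadrature_grid <- function(K = 4096L) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K < 2 ||
      K != floor(K)) {
    stop_domain("`K` must be an integer >= 2")
  }
  K <- as.integer(K)
  structure(
    list(midpoints = (seq_len(K) - 0.5) / K, weight = 1 / K, K = K),
    class = "quadrature_grid"
  )
}

as_grid <- function(grid) {
  if (!inherits(grid, "quadrature_grid")) {
    stop_domain("`grid` must be created with make_quadrature_grid()")
  }
  grid
}

#' Beta prior density of the relative LOF rate
#'
#' Density of the beta distribution in its mean/concentration
#' parameterization: shapes `mu * kappa` and `(1 - mu) * kappa`, so the mean
#' is `mu` and the variance shrinks as `kappa` grows. Computed via log-gamma
#' in log space and exponentiated, so it is stable for concentrations up to
#' 1e8 and beyond.
#'
#' @param eta evaluation points, strictly inside (0, 1).
#' @param mu prior mean in (0, 1).
#' @param kappa prior concentration, positive.
#' @param log if TRUE return the log density.
#' @return density values (recycled over `eta`).
#' @examples
#' beta_prior_density(0.3, mu = 0.5, kappa = 2)  # uniform: 1
#' @export
beta_prior_density <- function(eta, mu, kappa, log = FALSE) {
  if (!is.numeric(eta) || any(!is.finite(eta)) || any(eta <= 0) ||
      any(eta >= 1)) {
    stop_domain("`eta` must lie strictly in (0, 1)")
  }
  assert_beta_params(mu, kappa)
  a <- mu * kappa
  b <- (1 - mu) * kappa
  ld <- (a - 1) * base::log(eta) + (b - 1) * log1p(-eta) - lbeta(a, b)
  if (log) ld else exp(ld)
}

#' Poisson likelihood of an observed LOF count
#'
#' Probability of observing `y` LOF variants in a gene whose expected count
#' under the neutral mutation model is `n` and whose relative LOF rate is
#' `eta`: a Poisson pmf with mean `eta * n`.
#'
#' @param y observed count (nonnegative integer).
#' @param eta relative LOF rate in (0, 1].
#' @param n expected count under neutrality, positive.
#' @param log if TRUE return the log probability.
#' @return Poisson probability `(eta n)^y exp(-eta n) / y!`.
#' @examples
#' poisson_likelihood(0, eta = 0.5, n = 4)  # exp(-2)
#' @export
poisson_likelihood <- function(y, eta, n, log = FALSE) {
  assert_count_vector(y)
  if (!is.numeric(eta) || any(!is.finite(eta)) || any(eta <= 0) ||
      any(eta > 1)) {
    stop_domain("`eta` must lie in (0, 1]")
  }
  assert_positive(n, "n")
  stats::dpois(y, lambda = eta * n, log = log)
}

# Internal vectorized kernel: for genes (y, n, mu, kappa) and a grid, return
# per-gene log marginal likelihood and posterior expectations of eta,
# log(eta) and log(1 - eta) under the grid-discretized posterior. Genes are
# processed in row chunks to bound memory at large K.
posterior_quantities <- function(y, n, mu, kappa, grid,
                                 chunk_size = 2048L) {
  grid <- as_grid(grid)
  eta <- grid$midpoints
  log_eta <- base::log(eta)
  log_1m_eta <- log1p(-eta)
  B <- length(y)
  mu <- rep_len(mu, B)
  kappa <- rep_len(kappa, B)
  n <- rep_len(n, B)
  a <- mu * kappa
  b <- (1 - mu) * kappa

  logm <- numeric(B)
  e_eta <- numeric(B)
  e_log <- numeric(B)
  e_log1m <- numeric(B)

  for (start in seq(1L, B, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, B)
    ai <- a[idx]; bi <- b[idx]; yi <- y[idx]; ni <- n[idx]
    # log prior density + log Poisson likelihood on the grid, B_chunk x K
    L <- tcrossprod(ai - 1 + yi, log_eta) + tcrossprod(bi - 1, log_1m_eta) -
      tcrossprod(ni, eta) +
      (yi * base::log(ni) - lgamma(yi + 1) - lbeta(ai, bi))
    mx <- apply(L, 1L, max)
    W <- exp(L - mx)
    sw <- rowSums(W)
    logm[idx] <- mx + base::log(sw) - base::log(grid$K)
    W <- W / sw
    e_eta[idx] <- W %*% eta
    e_log[idx] <- W %*% log_eta
    e_log1m[idx] <- W %*% log_1m_eta
  }
  if (any(!is.finite(logm))) {
    stop_domain("marginal likelihood underflowed to zero for some gene(s)")
  }
  list(log_marginal = logm, post_mean = e_eta,
       post_mean_log = e_log, post_mean_log1m = e_log1m,
       a = a, b = b)
}

#' Marginal likelihood of an observed LOF count under the beta prior
#'
#' Integrates the Poisson likelihood over the beta prior of the relative LOF
#' rate, `P(y | x, n) = int_0^1 f(eta | x) P(y | eta, n) d eta`, using the
#' midpoint Riemann sum on `grid`. All computation is in log space with a
#' log-sum-exp reduction.
#'
#' @inheritParams poisson_likelihood
#' @param mu,kappa beta prior mean and concentration (vectorized over genes).
#' @param grid a [make_quadrature_grid()] object.
#' @param log if TRUE return the log marginal likelihood.
#' @return marginal probabilities, one per gene.
#' @export
marginal_likelihood <- function(y, n, mu, kappa, grid = make_quadrature_grid(),
                                log = FALSE) {
  assert_count_vector(y)
  assert_positive(n, "n")
  assert_beta_params(mu, kappa)
  q <- posterior_quantities(y, n, mu, kappa, grid)
  if (log) q$log_marginal else exp(q$log_marginal)
}

#' Posterior density of the relative LOF rate on the quadrature grid
#'
#' Bayes' rule on the midpoint grid: prior density times likelihood divided
#' by the quadrature marginal. The returned densities integrate to 1 under
#' the grid's midpoint rule.
#'
#' @inheritParams marginal_likelihood
#' @return numeric vector of length `grid$K`, the posterior density at each
#'   midpoint (single gene).
#' @export
posterior_density_on_grid <- function(y, n, mu, kappa,
                                      grid = make_quadrature_grid()) {
  stopifnot(length(y) == 1L, length(n) == 1L)
  assert_count_vector(y)
  assert_positive(n, "n")
  assert_beta_params(mu, kappa)
  grid <- as_grid(grid)
  logm <- posterior_quantities(y, n, mu, kappa, grid)$log_marginal
  ld <- beta_prior_density(grid$midpoints, mu, kappa, log = TRUE) +
    poisson_likelihood(y, grid$midpoints, n, log = TRUE) - logm
  exp(ld)
}

#' Posterior mean of the relative LOF rate
#'
#' `E[eta | y, x, n]` computed with the same midpoint rule as the marginal
#' likelihood. Vectorized over genes.
#'
#' @inheritParams marginal_likelihood
#' @return posterior means, strictly inside (0, 1).
#' @export
posterior_mean <- function(y, n, mu, kappa, grid = make_quadrature_grid()) {
  assert_count_vector(y)
  assert_positive(n, "n")
  assert_beta_params(mu, kappa)
  posterior_quantities(y, n, mu, kappa, grid)$post_mean
}

#' DeepLOF score
#'
#' One minus the posterior mean relative LOF rate: the estimated fraction of
#' LOF mutations removed by negative selection. Higher scores mark more
#' LOF-intolerant genes.
#'
#' @param post_mean_eta posterior mean(s) in \[0, 1\].
#' @return scores in \[0, 1\].
#' @export
deeplof_score <- function(post_mean_eta) {
  if (!is.numeric(post_mean_eta) || any(!is.finite(post_mean_eta)) ||
      any(post_mean_eta < 0) || any(post_mean_eta > 1)) {
    stop_domain("`post_mean_eta` must lie in [0, 1]")
  }
  1 - post_mean_eta
}

#' Mean negative log marginal likelihood of a gene batch
#'
#' The training objective: minus the average log marginal likelihood over a
#' mini-batch of genes (excluding any regularization penalty).
#'
#' @inheritParams marginal_likelihood
#' @return a single nonnegative number.
#' @export
batch_loss <- function(y, n, mu, kappa, grid = make_quadrature_grid()) {
  if (length(y) == 0L) stop_domain("empty batch")
  assert_count_vector(y)
  assert_positive(n, "n")
  assert_beta_params(mu, kappa)
  logm <- posterior_quantities(y, n, mu, kappa, grid)$log_marginal
  -mean(logm)
}
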