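# Shared fixtures built in code. Grids are cached because K = 4096 vectors
# are reused across many tests.

grid_4096 <- make_quadrature_grid(4096L)
grid_2048 <- make_quadrature_grid(2048L)

# Truncated-gamma closed form for the uniform-prior posterior mean:
# with a Beta(1, 1) prior, the posterior of eta is Gamma(y + 1, n) truncated
# to (0, 1), whose mean is (1/n) * igamma(y + 2, n) / igamma(y + 1, n) with
# igamma the lower incomplete gamma function.
uniform_prior_posterior_mean <- function(y, n) {
  (y + 1) / n * stats::pgamma(n, y + 2) / stats::pgamma(n, y + 1)
}

# Small labeled-score fixture with both classes.
make_labeled_scores <- function(n_pos = 10, n_neg = 15, seed = 1,
                                separation = 1) {
  set.seed(seed)
  list(scores = c(rnorm(n_pos, mean = separation), rnorm(n_neg)),
       labels = c(rep("essential", n_pos), rep("nonessential", n_neg)))
}

# Brute-force AUC: all positive x negative pairs, ties worth one half.
brute_force_auc <- function(scores, labels, pos = "essential") {
  sp <- scores[labels == pos]
  sn <- scores[labels != pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Independent DeLong oracle from placement values (covariance of the
# per-observation placements of each score vector).
delong_oracle <- function(scores_a, scores_b, labels, pos = "essential") {
  placements <- function(s) {
    x <- s[labels == pos]
    y <- s[labels != pos]
    psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  z <- (pa$auc - pb$auc) / sqrt(var_delta)
  list(delta_auc = pa$auc - pb$auc, var_delta = var_delta,
       p_value = 2 * stats::pnorm(-abs(z)))
}

# One standardized synthetic study with a linear generative prior, reused
# by training tests (built once at load).
make_linear_study <- function(G, w_star, b_star = -0.5, kappa = 5,
                              seed = 101, missing_rate = 0.05) {
  feats <- generate_features(G, F_cont = 5, F_bin = 3,
                             missing_rate = missing_rate, seed = seed)
  fm <- build_feature_matrix(feats$table, feats$specs)
  sim <- generate_genes(fm$values, w_mu = w_star, b_mu = b_star,
                        kappa = kappa, seed = seed + 1L)
  list(features = fm, sim = sim, w_star = w_star)
}
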