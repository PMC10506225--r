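#' Generate a raw gene-feature table with known structure
#'
#' Emulates the statistical shape of real gene-level genomic features:
#' roughly half of the continuous columns are Gaussian, the other half are
#' exponentiated Gaussians (nonnegative, right-skewed, flagged for log
#' transformation, as promoter peak lengths or expression levels would be);
#' binary columns are Bernoulli indicators (as gene-category memberships
#' are). Missing entries are inserted uniformly at random into continuous
#' columns only, since binary category features are complete by
#' construction.
#'
#' @param G number of genes.
#' @param F_cont,F_bin numbers of continuous and binary features.
#' @param missing_rate fraction of continuous entries set missing.
#' @param bin_prob Bernoulli probability of the binary features.
#' @param seed RNG seed.
#' @return list with `table` (data.frame incl. `gene_id`) and `specs` (the
#'   matching feature specification data.frame).
#' @export
generate_features <- function(G, F_cont = 5L, F_bin = 3L,
                              missing_rate = 0.05, bin_prob = 0.3,
                              seed = 1L) {
  if (G < 10L) stop_domain("`G` must be at least 10")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_domain("`missing_rate` must be in [0, 1)")
  }
  local_seed(seed, {
    cols <- list()
    specs <- data.frame(name = character(0), kind = character(0),
                        log_transform = logical(0),
                        stringsAsFactors = FALSE)
    for (j in seq_len(F_cont)) {
      skewed <- j %% 2L == 0L
      nm <- sprintf("feat_cont_%02d", j)
      v <- if (skewed) exp(stats::rnorm(G)) else stats::rnorm(G)
      if (missing_rate > 0) {
        v[stats::runif(G) < missing_rate] <- NA_real_
      }
      cols[[nm]] <- v
      specs <- rbind(specs, data.frame(name = nm, kind = "continuous",
                                       log_transform = skewed))
    }
    for (j in seq_len(F_bin)) {
      nm <- sprintf("feat_bin_%02d", j)
      cols[[nm]] <- stats::rbinom(G, 1L, bin_prob)
      specs <- rbind(specs, data.frame(name = nm, kind = "binary",
                                       log_transform = FALSE))
    }
    tab <- data.frame(gene_id = sprintf("gene_%05d", seq_len(G)), cols,
                      stringsAsFactors = FALSE)
    list(table = tab, specs = specs)
  })
}

#' Simulate observed/expected LOF counts from a feature-linked beta prior
#'
#' The generative model mirrors the DeepLOF assumptions: each gene's prior
#' mean relative LOF rate is `mu = logistic(x w_mu + b_mu)` over its
#' standardized features, the realized rate is `eta ~ Beta(mu kappa,
#' (1 - mu) kappa)`, the expected LOF count `n` is log-normal (median 20,
#' log-sd 1.3, clipped to \[0.1, 200\], placing about 30 percent of genes in
#' the short-gene stratum `n <= 10`), and the observed count is
#' `y ~ Poisson(eta n)`.
#'
#' @param x standardized feature matrix (G x F), e.g. the `values` element
#'   of [build_feature_matrix()].
#' @param w_mu,b_mu generative weights and intercept of the prior-mean map.
#' @param kappa prior concentration: a scalar, or a length-G vector for a
#'   feature-linked concentration.
#' @param mu optional length-G vector of prior means overriding the linear
#'   map (used to create nonlinear feature effects).
#' @param n_meanlog,n_sdlog,n_range log-normal parameters and clip range of
#'   the expected counts.
#' @param gene_id gene identifiers (default taken from `rownames(x)`).
#' @param seed RNG seed.
#' @return list with `data` (a [deeplof_data()]) and `truth` (data.frame of
#'   per-gene `mu`, `kappa`, `eta` plus the generative weights as
#'   attributes).
#' @export
generate_genes <- function(x, w_mu = NULL, b_mu = 0, kappa = 5,
                           mu = NULL,
                           n_meanlog = log(20), n_sdlog = 1.3,
                           n_range = c(0.1, 200), gene_id = NULL,
                           seed = 1L) {
  x <- as.matrix(x)
  G <- nrow(x)
  if (is.null(gene_id)) {
    gene_id <- rownames(x) %||% sprintf("gene_%05d", seq_len(G))
  }
  if (is.null(mu)) {
    if (is.null(w_mu)) w_mu <- numeric(ncol(x))
    if (length(w_mu) != ncol(x)) {
      stop_domain("`w_mu` must have one weight per feature column")
    }
    mu <- stats::plogis(drop(x %*% w_mu) + b_mu)
  } else if (length(mu) != G) {
    stop_domain("`mu` must have one value per gene")
  }
  kappa <- rep_len(kappa, G)
  local_seed(seed, {
    eta <- stats::rbeta(G, mu * kappa, (1 - mu) * kappa)
    # guard against exact 0/1 from extreme shapes
    eps <- 1e-12
    eta <- pmin(pmax(eta, eps), 1 - eps)
    n <- pmin(pmax(stats::rlnorm(G, n_meanlog, n_sdlog), n_range[1]),
              n_range[2])
    y <- stats::rpois(G, eta * n)
    truth <- data.frame(gene_id = gene_id, mu = mu, kappa = kappa, eta = eta,
                        stringsAsFactors = FALSE)
    attr(truth, "w_mu") <- w_mu
    attr(truth, "b_mu") <- b_mu
    list(data = deeplof_data(gene_id, y, n, x), truth = truth)
  })
}

#' Label the most constrained genes as essential
#'
#' Stand-in for curated essential-gene sets: genes whose true relative LOF
#' rate falls below the given quantile are labeled `"essential"`, the rest
#' `"nonessential"`.
#'
#' @param truth truth data.frame from [generate_genes()] (or any data.frame
#'   with `gene_id` and `eta`).
#' @param quantile quantile of the true eta distribution, in (0, 1).
#' @return named character vector of labels, indexed by gene id.
#' @export
label_essential <- function(truth, quantile = 0.1) {
  if (quantile <= 0 || quantile >= 1) {
    stop_domain("`quantile` must be in (0, 1)")
  }
  thr <- stats::quantile(truth$eta, quantile)
  labels <- ifelse(truth$eta < thr, "essential", "nonessential")
  names(labels) <- truth$gene_id
  labels
}

#' Write a complete synthetic study to disk
#'
#' Generates features, counts and ground truth, and lays genes out on a toy
#' chromosome with random benign deletions, producing every file the
#' command-line workflow consumes: `features.tsv`, `counts.tsv`,
#' `truth.tsv`, `feature_config.json`, `genes.bed`, `deletions.bed`.
#'
#' @param dir output directory (created if needed).
#' @param G number of genes.
#' @param n_deletions number of simulated deletions.
#' @param seed RNG seed.
#' @param ... further arguments to [generate_features()].
#' @return invisibly, the list of written paths.
#' @export
simulate_dataset <- function(dir, G = 2000L, n_deletions = 200L, seed = 1L,
                             ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feats <- generate_features(G, seed = seed, ...)
  fm <- build_feature_matrix(feats$table, feats$specs)
  F <- ncol(fm$values)
  w_mu <- local_seed(seed + 1L, stats::runif(F, -1, 1))
  sim <- generate_genes(fm$values, w_mu = w_mu, b_mu = 0, seed = seed + 2L)

  paths <- list(
    features = file.path(dir, "features.tsv"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.tsv"),
    feature_config = file.path(dir, "feature_config.json"),
    genes_bed = file.path(dir, "genes.bed"),
    deletions_bed = file.path(dir, "deletions.bed")
  )
  utils::write.table(feats$table, paths$features, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- data.frame(gene_id = sim$data$gene_id,
                       obs_lof = as.integer(sim$data$y),
                       exp_lof = sim$data$n)
  utils::write.table(counts, paths$counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_feature_config(feats$specs, paths$feature_config)

  # toy chromosome: gene length scales with expected count, fixed spacing
  local_seed(seed + 3L, {
    len <- pmax(300L, as.integer(round(sim$data$n * 1500)))
    gap <- 5000L
    start <- cumsum(c(0L, utils::head(len, -1) + gap))
    genes <- data.frame(chrom = "chr_sim", start = start,
                        end = start + len, name = sim$data$gene_id)
    utils::write.table(genes, paths$genes_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    chrom_len <- max(genes$end) + gap
    del_len <- as.integer(round(stats::rlnorm(n_deletions, log(2e4), 0.8)))
    del_start <- as.integer(floor(stats::runif(n_deletions, 0,
                                               chrom_len - del_len)))
    dels <- data.frame(chrom = "chr_sim", start = del_start,
                       end = del_start + del_len,
                       name = sprintf("del_%04d", seq_len(n_deletions)))
    utils::write.table(dels, paths$deletions_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  })
  invisible(paths)
}
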