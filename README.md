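# deeplof

Unsupervised estimation of gene-level intolerance to loss-of-function
(LOF) mutations from population and functional genomic data.

## The problem

Genes under strong purifying selection carry fewer LOF variants
(stop-gains, splice-site and frameshift mutations) than a neutral
mutation model predicts. Constraint scores built purely from this
depletion work well for long genes but lose power for short ones, where
even complete intolerance removes only a handful of expected variants and
cannot be distinguished from chance. Gene-level functional features
(promoter epigenomics, conservation, expression breadth, pathway
membership) carry complementary information that does not depend on gene
length.

`deeplof` combines the two sources in a single Bayesian model. For gene
$i$ with observed LOF count $y_i$ and neutral expectation $n_i$, the
relative LOF rate $\eta_i \in (0,1)$ gets a feature-driven beta prior and
a Poisson likelihood:

$$
\eta_i \sim \mathrm{Beta}(\mu_i \kappa_i,\ (1-\mu_i)\kappa_i), \qquad
y_i \mid \eta_i \sim \mathrm{Poisson}(\eta_i n_i),
$$

where $\mu_i = \mathrm{logistic}(\mathbf{w}_m^\top \mathbf{z}_i + b_m)$
and $\kappa_i = \exp(\mathbf{w}_k^\top \mathbf{z}_i + b_k)$ are produced
from the gene's feature vector by either a linear map or a one-hidden-layer
ReLU network with dropout. The network is trained **without labels** by
minimizing the mean negative log marginal likelihood
$-\overline{\log \int_0^1 f(\eta\mid\mathbf{x}_i) P(y_i\mid\eta,n_i)\,d\eta}$
(midpoint quadrature, mini-batch Adam, early stopping, L2 on weights).
Each gene's score is

$$
\text{score}_i = 1 - \mathbb{E}[\eta_i \mid y_i, \mathbf{x}_i, n_i],
$$

the estimated fraction of LOF mutations purged by selection: higher means
more LOF-intolerant. Because the posterior balances prior and likelihood
by the amount of data, features automatically dominate for short genes
and population counts for long ones. For the linear variant, the
*contribution score* $-(\mathbf{w}_m)_j$ measures each feature's
association with intolerance.

The package also ships the benchmarking toolkit used around such scores
(expected-count-matched control sets, ROC/AUC, DeLong tests, TPR at fixed
FPR with bootstrap SEs, enrichment log odds ratios, interval-overlap
permutation tests) and a synthetic-data generator with known ground truth
so the entire pipeline is testable offline.

## Worked example

Simulate 2,000 genes with a known linear feature-to-prior map, fit the
linear model, and inspect what it learned:

```r
library(deeplof)

feats <- generate_features(G = 2000, F_cont = 5, F_bin = 3, seed = 1)
fm <- build_feature_matrix(feats$table, feats$specs)

w_star <- c(1.0, -0.8, 0.6, -0.4, 0.3, -0.3, 0.2, 0.1)   # generative weights
sim <- generate_genes(fm$values, w_mu = w_star, b_mu = -0.5, kappa = 5, seed = 2)

sp  <- split_train_validation(sim$data, 0.8, seed = 3)
cfg <- train_config(variant = "linear", learning_rate = 1e-2, batch_size = 256,
                    max_epochs = 60, patience = 8, grid_K = 512, seed = 4)
fit <- train_model(sp$train, sp$validation, cfg)

fit$best_epoch; fit$best_val_loss
#> best epoch: 48   best val loss: 2.83688

sort(contribution_scores(fit$params), decreasing = TRUE)
#> feat_cont_02 feat_cont_04  feat_bin_01  feat_bin_03  feat_bin_02 feat_cont_05
#>        0.701        0.372        0.266       -0.027       -0.202       -0.246
#> feat_cont_03 feat_cont_01
#>       -0.482       -0.878
```

The contribution scores recover the negated generative weights: the
feature simulated with weight $-0.8$ on the prior mean gets contribution
$+0.70$ (associated with intolerance), the $+1.0$ feature gets $-0.88$,
and the near-null $+0.1$ feature sits at $-0.03$. Scoring and a quick
check against the simulation truth:

```r
scores <- score_genes(sim$data, fit$params, make_quadrature_grid(2048))
head(scores[order(-scores$deeplof_score), ], 5)
#>         gene_id posterior_mean_eta deeplof_score
#> 1311 gene_01311           0.001715        0.9983
#> 648  gene_00648           0.001804        0.9982
#> 1791 gene_01791           0.002113        0.9979
#> 331  gene_00331           0.002286        0.9977
#> 1754 gene_01754           0.002430        0.9976

labels <- label_essential(sim$truth, quantile = 0.1)
roc_auc(scores$deeplof_score, labels[scores$gene_id])
#> [1] 0.9777
```

A score of 0.998 reads as "this gene retains ~0.2% of the LOF variation
expected under neutrality"; the AUC shows the scores rank the truly
constrained decile almost perfectly.

The same workflow is available from a shell via the installed script
(`simulate`, `preprocess`, `train`, `score`, `evaluate` subcommands):

```sh
$(Rscript -e 'cat(system.file("exec", "deeplof", package = "deeplof"))') --help
```

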