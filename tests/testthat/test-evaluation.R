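test_that("greedy matching pairs genes by expected count", {
  ess <- data.frame(gene_id = "e1", n = 5.0)
  pool <- data.frame(gene_id = c("p1", "p2"), n = c(4.9, 10.0))
  m <- match_genes(ess, pool)
  expect_equal(m$matched_id, "p1")
  # descending-n greedy order: the n = 6 gene picks first
  ess2 <- data.frame(gene_id = c("e1", "e2"), n = c(5, 6))
  pool2 <- data.frame(gene_id = c("p1", "p2", "p3"), n = c(5.1, 5.9, 100))
  m2 <- match_genes(ess2, pool2)
  expect_equal(m2$essential_id, c("e2", "e1"))
  expect_equal(m2$matched_id, c("p2", "p1"))
  # a pool identical on n gives a perfect match
  pool3 <- data.frame(gene_id = c("q1", "q2"), n = c(6, 5))
  m3 <- match_genes(ess2, pool3)
  expect_equal(sum(abs(m3$essential_n - m3$matched_n)), 0)
  expect_error(match_genes(ess2, pool[1, , drop = FALSE]), "smaller")
})

test_that("AUC equals brute-force pair counting with half-credit ties", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c("essential", "essential",
                                        "nonessential", "nonessential")), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("essential", "nonessential"), 3)),
               0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1),
                       c("essential", "essential",
                         "nonessential", "nonessential")), 0.75)
  set.seed(11)
  for (rep in 1:10) {
    n_pos <- sample(5:100, 1)
    n_neg <- sample(5:100, 1)
    scores <- c(rnorm(n_pos, 0.5), rnorm(n_neg))
    if (rep %% 2 == 0) scores <- round(scores, 1)  # force ties
    labels <- c(rep("essential", n_pos), rep("nonessential", n_neg))
    expect_equal(roc_auc(scores, labels), brute_force_auc(scores, labels))
    # independent library cross-check
    expect_equal(roc_auc(scores, labels),
                 as.numeric(pROC::auc(
                   factor(labels, levels = c("nonessential", "essential")),
                   scores, direction = "<", quiet = TRUE)))
  }
  expect_error(roc_auc(1:3, rep("essential", 3)), "both classes")
})

test_that("DeLong test matches an independent placement-value oracle", {
  fx <- make_labeled_scores(n_pos = 9, n_neg = 11, seed = 21)
  set.seed(22)
  scores_b <- fx$scores + rnorm(20, sd = 0.8)
  res <- delong_test(fx$scores, scores_b, fx$labels)
  oracle <- delong_oracle(fx$scores, scores_b, fx$labels)
  expect_equal(res$delta_auc, oracle$delta_auc)
  expect_equal(res$p_value, oracle$p_value, tolerance = 1e-10)
  # identical scores: zero difference, p = 1
  same <- delong_test(fx$scores, fx$scores, fx$labels)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)
  # swapping arguments flips the sign, keeps the p-value
  swapped <- delong_test(scores_b, fx$scores, fx$labels)
  expect_equal(swapped$delta_auc, -res$delta_auc)
  expect_equal(swapped$p_value, res$p_value)
  expect_error(delong_test(fx$scores, scores_b[-1], fx$labels), "paired")
})

test_that("DeLong p-values are near-uniform under label permutation", {
  set.seed(23)
  n <- 60
  base_labels <- rep(c("essential", "nonessential"), each = n / 2)
  pvals <- replicate(500, {
    labels <- sample(base_labels)
    delong_test(rnorm(n), rnorm(n), labels)$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("TPR at fixed FPR takes the best admissible threshold", {
  # perfect separation
  perfect <- tpr_at_fpr(c(5, 4, 3, 1, 0.5),
                        c(rep("essential", 3), rep("nonessential", 2)),
                        target_fpr = 0.05, n_boot = 10, seed = 1)
  expect_equal(perfect$tpr, 1)
  # one admissible false positive out of three: lowering the threshold to 1
  # keeps FPR at 1/3 while capturing every positive
  res <- tpr_at_fpr(c(3, 2, 1, 2.5, 0.5, 0.1),
                    c(rep("essential", 3), rep("nonessential", 3)),
                    target_fpr = 0.34, n_boot = 50, seed = 2)
  expect_equal(res$tpr, 1)
  # partial recall: with the low positive moved below every control score,
  # the best admissible threshold captures only two of three positives
  res_partial <- tpr_at_fpr(c(3, 2, 0.05, 2.5, 0.5, 0.1),
                            c(rep("essential", 3), rep("nonessential", 3)),
                            target_fpr = 0.34, n_boot = 50, seed = 2)
  expect_equal(res_partial$tpr, 2 / 3)
  res2 <- tpr_at_fpr(c(3, 2, 1, 2.5, 0.5, 0.1),
                     c(rep("essential", 3), rep("nonessential", 3)),
                     target_fpr = 0.34, n_boot = 50, seed = 2)
  expect_identical(res$bootstrap_se, res2$bootstrap_se)
  expect_error(tpr_at_fpr(1:4, rep(c("essential", "nonessential"), 2),
                          n_boot = 0), "n_boot")
})

test_that("threshold classification is inclusive in either direction", {
  ids <- c("a", "b", "c")
  expect_equal(threshold_classify(ids, c(0.9, 0.84, 0.8), 0.835),
               c("a", "b"))
  expect_equal(threshold_classify(ids, c(0.9, 0.84, 0.8), 0.95),
               character(0))
  expect_equal(threshold_classify(ids, c(0.2, 0.35, 0.5), 0.35,
                                  direction = "low_is_intolerant"),
               c("a", "b"))
})

test_that("venn partition reports memberships, uniques and the union", {
  part <- venn_partition(list(A = c("g1", "g2"), B = "g2"))
  expect_equal(part$gene_id, c("g1", "g2"))
  expect_equal(venn_unique_to(part, "A"), "g1")
  expect_length(venn_unique_to(part, "B"), 0)
  same <- venn_partition(list(A = c("x", "y"), B = c("x", "y")))
  expect_length(venn_unique_to(same, "A"), 0)
  set.seed(31)
  sets <- lapply(1:4, function(i) sample(paste0("g", 1:50), 20))
  names(sets) <- paste0("m", 1:4)
  p4 <- venn_partition(sets)
  expect_setequal(p4$gene_id, Reduce(union, sets))
  expect_error(venn_partition(list()), "named")
})

test_that("enrichment log OR and Wald interval match hand computation", {
  e <- enrichment_log_or(20, 10, 10, 20)
  expect_equal(e$log_or, log(4), tolerance = 1e-10)
  expect_equal(e$log_or, 1.3863, tolerance = 1e-4)
  expect_equal(e$se, sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20))
  expect_equal(e$se, 0.5477, tolerance = 1e-4)
  expect_equal(e$ci_low, 0.3128, tolerance = 1e-3)
  expect_equal(e$ci_high, 2.4598, tolerance = 1e-3)
  expect_equal(enrichment_log_or(10, 10, 10, 10)$log_or, 0)
  flip <- enrichment_log_or(10, 20, 20, 10)
  expect_equal(flip$log_or, -enrichment_log_or(20, 10, 10, 20)$log_or)
  expect_equal(flip$se, enrichment_log_or(20, 10, 10, 20)$se)
  expect_error(enrichment_log_or(0, 5, 5, 5), "zero cell")
})

test_that("enrichment interval covers the true log OR about 95% of the time", {
  probs <- c(0.15, 0.10, 0.20, 0.55)
  true_lor <- log((probs[1] / probs[2]) / (probs[3] / probs[4]))
  set.seed(41)
  covered <- replicate(2000, {
    cells <- drop(rmultinom(1, 800, probs))
    if (any(cells == 0)) return(NA)
    e <- enrichment_log_or(cells[1], cells[2], cells[3], cells[4])
    e$ci_low <= true_lor && true_lor <= e$ci_high
  })
  coverage <- mean(covered, na.rm = TRUE)
  expect_gt(coverage, 0.93)
  expect_lt(coverage, 0.97)
})

make_overlap_fixture <- function() {
  genes <- GenomicRanges::GRanges(
    "chr_sim",
    IRanges::IRanges(start = c(1, 101, 201, 301), width = 50),
    gene_id = paste0("g", 1:4))
  names(genes) <- paste0("g", 1:4)
  dels <- GenomicRanges::GRanges(
    "chr_sim", IRanges::IRanges(start = c(20, 120, 400), width = 30))
  list(genes = genes, dels = dels)
}

test_that("deletion overlap permutation p matches exhaustive enumeration", {
  fx <- make_overlap_fixture()
  # deletions hit g1 and g2 only; target {g3, g4} overlaps none
  res <- deletion_overlap_permutation(fx$dels, fx$genes,
                                      target_ids = c("g3", "g4"),
                                      pool_ids = paste0("g", 1:4),
                                      exhaustive = TRUE)
  expect_equal(res$observed_prop, 0)
  # brute force over all 6 subsets of size 2
  subsets <- combn(paste0("g", 1:4), 2)
  props <- apply(subsets, 2, function(ids) {
    sel <- fx$genes[ids]
    mean(GenomicRanges::countOverlaps(fx$dels, sel) > 0)
  })
  expect_equal(sort(res$null_props), sort(props))
  expect_equal(res$p_value, mean(props <= res$observed_prop))
  # deletions identical to the target spans: observed 1, p = 1
  res2 <- deletion_overlap_permutation(
    fx$genes[c("g1", "g2")], fx$genes, target_ids = c("g1", "g2"),
    pool_ids = paste0("g", 1:4), exhaustive = TRUE)
  expect_equal(res2$observed_prop, 1)
  expect_equal(res2$p_value, 1)
  # sampled mode is seeded and supports the pseudo-count estimator
  s1 <- deletion_overlap_permutation(fx$dels, fx$genes, c("g3", "g4"),
                                     paste0("g", 1:4), B = 200, seed = 5)
  s2 <- deletion_overlap_permutation(fx$dels, fx$genes, c("g3", "g4"),
                                     paste0("g", 1:4), B = 200, seed = 5)
  expect_identical(s1$null_props, s2$null_props)
  pc <- deletion_overlap_permutation(fx$dels, fx$genes, c("g3", "g4"),
                                     paste0("g", 1:4), B = 200, seed = 5,
                                     pseudo_count = TRUE)
  expect_equal(pc$p_value, (sum(s1$null_props <= s1$observed_prop) + 1) / 201)
  expect_error(deletion_overlap_permutation(fx$dels, fx$genes,
                                            paste0("g", 1:3), c("g1", "g2")),
               "pool smaller")
})

test_that("prior influence summary handles identical and symmetric inputs", {
  sc <- data.frame(gene_id = paste0("g", 1:30),
                   deeplof_score = seq(0, 1, length.out = 30))
  n <- setNames(exp(seq(log(0.5), log(100), length.out = 30)),
                sc$gene_id)
  expect_message(same <- prior_influence_summary(sc, sc, n, n_bins = 5),
                 "undefined")
  expect_true(all(same$per_gene$abs_diff == 0))
  expect_true(is.na(same$spearman_rho))
  sc2 <- sc
  set.seed(51)
  sc2$deeplof_score <- sc2$deeplof_score + rnorm(30, sd = 0.05)
  a <- prior_influence_summary(sc, sc2, n, n_bins = 5)
  b <- prior_influence_summary(sc2, sc, n, n_bins = 5)
  expect_equal(a$per_gene$abs_diff, b$per_gene$abs_diff)
  expect_equal(a$spearman_rho, b$spearman_rho)
  expect_error(prior_influence_summary(sc, sc2[1:10, ], n), "same genes")
})
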