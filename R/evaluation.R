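#' Match essential genes to controls on expected LOF count
#'
#' Deterministic greedy one-to-one nearest-neighbour matching without
#' replacement on the expected LOF count `n`: essential genes are processed
#' in descending order of `n` and each takes the remaining pool gene with
#' the smallest absolute difference in `n` (first occurrence wins on ties).
#' This removes the gene-length confounding from ROC comparisons.
#'
#' @param essential data.frame with columns `gene_id` and `n`.
#' @param pool data.frame with columns `gene_id` and `n` (candidate
#'   controls; must be at least as large as `essential`).
#' @return data.frame with `essential_id`, `matched_id`, `essential_n`,
#'   `matched_n`.
#' @export
match_genes <- function(essential, pool) {
  for (d in list(essential, pool)) {
    if (!all(c("gene_id", "n") %in% colnames(d))) {
      stop_domain("inputs need columns gene_id and n")
    }
  }
  if (nrow(pool) < nrow(essential)) {
    stop_domain("control pool smaller than the essential set")
  }
  ord <- order(essential$n, decreasing = TRUE)
  avail <- rep(TRUE, nrow(pool))
  out <- data.frame(essential_id = character(nrow(essential)),
                    matched_id = character(nrow(essential)),
                    essential_n = numeric(nrow(essential)),
                    matched_n = numeric(nrow(essential)),
                    stringsAsFactors = FALSE)
  for (k in seq_along(ord)) {
    i <- ord[k]
    cand <- which(avail)
    j <- cand[which.min(abs(pool$n[cand] - essential$n[i]))]
    avail[j] <- FALSE
    out$essential_id[k] <- as.character(essential$gene_id[i])
    out$matched_id[k] <- as.character(pool$gene_id[j])
    out$essential_n[k] <- essential$n[i]
    out$matched_n[k] <- pool$n[j]
  }
  out
}

check_labels <- function(labels, pos_class, neg_class) {
  if (!all(labels %in% c(pos_class, neg_class))) {
    stop_domain("labels must be '", pos_class, "' or '", neg_class, "'")
  }
  if (!any(labels == pos_class) || !any(labels == neg_class)) {
    stop_domain("both classes must be present")
  }
  invisible(NULL)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive-class gene outscores a
#' randomly chosen negative-class gene, with ties counting one half -- the
#' tie-corrected Mann-Whitney statistic, identical to the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param scores numeric predictions; higher means more likely positive.
#' @param labels class labels.
#' @param pos_class,neg_class the two label values.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, pos_class = "essential",
                    neg_class = "nonessential") {
  if (length(scores) != length(labels)) stop_domain("length mismatch")
  if (any(!is.finite(scores))) stop_domain("scores must be finite")
  check_labels(labels, pos_class, neg_class)
  pos <- labels == pos_class
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scoring methods evaluated on the same genes,
#' using the DeLong placement-value variance of the paired AUC difference.
#' If the two score vectors are identical the difference is exactly zero
#' and p = 1.
#'
#' @param scores_a,scores_b paired score vectors on the same genes.
#' @inheritParams roc_auc
#' @return list with `auc_a`, `auc_b`, `delta_auc`, `p_value` (two-sided).
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        pos_class = "essential",
                        neg_class = "nonessential") {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop_domain("scores_a, scores_b and labels must be paired")
  }
  check_labels(labels, pos_class, neg_class)
  auc_a <- roc_auc(scores_a, labels, pos_class, neg_class)
  auc_b <- roc_auc(scores_b, labels, pos_class, neg_class)
  if (identical(scores_a, scores_b)) {
    return(list(auc_a = auc_a, auc_b = auc_b, delta_auc = 0, p_value = 1))
  }
  resp <- factor(labels, levels = c(neg_class, pos_class))
  ra <- pROC::roc(resp, scores_a, direction = "<", quiet = TRUE,
                  levels = c(neg_class, pos_class))
  rb <- pROC::roc(resp, scores_b, direction = "<", quiet = TRUE,
                  levels = c(neg_class, pos_class))
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(auc_a = auc_a, auc_b = auc_b, delta_auc = auc_a - auc_b,
       p_value = as.numeric(tst$p.value))
}

#' True positive rate at a fixed false positive rate
#'
#' Sweeps all score thresholds (genes scoring at or above a threshold are
#' called positive) and reports the maximum true positive rate among
#' thresholds whose empirical false positive rate does not exceed
#' `target_fpr`. The standard error comes from a seeded stratified
#' bootstrap (resampling within each class).
#'
#' @inheritParams roc_auc
#' @param target_fpr tolerated false positive rate, in (0, 1).
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return list with `tpr` and `bootstrap_se`.
#' @export
tpr_at_fpr <- function(scores, labels, target_fpr = 0.05, n_boot = 200L,
                       seed = 1L, pos_class = "essential",
                       neg_class = "nonessential") {
  if (target_fpr <= 0 || target_fpr >= 1) {
    stop_domain("`target_fpr` must be in (0, 1)")
  }
  if (n_boot < 1L) stop_domain("`n_boot` must be at least 1")
  check_labels(labels, pos_class, neg_class)
  point <- function(sc, lb) {
    pos <- sc[lb == pos_class]
    neg <- sc[lb == neg_class]
    thr <- sort(unique(sc))
    tpr_v <- vapply(thr, function(t) mean(pos >= t), numeric(1))
    fpr_v <- vapply(thr, function(t) mean(neg >= t), numeric(1))
    ok <- fpr_v <= target_fpr
    if (!any(ok)) 0 else max(tpr_v[ok])
  }
  tpr <- point(scores, labels)
  pos_idx <- which(labels == pos_class)
  neg_idx <- which(labels == neg_class)
  boots <- local_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos_idx, length(pos_idx), replace = TRUE),
             sample(neg_idx, length(neg_idx), replace = TRUE))
    point(scores[idx], labels[idx])
  }, numeric(1)))
  list(tpr = tpr, bootstrap_se = stats::sd(boots))
}

#' Call LOF-intolerant genes by score threshold
#'
#' Inclusive comparison: with `direction = "high_is_intolerant"` genes with
#' score >= cutoff are returned; with `"low_is_intolerant"` (e.g. LOEUF at
#' 0.35) genes with score <= cutoff are returned.
#'
#' @param gene_ids gene identifiers aligned with `scores`.
#' @param scores numeric scores.
#' @param cutoff finite threshold.
#' @param direction orientation of the score.
#' @return character vector of selected gene ids.
#' @export
threshold_classify <- function(gene_ids, scores, cutoff,
                               direction = c("high_is_intolerant",
                                             "low_is_intolerant")) {
  direction <- match.arg(direction)
  if (!is.finite(cutoff)) stop_domain("`cutoff` must be finite")
  if (length(gene_ids) != length(scores)) stop_domain("length mismatch")
  keep <- if (direction == "high_is_intolerant") scores >= cutoff
          else scores <= cutoff
  as.character(gene_ids[keep])
}

#' Membership table across predicted gene sets
#'
#' @param sets named list of character vectors of gene ids.
#' @return data.frame with `gene_id` (the union) and one logical column per
#'   set.
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 1L || is.null(names(sets)) || any(names(sets) == "")) {
    stop_domain("`sets` must be a nonempty named list")
  }
  all_genes <- sort(unique(unlist(sets, use.names = FALSE)))
  out <- data.frame(gene_id = all_genes, stringsAsFactors = FALSE)
  for (nm in names(sets)) out[[nm]] <- all_genes %in% sets[[nm]]
  out
}

#' @rdname venn_partition
#' @param partition output of `venn_partition()`.
#' @param set_name the set whose exclusive members are requested.
#' @return `venn_unique_to()` returns gene ids belonging to `set_name` and
#'   to no other set.
#' @export
venn_unique_to <- function(partition, set_name) {
  flags <- partition[setdiff(colnames(partition), "gene_id")]
  if (!set_name %in% colnames(flags)) stop_domain("unknown set name")
  others <- flags[setdiff(colnames(flags), set_name)]
  only <- flags[[set_name]] &
    (if (ncol(others) == 0L) TRUE else rowSums(others) == 0)
  partition$gene_id[only]
}

#' Enrichment log odds ratio with Wald confidence interval
#'
#' For a 2x2 table (essential/nonessential x intolerant/tolerant) returns
#' `log((n11/n12)/(n21/n22))` with standard error
#' `sqrt(1/n11 + 1/n12 + 1/n21 + 1/n22)` and the 1.96 * SE interval. All
#' cells must be positive; no continuity correction is applied.
#'
#' @param n11 essential genes called intolerant.
#' @param n12 nonessential genes called intolerant.
#' @param n21 essential genes called tolerant.
#' @param n22 nonessential genes called tolerant.
#' @return list with `log_or`, `se`, `ci_low`, `ci_high`.
#' @export
enrichment_log_or <- function(n11, n12, n21, n22) {
  cells <- c(n11, n12, n21, n22)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop_domain("cells must be nonnegative integers")
  }
  if (any(cells == 0)) {
    stop_domain("log odds ratio undefined with a zero cell")
  }
  log_or <- log((n11 / n12) / (n21 / n22))
  se <- sqrt(sum(1 / cells))
  list(log_or = log_or, se = se,
       ci_low = log_or - 1.96 * se, ci_high = log_or + 1.96 * se)
}

#' Permutation test for deletion overlap depletion
#'
#' Computes the proportion of deletions overlapping at least one target
#' gene, then compares it with a null distribution obtained by repeatedly
#' drawing `length(target_ids)` genes uniformly without replacement from
#' the pool. Intervals follow the BED half-open convention and overlap
#' requires a shared chromosome; strand is ignored. The one-tailed p-value
#' is the fraction of permutations whose overlap proportion is less than or
#' equal to the observed one (reported as is, even when zero; set
#' `pseudo_count = TRUE` for the (b + 1) / (B + 1) estimator).
#'
#' @param deletions `GRanges` of deletion spans.
#' @param genes `GRanges` of gene spans, named by gene id (or carrying a
#'   `gene_id` metadata column).
#' @param target_ids gene ids of the predicted LOF-intolerant set.
#' @param pool_ids gene ids eligible for random draws (typically all genes
#'   in the same expected-count stratum).
#' @param B number of permutations (ignored when `exhaustive = TRUE`).
#' @param seed RNG seed.
#' @param pseudo_count use the positively biased (b + 1)/(B + 1) estimator.
#' @param exhaustive enumerate every subset of the pool instead of sampling
#'   (exact null distribution; only sensible for small pools).
#' @return list with `observed_prop`, `null_props` (length B, or the number
#'   of subsets when exhaustive), `p_value`.
#' @export
deletion_overlap_permutation <- function(deletions, genes, target_ids,
                                         pool_ids, B = 10000L, seed = 1L,
                                         pseudo_count = FALSE,
                                         exhaustive = FALSE) {
  if (B < 1L) stop_domain("`B` must be at least 1")
  ids <- names(genes)
  if (is.null(ids) && !is.null(S4Vectors::mcols(genes)$gene_id)) {
    ids <- as.character(S4Vectors::mcols(genes)$gene_id)
  }
  if (is.null(ids)) stop_domain("`genes` must be named by gene id")
  if (!all(target_ids %in% ids) || !all(pool_ids %in% ids)) {
    stop_domain("target/pool ids missing from `genes`")
  }
  k <- length(target_ids)
  if (length(pool_ids) < k) stop_domain("pool smaller than the target set")

  prop_overlap <- function(sel_ids) {
    sel <- genes[match(sel_ids, ids)]
    mean(GenomicRanges::countOverlaps(deletions, sel,
                                      ignore.strand = TRUE) > 0)
  }
  observed <- prop_overlap(target_ids)
  null_props <- if (exhaustive) {
    apply(utils::combn(pool_ids, k), 2L, prop_overlap)
  } else {
    local_seed(seed, vapply(seq_len(B), function(b) {
      prop_overlap(sample(pool_ids, k))
    }, numeric(1)))
  }
  nB <- length(null_props)
  hits <- sum(null_props <= observed)
  p <- if (pseudo_count) (hits + 1) / (nB + 1) else hits / nB
  list(observed_prop = observed, null_props = null_props, p_value = p)
}

#' Feature influence on scores as a function of gene length
#'
#' Pairs the scores of the same genes under a feature-informed model and a
#' feature-free model, computes the per-gene absolute score difference, and
#' summarizes it within bins (deciles by default) of the expected LOF count
#' `n`. A negative Spearman correlation between the bin median `n` and the
#' bin mean absolute difference means the feature-driven prior matters most
#' for short genes -- the automatic reweighting a Bayesian posterior
#' performs as likelihood information accumulates.
#'
#' @param scores_with,scores_without data.frames with `gene_id` and
#'   `deeplof_score` over the same genes (any order).
#' @param n named or aligned numeric vector of expected LOF counts for the
#'   same genes.
#' @param n_bins number of quantile bins of `n`.
#' @return list with `per_gene` (gene_id, n, abs_diff), `bins` (bin median
#'   n, bin mean abs diff, size) and `spearman_rho` (NA with a message if
#'   every difference is zero).
#' @export
prior_influence_summary <- function(scores_with, scores_without, n,
                                    n_bins = 10L) {
  if (!setequal(scores_with$gene_id, scores_without$gene_id)) {
    stop_domain("the two score tables must cover the same genes")
  }
  m <- match(scores_with$gene_id, scores_without$gene_id)
  d <- abs(scores_with$deeplof_score - scores_without$deeplof_score[m])
  if (!is.null(names(n))) {
    n <- n[scores_with$gene_id]
    if (any(is.na(n))) stop_domain("`n` missing for some genes")
  }
  if (length(n) != nrow(scores_with)) stop_domain("`n` misaligned")
  per_gene <- data.frame(gene_id = scores_with$gene_id, n = as.numeric(n),
                         abs_diff = d, stringsAsFactors = FALSE)
  brk <- unique(stats::quantile(per_gene$n, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(per_gene$n, breaks = brk, include.lowest = TRUE)
  bins <- data.frame(
    bin = levels(bin),
    median_n = as.numeric(tapply(per_gene$n, bin, stats::median)),
    mean_abs_diff = as.numeric(tapply(per_gene$abs_diff, bin, mean)),
    n_genes = as.integer(table(bin)),
    stringsAsFactors = FALSE
  )
  rho <- if (all(d == 0)) {
    message("identical score tables: Spearman correlation undefined")
    NA_real_
  } else {
    stats::cor(bins$median_n, bins$mean_abs_diff, method = "spearman")
  }
  list(per_gene = per_gene, bins = bins, spearman_rho = rho)
}
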