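#' Read a gene-level count/feature table
#'
#' Tab-separated table with a header; required columns `gene_id`, `obs_lof`
#' (nonnegative integer) and `exp_lof` (positive). Empty strings and "NA"
#' become missing values in feature columns. Genes with `exp_lof <= 0` or
#' missing counts are dropped with a message; malformed counts or duplicate
#' gene ids are errors.
#'
#' @param path file path.
#' @param sep field separator (a comma-separated file can be read with
#'   `sep = ","`).
#' @return data.frame with typed columns.
#' @export
read_gene_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("NA", ""), quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  req <- c("gene_id", "obs_lof", "exp_lof")
  miss <- setdiff(req, colnames(tab))
  if (length(miss) > 0L) {
    stop_domain("missing required column(s): ", paste(miss, collapse = ", "))
  }
  tab$gene_id <- as.character(tab$gene_id)
  if (anyDuplicated(tab$gene_id)) {
    dup <- tab$gene_id[duplicated(tab$gene_id)][1]
    stop_domain(sprintf("duplicate gene_id '%s'", dup))
  }
  obs <- suppressWarnings(as.numeric(tab$obs_lof))
  bad <- which(!is.na(tab$obs_lof) & (is.na(obs) | obs < 0 | obs != floor(obs)))
  if (length(bad) > 0L) {
    stop_domain(sprintf(
      "obs_lof must be a nonnegative integer (row %d: '%s')",
      bad[1], tab$obs_lof[bad[1]]))
  }
  tab$obs_lof <- as.integer(obs)
  exp_ <- suppressWarnings(as.numeric(tab$exp_lof))
  bad <- which(!is.na(tab$exp_lof) & is.na(exp_))
  if (length(bad) > 0L) {
    stop_domain(sprintf("exp_lof must be numeric (row %d: '%s')",
                        bad[1], tab$exp_lof[bad[1]]))
  }
  tab$exp_lof <- exp_
  drop <- is.na(tab$obs_lof) | is.na(tab$exp_lof) | tab$exp_lof <= 0
  if (any(drop)) {
    message(sprintf("dropping %d gene(s) with missing counts or exp_lof <= 0",
                    sum(drop)))
    tab <- tab[!drop, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop_domain("no usable genes in table")
  n_missing <- sum(is.na(tab))
  message(sprintf("read %d genes (%d missing feature values)",
                  nrow(tab), n_missing))
  tab
}

#' Write a score table
#'
#' Rows sorted by gene id, numeric columns printed with six decimals, so
#' repeated runs diff cleanly.
#'
#' @param scores data.frame with `gene_id`, `posterior_mean_eta`,
#'   `deeplof_score` (as from [score_genes()]).
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_score_table <- function(scores, path) {
  req <- c("gene_id", "posterior_mean_eta", "deeplof_score")
  if (!all(req %in% colnames(scores))) {
    stop_domain("score table needs columns ", paste(req, collapse = ", "))
  }
  if (nrow(scores) > 0 &&
      (any(!is.finite(scores$posterior_mean_eta)) ||
       any(!is.finite(scores$deeplof_score)))) {
    stop_domain("scores must be finite")
  }
  scores <- scores[order(scores$gene_id), req, drop = FALSE]
  out <- data.frame(
    gene_id = scores$gene_id,
    posterior_mean_eta = sprintf("%.6f", scores$posterior_mean_eta),
    deeplof_score = sprintf("%.6f", scores$deeplof_score)
  )
  if (nrow(scores) == 0L) out <- out[0, , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#' @param path file path.
#' @return data.frame with numeric score columns.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "numeric"))
  tab
}

#' Read BED intervals
#'
#' BED3+ (0-based half-open) via rtracklayer, preceded by a line-level
#' validation pass so malformed records are reported with their line
#' number. Extra columns beyond the name field are preserved by
#' rtracklayer's BED parsing.
#'
#' @param path file path.
#' @return a `GRanges`; interval names come from the BED name column when
#'   present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop_domain(sprintf("line %d: fewer than 3 BED fields", i))
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      stop_domain(sprintf("line %d: non-numeric coordinates", i))
    }
    if (s < 0) stop_domain(sprintf("line %d: negative start", i))
    if (s >= e) stop_domain(sprintf("line %d: start >= end", i))
  }
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(S4Vectors::mcols(gr)$name)) {
    names(gr) <- S4Vectors::mcols(gr)$name
  }
  gr
}

#' Assemble model-ready data from table files
#'
#' Convenience wrapper: reads the gene table, builds the feature matrix from
#' the feature configuration (when given), and returns a [deeplof_data()].
#'
#' @param table_path gene table TSV.
#' @param feature_config_path optional JSON feature specification; omit for
#'   a count-only (flat-model) dataset.
#' @return list with `data` (`deeplof_data`) and `features`
#'   (`deeplof_features` or NULL).
#' @export
load_dataset <- function(table_path, feature_config_path = NULL) {
  tab <- read_gene_table(table_path)
  features <- NULL
  x <- NULL
  if (!is.null(feature_config_path)) {
    specs <- read_feature_config(feature_config_path)
    features <- build_feature_matrix(tab, specs)
    x <- features$values
  }
  list(data = deeplof_data(tab$gene_id, tab$obs_lof, tab$exp_lof, x),
       features = features)
}
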