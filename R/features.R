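#' Log transform a right-skewed feature column
#'
#' Applies `log(x + delta)` where `delta` is the minimum observed positive
#' value of the column, so zeros are mapped to a finite value on the same
#' scale as the smallest measurement. Missing entries are left missing (they
#' are imputed after standardization).
#'
#' @param values numeric vector, possibly containing NA.
#' @param name column name used in error messages.
#' @return list with `values` (transformed) and `delta`.
#' @export
log_transform_column <- function(values, name = "feature") {
  pos <- values[!is.na(values) & values > 0]
  if (length(pos) == 0L) {
    stop_domain(sprintf(
      "column '%s' has no positive value; cannot pick a log offset", name))
  }
  delta <- min(pos)
  list(values = log(values + delta), delta = delta)
}

#' Standardize a feature column
#'
#' Centers and scales by the sample standard deviation (denominator G - 1)
#' of the non-missing entries. A constant column is mapped to all zeros with
#' a warning rather than an error, so degenerate simulated configurations
#' still run.
#'
#' @param values numeric vector, possibly containing NA.
#' @param name column name used in messages.
#' @return list with `values`, `mean` and `sd`.
#' @export
standardize_column <- function(values, name = "feature") {
  obs <- values[!is.na(values)]
  if (length(obs) < 2L) {
    stop_domain(sprintf("column '%s' needs at least 2 non-missing values", name))
  }
  m <- mean(obs)
  s <- stats::sd(obs)
  if (s == 0) {
    warning(sprintf("column '%s' is constant; standardized to zeros", name),
            call. = FALSE)
    out <- ifelse(is.na(values), NA_real_, 0)
    return(list(values = out, mean = m, sd = 0))
  }
  list(values = (values - m) / s, mean = m, sd = s)
}

#' Mean-impute a feature column
#'
#' Replaces missing entries with the mean of the non-missing entries. For
#' continuous features this runs after standardization, so the fill value is
#' approximately zero.
#'
#' @param values numeric vector with at least one non-missing entry.
#' @return filled numeric vector.
#' @export
impute_missing_column <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) == 0L) stop_domain("column is entirely missing")
  values[is.na(values)] <- mean(obs)
  values
}

#' Build the model-ready feature matrix
#'
#' Runs the preprocessing pipeline per feature: continuous columns are log
#' transformed (when flagged), standardized, then mean-imputed; binary
#' columns must already be coded 0/1 and pass through untouched. The
#' transform state (log offset, mean, sd, imputation fill) is stored so the
#' identical transform can be replayed on new genes with
#' [apply_feature_transform()].
#'
#' @param raw_table data.frame of raw feature values, one row per gene.
#'   A `gene_id` column, if present, is used for row labels.
#' @param specs data.frame with columns `name`, `kind`
#'   (`"continuous"`/`"binary"`) and `log_transform` (logical; must be FALSE
#'   for binary features).
#' @return object of class `deeplof_features`: list with `gene_ids`, the
#'   numeric matrix `values` (G x F), `specs` and `transform_state`.
#' @export
build_feature_matrix <- function(raw_table, specs) {
  specs <- validate_feature_specs(specs)
  if (nrow(raw_table) == 0L) stop_domain("empty gene table")
  missing_cols <- setdiff(specs$name, colnames(raw_table))
  if (length(missing_cols) > 0L) {
    stop_domain("feature column(s) not in table: ",
                paste(missing_cols, collapse = ", "))
  }
  gene_ids <- if ("gene_id" %in% colnames(raw_table)) {
    as.character(raw_table$gene_id)
  } else {
    as.character(seq_len(nrow(raw_table)))
  }
  out <- matrix(NA_real_, nrow(raw_table), nrow(specs),
                dimnames = list(gene_ids, specs$name))
  state <- vector("list", nrow(specs))
  names(state) <- specs$name
  for (j in seq_len(nrow(specs))) {
    nm <- specs$name[j]
    v <- raw_table[[nm]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    if (specs$kind[j] == "binary") {
      obs <- v[!is.na(v)]
      if (any(is.na(v))) {
        stop_domain(sprintf("binary column '%s' contains missing values", nm))
      }
      if (!all(obs %in% c(0, 1))) {
        stop_domain(sprintf("binary column '%s' has values outside {0, 1}", nm))
      }
      out[, j] <- v
      state[[j]] <- list(kind = "binary")
    } else {
      st <- list(kind = "continuous", delta = NA_real_)
      if (specs$log_transform[j]) {
        lt <- log_transform_column(v, nm)
        v <- lt$values
        st$delta <- lt$delta
      }
      sc <- standardize_column(v, nm)
      st$mean <- sc$mean
      st$sd <- sc$sd
      v <- sc$values
      st$impute <- if (any(is.na(v))) mean(v, na.rm = TRUE) else 0
      out[, j] <- impute_missing_column(v)
      state[[j]] <- st
    }
  }
  structure(list(gene_ids = gene_ids, values = out, specs = specs,
                 transform_state = state),
            class = "deeplof_features")
}

#' Replay a fitted feature transform on new genes
#'
#' @param features a `deeplof_features` object from [build_feature_matrix()].
#' @param raw_table new raw feature table with the same columns.
#' @return numeric matrix with the frozen transform applied.
#' @export
apply_feature_transform <- function(features, raw_table) {
  if (!inherits(features, "deeplof_features")) {
    stop_domain("`features` must come from build_feature_matrix()")
  }
  specs <- features$specs
  out <- matrix(NA_real_, nrow(raw_table), nrow(specs),
                dimnames = list(NULL, specs$name))
  for (j in seq_len(nrow(specs))) {
    nm <- specs$name[j]
    v <- raw_table[[nm]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    st <- features$transform_state[[nm]]
    if (st$kind == "binary") {
      if (any(is.na(v)) || !all(v %in% c(0, 1))) {
        stop_domain(sprintf("binary column '%s' must be 0/1 and complete", nm))
      }
      out[, j] <- v
    } else {
      if (!is.na(st$delta)) v <- log(v + st$delta)
      v <- if (st$sd == 0) ifelse(is.na(v), NA_real_, 0) else (v - st$mean) / st$sd
      v[is.na(v)] <- st$impute
      out[, j] <- v
    }
  }
  out
}

validate_feature_specs <- function(specs) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  req <- c("name", "kind", "log_transform")
  if (!all(req %in% colnames(specs))) {
    stop_domain("`specs` needs columns name, kind, log_transform")
  }
  if (!all(specs$kind %in% c("continuous", "binary"))) {
    stop_domain("feature kind must be 'continuous' or 'binary'")
  }
  specs$log_transform <- as.logical(specs$log_transform)
  if (any(specs$kind == "binary" & specs$log_transform)) {
    stop_domain("binary features cannot be log-transformed")
  }
  if (anyDuplicated(specs$name)) stop_domain("duplicate feature names")
  specs
}

#' Read a feature configuration file
#'
#' JSON array of objects with fields `name`, `kind` and `log_transform`,
#' one per feature.
#'
#' @param path file path.
#' @return validated specs data.frame.
#' @export
read_feature_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_feature_specs(cfg)
}

#' @rdname read_feature_config
#' @param specs specs data.frame to write.
#' @export
write_feature_config <- function(specs, path) {
  specs <- validate_feature_specs(specs)
  jsonlite::write_json(specs, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
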