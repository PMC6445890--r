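#' @include AllClasses.R
NULL

.read_delim_matrix <- function(path, delim = NULL, na_tokens = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = if (is.null(delim)) "auto" else delim,
                          header = TRUE, na.strings = na_tokens,
                          colClasses = list(character = 1L),
                          data.table = FALSE, showProgress = FALSE)
  if (ncol(dt) < 2L)
    stop("expected an id column plus at least one data column in ", path,
         call. = FALSE)
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, call. = FALSE)
  vals <- dt[, -1L, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(non_num)) {
    coerced <- suppressWarnings(lapply(vals[non_num], as.numeric))
    bad <- vapply(seq_along(coerced), function(i) {
      any(is.na(coerced[[i]]) & !is.na(vals[non_num][[i]]))
    }, logical(1L))
    if (any(bad))
      stop("non-numeric cell(s) in column(s) ",
           paste(names(vals[non_num])[bad], collapse = ", "), " of ", path,
           call. = FALSE)
    vals[non_num] <- coerced
  }
  m <- as.matrix(vals)
  if (anyDuplicated(colnames(m)))
    stop("duplicate column ids in ", path, call. = FALSE)
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

.write_delim_matrix <- function(m, path, id_col, delim = ",") {
  # 17 significant digits make the text round-trip bit-exact
  chr <- vapply(seq_len(ncol(m)), function(j) {
    out <- formatC(m[, j], digits = 17L, format = "g")
    out[is.na(m[, j])] <- "NA"
    out
  }, character(nrow(m)))
  chr <- matrix(chr, nrow = nrow(m))
  df <- data.frame(id = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  data.table::fwrite(df, path, sep = delim, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a cell-line-by-feature table from a delimited text file
#'
#' The first column holds cell-line identifiers, the header row feature
#' identifiers. Empty cells or cells equal to one of \code{na_tokens} are
#' treated as missing. SNV tables must contain only 0, 1 or missing.
#'
#' @param path path to a CSV/TSV file.
#' @param kind feature kind: \code{"expression"}, \code{"cna"} or
#'   \code{"snv"}.
#' @param delim field delimiter; \code{NULL} (default) auto-detects.
#' @param na_tokens character vector of missing-value markers.
#' @return a \linkS4class{FeatureMatrix}.
#' @seealso \code{\link{writeFeatureMatrix}}
#' @export
readFeatureMatrix <- function(path, kind, delim = NULL,
                              na_tokens = c("", "NA")) {
  m <- .read_delim_matrix(path, delim, na_tokens)
  FeatureMatrix(m, kind)
}

#' Write a FeatureMatrix to a delimited text file
#'
#' Inverse of \code{\link{readFeatureMatrix}}: cell lines as rows, missing
#' entries written as \code{NA}. Round-trips are lossless including the
#' missing pattern.
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param path output file path.
#' @param delim field delimiter (default comma).
#' @return invisibly, \code{path}.
#' @export
writeFeatureMatrix <- function(x, path, delim = ",") {
  stopifnot(is(x, "FeatureMatrix"))
  .write_delim_matrix(featureValues(x), path, "cell_line", delim)
}

#' Read a drug-by-cell-line IC50 table
#'
#' Drugs are rows (first column holds drug identifiers), cell lines are
#' columns. Fully missing rows are preserved; filtering them is the
#' preprocessing step's job.
#'
#' @inheritParams readFeatureMatrix
#' @return a \linkS4class{ResponseTable}.
#' @export
readResponseTable <- function(path, delim = NULL, na_tokens = c("", "NA")) {
  ResponseTable(.read_delim_matrix(path, delim, na_tokens))
}

#' Write a ResponseTable to a delimited text file
#'
#' @param x a \linkS4class{ResponseTable}.
#' @inheritParams writeFeatureMatrix
#' @return invisibly, \code{path}.
#' @export
writeResponseTable <- function(x, path, delim = ",") {
  stopifnot(is(x, "ResponseTable"))
  .write_delim_matrix(ic50Values(x), path, "drug", delim)
}

#' Construct a PipelineConfig
#'
#' Bundles every tunable setting of the pipeline with the defaults used
#' throughout: 50\% missingness filters, K = 10 imputation neighbours,
#' a 50\% autoencoder screen cut with 0.95 correlation pruning, 200 Boruta
#' iterations, a 1,000-tree forest on ceiling(0.632 N) subsamples,
#' EasyEnsemble above imbalance ratio 2, and 10-fold cross-validation.
#'
#' @param k_impute number of nearest neighbours for imputation.
#' @param missing_feature_threshold drop features with a missing fraction
#'   strictly greater than this.
#' @param missing_cell_threshold drop cell lines with a missing fraction
#'   strictly greater than this (after the feature filter).
#' @param joint_response_filter count per-drug response missingness
#'   together with feature missingness in the cell-line filter.
#' @param weight_mode imputation weighting: \code{"inverse_distance"}
#'   (default) or \code{"as_printed"} (weights proportional to distance).
#' @param screen_keep_fraction fraction of features kept by the
#'   contribution ranking.
#' @param corr_threshold correlation above which screened features are
#'   pruned.
#' @param corr_method \code{"pairwise"} (default; prune on the maximum
#'   absolute correlation with a retained survivor) or \code{"mean"}
#'   (prune on the mean absolute correlation with all other survivors).
#' @param ae_hidden autoencoder hidden size; \code{NA} (default) means
#'   \code{min(128, ceiling(G / 4))} for G inputs.
#' @param ae_epochs,ae_learning_rate autoencoder training settings.
#' @param boruta_max_iter,boruta_alpha,boruta_trees Boruta iteration cap,
#'   binomial-test level, and internal forest size.
#' @param keep_tentative include still-tentative features in the final
#'   selection.
#' @param rf_trees trees in the final classifier forest.
#' @param bootstrap_fraction per-tree subsample fraction (size is
#'   \code{ceiling(fraction * N)}).
#' @param bootstrap_replace draw per-tree samples with replacement.
#' @param min_leaf minimum samples per leaf.
#' @param ir_threshold imbalance ratio above which EasyEnsemble is used.
#' @param cv_folds number of cross-validation folds.
#' @param select_per_fold run Boruta inside each training fold (default)
#'   rather than once on all data.
#' @param seed master seed; per-stage seeds are derived from it with
#'   \code{\link{deriveSeed}}.
#' @return a validated \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig(seed = 7L, cv_folds = 5L)
#' @export
pipelineConfig <- function(k_impute = 10L,
                           missing_feature_threshold = 0.5,
                           missing_cell_threshold = 0.5,
                           joint_response_filter = TRUE,
                           weight_mode = "inverse_distance",
                           screen_keep_fraction = 0.5,
                           corr_threshold = 0.95,
                           corr_method = "pairwise",
                           ae_hidden = NA_integer_,
                           ae_epochs = 500L,
                           ae_learning_rate = 0.05,
                           boruta_max_iter = 200L,
                           boruta_alpha = 0.01,
                           boruta_trees = 250L,
                           keep_tentative = FALSE,
                           rf_trees = 1000L,
                           bootstrap_fraction = 0.632,
                           bootstrap_replace = FALSE,
                           min_leaf = 1L,
                           ir_threshold = 2,
                           cv_folds = 10L,
                           select_per_fold = TRUE,
                           seed = 1L) {
  new("PipelineConfig",
      k_impute = as.integer(k_impute),
      missing_feature_threshold = missing_feature_threshold,
      missing_cell_threshold = missing_cell_threshold,
      joint_response_filter = isTRUE(joint_response_filter),
      weight_mode = weight_mode,
      screen_keep_fraction = screen_keep_fraction,
      corr_threshold = corr_threshold,
      corr_method = corr_method,
      ae_hidden = as.integer(ae_hidden),
      ae_epochs = as.integer(ae_epochs),
      ae_learning_rate = ae_learning_rate,
      boruta_max_iter = as.integer(boruta_max_iter),
      boruta_alpha = boruta_alpha,
      boruta_trees = as.integer(boruta_trees),
      keep_tentative = isTRUE(keep_tentative),
      rf_trees = as.integer(rf_trees),
      bootstrap_fraction = bootstrap_fraction,
      bootstrap_replace = isTRUE(bootstrap_replace),
      min_leaf = as.integer(min_leaf),
      ir_threshold = ir_threshold,
      cv_folds = as.integer(cv_folds),
      select_per_fold = isTRUE(select_per_fold),
      seed = as.integer(seed))
}

#' Read / write a PipelineConfig as a flat key-value (YAML) file
#'
#' Only keys naming \code{\link{pipelineConfig}} arguments are accepted;
#' omitted keys take their defaults.
#'
#' @param path path to a YAML file of scalar key-value pairs.
#' @return \code{readPipelineConfig}: a \linkS4class{PipelineConfig};
#'   \code{writePipelineConfig}: invisibly, \code{path}.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @param config a \linkS4class{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(is(config, "PipelineConfig"))
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  names(vals) <- slotNames(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}
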