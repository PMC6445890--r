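#' @include abrf-package.R
NULL

.FEATURE_KINDS <- c("expression", "cna", "snv")
.LABEL_LEVELS <- c("non_sensitive", "sensitive")

#' FeatureMatrix: a cell-line-by-feature table of one genomic kind
#'
#' Holds one kind of explanatory feature table: real-valued gene
#' expression, real-valued copy-number alteration (CNA), or binary
#' single-nucleotide mutation status (SNV, 1 = mutated, 0 = wild type).
#' Rows are cell lines, columns are features; \code{NA} marks missing
#' values. Expression tables are expected to be complete (the imputation
#' step measures cell-line distances on them), which is checked by the
#' preprocessing functions rather than by the class itself.
#'
#' @slot values numeric matrix (cell line x feature) with \code{NA} for
#'   missing entries; dimnames give cell-line and feature identifiers.
#' @slot kind one of \code{"expression"}, \code{"cna"}, \code{"snv"}.
#' @aliases FeatureMatrix
#' @name FeatureMatrix-class
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", kind = "character"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (length(object@kind) != 1L || !object@kind %in% .FEATURE_KINDS)
    msgs <- c(msgs, sprintf("kind must be one of %s",
                            paste(.FEATURE_KINDS, collapse = ", ")))
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must have cell-line rownames and feature colnames")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate cell-line ids")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate feature ids")
  }
  if (is.numeric(v) && any(is.infinite(v)))
    msgs <- c(msgs, "values must be finite or NA")
  if (identical(object@kind, "snv") && is.numeric(v)) {
    obs <- v[!is.na(v)]
    if (!all(obs %in% c(0, 1)))
      msgs <- c(msgs, "snv values must be 0, 1 or missing")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix, cell lines as rows (rownames) and features
#'   as columns (colnames); \code{NA} marks missing values.
#' @param kind feature kind: \code{"expression"}, \code{"cna"} or
#'   \code{"snv"}.
#' @return a validated \linkS4class{FeatureMatrix}.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
#' FeatureMatrix(m, "expression")
#' @export
FeatureMatrix <- function(values, kind) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("FeatureMatrix", values = values, kind = kind)
}

#' ResponseTable: per-drug IC50 values across cell lines
#'
#' Drugs are rows, cell lines are columns; \code{NA} marks cell lines
#' without a measured IC50 for that drug.
#'
#' @slot ic50 numeric matrix (drug x cell line) with dimnames.
#' @aliases ResponseTable
#' @name ResponseTable-class
#' @exportClass ResponseTable
setClass("ResponseTable", representation(ic50 = "matrix"))

setValidity("ResponseTable", function(object) {
  v <- object@ic50
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "ic50 must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "ic50 must have drug rownames and cell-line colnames")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate drug ids")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate cell-line ids")
  }
  if (is.numeric(v) && any(is.infinite(v)))
    msgs <- c(msgs, "non-missing IC50 values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ResponseTable
#'
#' @param ic50 numeric matrix with drugs as rows and cell lines as columns.
#' @return a validated \linkS4class{ResponseTable}.
#' @export
ResponseTable <- function(ic50) {
  ic50 <- as.matrix(ic50)
  storage.mode(ic50) <- "double"
  new("ResponseTable", ic50 = ic50)
}

#' LabelVector: binary sensitivity labels for one drug
#'
#' @slot drug drug identifier.
#' @slot labels factor with levels \code{non_sensitive}, \code{sensitive},
#'   named by cell line.
#' @slot threshold the IC50 threshold used (the per-drug median unless an
#'   external threshold was supplied); sensitive iff IC50 < threshold.
#' @aliases LabelVector
#' @name LabelVector-class
#' @exportClass LabelVector
setClass("LabelVector",
  representation(drug = "character", labels = "factor", threshold = "numeric"))

setValidity("LabelVector", function(object) {
  msgs <- character()
  if (!identical(levels(object@labels), .LABEL_LEVELS))
    msgs <- c(msgs, "labels must have levels non_sensitive, sensitive")
  if (is.null(names(object@labels)))
    msgs <- c(msgs, "labels must be named by cell line")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msgs <- c(msgs, "threshold must be a single finite number")
  if (length(msgs)) msgs else TRUE
})

#' AutoencoderModel: a trained single-hidden-layer tanh autoencoder
#'
#' @slot W encoder weights, inputs (G) x hidden units (K).
#' @slot V decoder weights, hidden units (K) x outputs (G).
#' @slot b_h,b_o hidden and output biases.
#' @slot center,scale per-feature standardisation applied before training.
#' @slot epochs_run,initial_loss,final_loss,seed training metadata.
#' @aliases AutoencoderModel
#' @name AutoencoderModel-class
#' @exportClass AutoencoderModel
setClass("AutoencoderModel",
  representation(W = "matrix", V = "matrix", b_h = "numeric", b_o = "numeric",
                 center = "numeric", scale = "numeric",
                 epochs_run = "integer", initial_loss = "numeric",
                 final_loss = "numeric", seed = "integer"))

setValidity("AutoencoderModel", function(object) {
  msgs <- character()
  G <- nrow(object@W); K <- ncol(object@W)
  if (nrow(object@V) != K || ncol(object@V) != G)
    msgs <- c(msgs, "decoder shape must be hidden x inputs")
  if (length(object@b_h) != K || length(object@b_o) != G)
    msgs <- c(msgs, "bias lengths inconsistent with weight shapes")
  if (!all(is.finite(object@W)) || !all(is.finite(object@V)))
    msgs <- c(msgs, "weights must be finite")
  if (length(msgs)) msgs else TRUE
})

#' ContributionScores: Gedeon proportional input contributions
#'
#' \code{P} holds input-to-hidden contributions (each hidden unit's column
#' sums to 1), \code{Q} input-to-output contributions (each output's column
#' sums to 1), and \code{q} the per-input totals, which sum to the number
#' of inputs.
#'
#' @slot feature_ids input feature identifiers.
#' @slot P G x K matrix of input-to-hidden contributions.
#' @slot Q G x G matrix of input-to-output contributions.
#' @slot q length-G numeric vector of total contributions.
#' @aliases ContributionScores
#' @name ContributionScores-class
#' @exportClass ContributionScores
setClass("ContributionScores",
  representation(feature_ids = "character", P = "matrix", Q = "matrix",
                 q = "numeric"))

setValidity("ContributionScores", function(object) {
  msgs <- character()
  G <- length(object@feature_ids)
  if (nrow(object@P) != G || nrow(object@Q) != G || ncol(object@Q) != G ||
      length(object@q) != G)
    msgs <- c(msgs, "dimensions inconsistent with feature_ids")
  if (any(object@P < 0) || any(object@Q < 0) || any(object@q < 0))
    msgs <- c(msgs, "contributions must be nonnegative")
  if (max(abs(colSums(object@P) - 1)) > 1e-10)
    msgs <- c(msgs, "columns of P must sum to 1")
  if (max(abs(colSums(object@Q) - 1)) > 1e-10)
    msgs <- c(msgs, "columns of Q must sum to 1")
  if (abs(sum(object@q) - G) > 1e-8)
    msgs <- c(msgs, "total contributions must sum to the number of inputs")
  if (length(msgs)) msgs else TRUE
})

#' BorutaResult: outcome of a Boruta shadow-feature selection run
#'
#' @slot confirmed,rejected,tentative character vectors partitioning the
#'   input feature set.
#' @slot history data.frame with one row per (iteration, feature): Z score,
#'   the iteration's maximum shadow Z (MZSA), hit indicator, cumulative
#'   hits, and the decision in force after the iteration.
#' @slot iterations_run number of iterations executed.
#' @aliases BorutaResult
#' @name BorutaResult-class
#' @exportClass BorutaResult
setClass("BorutaResult",
  representation(confirmed = "character", rejected = "character",
                 tentative = "character", history = "data.frame",
                 iterations_run = "integer"))

setValidity("BorutaResult", function(object) {
  all_ids <- c(object@confirmed, object@rejected, object@tentative)
  if (anyDuplicated(all_ids))
    return("confirmed/rejected/tentative must be disjoint")
  TRUE
})

#' ForestModel: a random forest of CART trees
#'
#' Trees are stored as plain tables (split variable, threshold, child
#' indices, leaf class counts) so they can be serialized to text with
#' \code{\link{writeForestModel}} and re-scored without retraining.
#'
#' @slot trees list of per-tree tables (parallel vectors \code{var},
#'   \code{val}, \code{left}, \code{right}, \code{pred}, \code{n0},
#'   \code{n1}; 0-based feature and node indices, -1 for leaves).
#' @slot oob list of per-tree out-of-bag sample indices (1-based).
#' @slot feature_ids training feature names, in column order.
#' @slot n_trees,bootstrap_size,seed training settings.
#' @aliases ForestModel
#' @name ForestModel-class
#' @exportClass ForestModel
setClass("ForestModel",
  representation(trees = "list", oob = "list", feature_ids = "character",
                 n_trees = "integer", bootstrap_size = "integer",
                 seed = "integer"))

#' EasyEnsembleModel: forests trained on balanced majority-class subsets
#'
#' The majority class is partitioned into \code{T = floor(IR)} disjoint
#' subsets of near-equal size; one forest is trained per subset together
#' with the full minority class. Prediction is the majority vote of the
#' sub-forests and the score the mean of their sensitive-vote fractions.
#'
#' @slot forests list of \linkS4class{ForestModel}.
#' @slot partition list of majority-class cell ids per subset.
#' @slot ir the imbalance ratio |majority| / |minority|.
#' @aliases EasyEnsembleModel
#' @name EasyEnsembleModel-class
#' @exportClass EasyEnsembleModel
setClass("EasyEnsembleModel",
  representation(forests = "list", partition = "list", ir = "numeric"))

setValidity("EasyEnsembleModel", function(object) {
  msgs <- character()
  if (length(object@forests) != length(object@partition))
    msgs <- c(msgs, "one forest per majority subset required")
  ids <- unlist(object@partition)
  if (anyDuplicated(ids)) msgs <- c(msgs, "majority subsets must be disjoint")
  sizes <- lengths(object@partition)
  if (length(sizes) && diff(range(sizes)) > 1L)
    msgs <- c(msgs, "majority subset sizes must differ by at most 1")
  if (length(msgs)) msgs else TRUE
})

#' MetricsReport: cross-validated classification metrics for one drug
#'
#' @slot drug drug identifier.
#' @slot folds data.frame of per-fold confusion counts and metrics
#'   (TP, FP, FN, TN, ACC, REC, SPC, F1, MCC, AUC).
#' @slot means named numeric vector of fold-mean metrics.
#' @slot fold_assignment integer fold id per cell line (named).
#' @slot seed the seed used for fold assignment and training.
#' @aliases MetricsReport
#' @name MetricsReport-class
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(drug = "character", folds = "data.frame", means = "numeric",
                 fold_assignment = "integer", seed = "integer"))

setValidity("MetricsReport", function(object) {
  m <- object@means
  msgs <- character()
  bounded01 <- intersect(names(m), c("ACC", "REC", "SPC", "F1", "AUC"))
  if (length(bounded01) && any(m[bounded01] < -1e-9 | m[bounded01] > 1 + 1e-9,
                               na.rm = TRUE))
    msgs <- c(msgs, "ACC/REC/SPC/F1/AUC must lie in [0, 1]")
  if ("MCC" %in% names(m) && !is.na(m[["MCC"]]) &&
      (m[["MCC"]] < -1 - 1e-9 || m[["MCC"]] > 1 + 1e-9))
    msgs <- c(msgs, "MCC must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

#' PipelineConfig: tunable settings for the full pipeline
#'
#' See \code{\link{pipelineConfig}} for defaults and meanings.
#'
#' @aliases PipelineConfig
#' @name PipelineConfig-class
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(k_impute = "integer",
                 missing_feature_threshold = "numeric",
                 missing_cell_threshold = "numeric",
                 joint_response_filter = "logical",
                 weight_mode = "character",
                 screen_keep_fraction = "numeric",
                 corr_threshold = "numeric",
                 corr_method = "character",
                 ae_hidden = "integer",
                 ae_epochs = "integer",
                 ae_learning_rate = "numeric",
                 boruta_max_iter = "integer",
                 boruta_alpha = "numeric",
                 boruta_trees = "integer",
                 keep_tentative = "logical",
                 rf_trees = "integer",
                 bootstrap_fraction = "numeric",
                 bootstrap_replace = "logical",
                 min_leaf = "integer",
                 ir_threshold = "numeric",
                 cv_folds = "integer",
                 select_per_fold = "logical",
                 seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  frac_in_01 <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x <= 1
  for (s in c("missing_feature_threshold", "missing_cell_threshold",
              "screen_keep_fraction", "corr_threshold", "bootstrap_fraction"))
    if (!frac_in_01(slot(object, s)))
      msgs <- c(msgs, sprintf("%s must lie in (0, 1]", s))
  for (s in c("k_impute", "ae_epochs", "boruta_max_iter", "boruta_trees",
              "rf_trees", "cv_folds", "min_leaf"))
    if (slot(object, s) < 1L && !(s == "ae_epochs" && slot(object, s) == 0L))
      msgs <- c(msgs, sprintf("%s must be >= 1", s))
  if (!object@weight_mode %in% c("inverse_distance", "as_printed"))
    msgs <- c(msgs, "weight_mode must be inverse_distance or as_printed")
  if (!object@corr_method %in% c("pairwise", "mean"))
    msgs <- c(msgs, "corr_method must be pairwise or mean")
  if (object@boruta_alpha <= 0 || object@boruta_alpha >= 1)
    msgs <- c(msgs, "boruta_alpha must lie in (0, 1)")
  if (object@ir_threshold < 1)
    msgs <- c(msgs, "ir_threshold must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticConfig: study conditions for the synthetic-data generator
#'
#' See \code{\link{syntheticConfig}} for defaults and meanings.
#'
#' @aliases SyntheticConfig
#' @name SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(n_cells = "integer", n_expression = "integer",
                 n_cna = "integer", n_snv = "integer",
                 n_informative = "integer", effect_size = "numeric",
                 noise_sd = "numeric", block_size = "integer",
                 block_cor = "numeric", missing_ic50 = "numeric",
                 missing_cna = "numeric", missing_snv = "numeric",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  if (object@n_cells < 4L) msgs <- c(msgs, "n_cells must be >= 4")
  kinds <- c(object@n_expression, object@n_cna, object@n_snv)
  if (any(kinds < 0L) || sum(kinds) < 1L)
    msgs <- c(msgs, "feature counts must be nonnegative with at least one feature")
  if (object@n_informative < 0L ||
      any(kinds > 0L & object@n_informative > kinds))
    msgs <- c(msgs, "n_informative cannot exceed the feature count of a kind")
  for (s in c("missing_ic50", "missing_cna", "missing_snv")) {
    v <- slot(object, s)
    if (v < 0 || v >= 1) msgs <- c(msgs, sprintf("%s must lie in [0, 1)", s))
  }
  if (object@effect_size < 0) msgs <- c(msgs, "effect_size must be >= 0")
  if (object@noise_sd <= 0) msgs <- c(msgs, "noise_sd must be > 0")
  if (object@block_size < 1L) msgs <- c(msgs, "block_size must be >= 1")
  if (object@block_cor < 0 || object@block_cor >= 1)
    msgs <- c(msgs, "block_cor must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})
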