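#' @include evaluation.R autoencoder.R synthetic.R io.R
NULL

.screen_kind <- function(fm, config, seed) {
  G <- ncol(featureValues(fm))
  model <- trainAutoencoder(fm, hidden_size = config@ae_hidden,
                            epochs = config@ae_epochs,
                            learning_rate = config@ae_learning_rate,
                            seed = seed)
  scores <- gedeonContributions(model, feature_ids = featureIds(fm))
  screened <- screenFeatures(fm, scores,
                             keep_fraction = config@screen_keep_fraction,
                             corr_threshold = config@corr_threshold,
                             corr_method = config@corr_method)
  abrfLog("screen [%s]: %d -> %d features", featureKind(fm), G,
          ncol(featureValues(screened)))
  list(screened = screened, scores = scores)
}

#' Run the full per-drug pipeline on in-memory tables
#'
#' Executes preprocess (missingness filters + weighted-KNN imputation),
#' median-split labelling for one drug, the autoencoder contribution
#' screen on expression and CNA (SNV features bypass the screen and join
#' afterwards), cross-validated Boruta + forest/EasyEnsemble evaluation,
#' a final Boruta selection on the full preprocessed data for the
#' reported feature list, and Wilcoxon/Fisher significance tests of the
#' selected features. All randomness derives from \code{config@seed}, so
#' a repeated run is identical.
#'
#' @param features named list of \linkS4class{FeatureMatrix} objects
#'   (an \code{expression} entry is required for imputation distances).
#' @param response a \linkS4class{ResponseTable}.
#' @param drug drug id to model; must be present in \code{response}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param out_dir if non-NULL, write selected features, per-fold metrics,
#'   labels and significance tables there.
#' @param threshold optional external IC50 labelling threshold; default
#'   is the per-drug median.
#' @return list with elements \code{metrics}
#'   (\linkS4class{MetricsReport}), \code{selection}
#'   (\linkS4class{BorutaResult} on the full data), \code{labels}
#'   (\linkS4class{LabelVector}), \code{screened_features},
#'   \code{significance} (data.frame) and \code{removed} (filter report).
#' @export
runPipelineData <- function(features, response, drug,
                            config = pipelineConfig(), out_dir = NULL,
                            threshold = NULL) {
  if (!drug %in% drugIds(response))
    stop("drug '", drug, "' not found in the response table", call. = FALSE)
  seed <- config@seed

  filtered <- filterMissing(features, response,
                            feature_threshold = config@missing_feature_threshold,
                            cell_threshold = config@missing_cell_threshold,
                            joint_response = config@joint_response_filter)
  if (!drug %in% drugIds(filtered$response))
    stop("drug '", drug, "' was removed by the missingness filter",
         call. = FALSE)
  complete <- imputeAll(filtered$features, filtered$response,
                        K = config@k_impute,
                        weight_mode = config@weight_mode)

  ic50 <- ic50Values(complete$response)[drug, ]
  labels <- assignLabels(ic50, drug = drug, threshold = threshold)

  blocks <- list()
  for (kind in names(complete$features)) {
    fm <- complete$features[[kind]]
    if (featureKind(fm) == "snv") {
      blocks[[kind]] <- featureValues(fm)
    } else {
      blocks[[kind]] <- featureValues(
        .screen_kind(fm, config,
                     deriveSeed(seed, paste0("autoencoder_", kind)))$screened)
    }
  }
  X <- do.call(cbind, unname(blocks))

  metrics <- crossValidate(X, labels, config, seed = seed, drug = drug)

  selection <- .select_features(X, labelValues(labels), config,
                                deriveSeed(seed, "select_global"))
  selected <- selection$selected
  significance <- if (length(selected))
    biomarkerSignificance(selected, labels, complete$features)
  else
    data.frame(feature = character(), kind = character(),
               p_value = numeric(), flagged = logical())

  result <- list(metrics = metrics, selection = selection$result,
                 labels = labels, screened_features = colnames(X),
                 significance = significance, removed = filtered$removed)
  if (!is.null(out_dir)) writePipelineOutputs(result, out_dir)
  result
}

#' Run the full per-drug pipeline from delimited files
#'
#' File-based front end to \code{\link{runPipelineData}}: reads the three
#' feature tables (cell lines as rows) and the response table (drugs as
#' rows), aligns them on their common cell lines, and runs the pipeline.
#'
#' @param paths named list with file paths \code{expression}, \code{cna},
#'   \code{snv} (any subset, expression required) and \code{response}.
#' @inheritParams runPipelineData
#' @return see \code{\link{runPipelineData}}.
#' @export
runPipeline <- function(paths, drug, config = pipelineConfig(),
                        out_dir = NULL, threshold = NULL) {
  kinds <- intersect(names(paths), .FEATURE_KINDS)
  if (!"expression" %in% kinds)
    stop("an expression table is required", call. = FALSE)
  if (!"response" %in% names(paths))
    stop("a response table is required", call. = FALSE)
  features <- lapply(setNames(kinds, kinds), function(k)
    readFeatureMatrix(paths[[k]], kind = k))
  response <- readResponseTable(paths$response)
  aligned <- alignCellLines(features, response)
  runPipelineData(aligned$features, aligned$response, drug, config,
                  out_dir = out_dir, threshold = threshold)
}

#' Write the pipeline's output files
#'
#' Emits \code{selected_features.txt} (one id per line),
#' \code{metrics.csv} (per-fold rows plus a mean row),
#' \code{labels.csv} (cell line, label; the threshold on a header
#' comment line), \code{significance.csv} and \code{boruta_history.csv}.
#' Contents are deterministic for a fixed config seed.
#'
#' @param result list returned by \code{\link{runPipelineData}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, \code{out_dir}.
#' @export
writePipelineOutputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(confirmedFeatures(result$selection),
             file.path(out_dir, "selected_features.txt"))

  folds <- foldMetrics(result$metrics)
  mean_row <- folds[1L, ]
  mean_row[, ] <- NA
  mean_row$fold <- NA_integer_
  for (m in names(meanMetrics(result$metrics)))
    mean_row[[m]] <- meanMetrics(result$metrics)[[m]]
  out <- rbind(cbind(set = "fold", folds),
               cbind(set = "mean", mean_row))
  data.table::fwrite(out, file.path(out_dir, "metrics.csv"), na = "NA")

  lab <- labelValues(result$labels)
  lab_df <- data.frame(cell_line = names(lab), label = as.character(lab))
  con <- file(file.path(out_dir, "labels.csv"), "w")
  writeLines(sprintf("# drug=%s threshold=%.10g", result$labels@drug,
                     labelThreshold(result$labels)), con)
  close(con)
  data.table::fwrite(lab_df, file.path(out_dir, "labels.csv"),
                     append = TRUE, col.names = TRUE)

  data.table::fwrite(result$significance,
                     file.path(out_dir, "significance.csv"))
  data.table::fwrite(selectionHistory(result$selection),
                     file.path(out_dir, "boruta_history.csv"))
  invisible(out_dir)
}

#' Write a synthetic dataset as the standard pipeline file set
#'
#' Emits \code{expression.csv}, \code{cna.csv}, \code{snv.csv} (for
#' non-empty kinds), \code{response.csv} and \code{truth.json}
#' (informative feature ids, coefficients, seed).
#'
#' @param dataset a dataset from \code{\link{generateDataset}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
writeDataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (kind in names(dataset$features)) {
    p <- file.path(out_dir, paste0(kind, ".csv"))
    writeFeatureMatrix(dataset$features[[kind]], p)
    paths[[kind]] <- p
  }
  paths$response <- file.path(out_dir, "response.csv")
  writeResponseTable(dataset$response, paths$response)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(dataset$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths$truth <- truth_path
  invisible(paths)
}
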