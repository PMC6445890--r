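#' @include AllClasses.R
NULL

#' Accessors for abrf data classes
#'
#' \code{featureValues} returns the underlying numeric matrix (cell line x
#' feature, \code{NA} = missing); \code{featureKind} the feature kind;
#' \code{cellLines} and \code{featureIds} the identifier vectors;
#' \code{ic50Values} the drug x cell-line IC50 matrix; \code{drugIds} the
#' drug identifiers.
#'
#' @param x a \linkS4class{FeatureMatrix} or \linkS4class{ResponseTable}.
#' @return the requested component.
#' @examples
#' m <- matrix(1:4, 2, 2, dimnames = list(c("c1", "c2"), c("g1", "g2")))
#' fm <- FeatureMatrix(m, "cna")
#' featureKind(fm)
#' cellLines(fm)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))
#' @rdname accessors
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("ic50Values", function(x) standardGeneric("ic50Values"))
#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname accessors
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
setMethod("featureKind", "FeatureMatrix", function(x) x@kind)
#' @rdname accessors
setMethod("cellLines", "FeatureMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("featureIds", "FeatureMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("ic50Values", "ResponseTable", function(x) x@ic50)
#' @rdname accessors
setMethod("cellLines", "ResponseTable", function(x) colnames(x@ic50))
#' @rdname accessors
setMethod("drugIds", "ResponseTable", function(x) rownames(x@ic50))

#' @describeIn FeatureMatrix-class matrix dimensions.
#' @param x a FeatureMatrix.
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

#' Subset a FeatureMatrix by cell lines and/or features
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param i cell-line subscript. @param j feature subscript.
#' @param ... ignored. @param drop ignored; the result stays a matrix.
#' @return a \linkS4class{FeatureMatrix} of the selected rows/columns.
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  FeatureMatrix(v, x@kind)
})

setMethod("show", "FeatureMatrix", function(object) {
  v <- object@values
  cat(sprintf("FeatureMatrix [%s]: %d cell lines x %d features, %d missing (%.1f%%)\n",
              object@kind, nrow(v), ncol(v), sum(is.na(v)),
              100 * mean(is.na(v))))
})

setMethod("show", "ResponseTable", function(object) {
  v <- object@ic50
  cat(sprintf("ResponseTable: %d drugs x %d cell lines, %d missing IC50 (%.1f%%)\n",
              nrow(v), ncol(v), sum(is.na(v)), 100 * mean(is.na(v))))
})

setMethod("show", "LabelVector", function(object) {
  tab <- table(object@labels)
  cat(sprintf("LabelVector [%s]: %d sensitive / %d non-sensitive (threshold %.4g)\n",
              object@drug, tab[["sensitive"]], tab[["non_sensitive"]],
              object@threshold))
})

setMethod("show", "AutoencoderModel", function(object) {
  cat(sprintf("AutoencoderModel: %d inputs, %d hidden units, %d epochs, final loss %.4g\n",
              nrow(object@W), ncol(object@W), object@epochs_run,
              object@final_loss))
})

setMethod("show", "ContributionScores", function(object) {
  cat(sprintf("ContributionScores: %d inputs, %d hidden units\n",
              nrow(object@P), ncol(object@P)))
  top <- head(order(object@q, decreasing = TRUE), 5L)
  cat("  top contributions:",
      paste(sprintf("%s=%.3f", object@feature_ids[top], object@q[top]),
            collapse = ", "), "\n")
})

setMethod("show", "BorutaResult", function(object) {
  cat(sprintf("BorutaResult: %d confirmed, %d rejected, %d tentative after %d iterations\n",
              length(object@confirmed), length(object@rejected),
              length(object@tentative), object@iterations_run))
})

setMethod("show", "ForestModel", function(object) {
  cat(sprintf("ForestModel: %d trees on %d features, bootstrap size %d\n",
              object@n_trees, length(object@feature_ids),
              object@bootstrap_size))
})

setMethod("show", "EasyEnsembleModel", function(object) {
  cat(sprintf("EasyEnsembleModel: %d balanced sub-forests (IR = %.2f)\n",
              length(object@forests), object@ir))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport [%s]: %d folds\n", object@drug,
              nrow(object@folds)))
  cat("  mean:", paste(sprintf("%s=%.4f", names(object@means), object@means),
                       collapse = " "), "\n")
})

#' Selection accessors for BorutaResult
#'
#' @param x a \linkS4class{BorutaResult}.
#' @return character vectors of feature ids, or the history data.frame.
#' @name boruta-accessors
NULL

#' @rdname boruta-accessors
#' @export
setGeneric("confirmedFeatures", function(x) standardGeneric("confirmedFeatures"))
#' @rdname boruta-accessors
#' @export
setGeneric("rejectedFeatures", function(x) standardGeneric("rejectedFeatures"))
#' @rdname boruta-accessors
#' @export
setGeneric("tentativeFeatures", function(x) standardGeneric("tentativeFeatures"))
#' @rdname boruta-accessors
#' @export
setGeneric("selectionHistory", function(x) standardGeneric("selectionHistory"))

#' @rdname boruta-accessors
setMethod("confirmedFeatures", "BorutaResult", function(x) x@confirmed)
#' @rdname boruta-accessors
setMethod("rejectedFeatures", "BorutaResult", function(x) x@rejected)
#' @rdname boruta-accessors
setMethod("tentativeFeatures", "BorutaResult", function(x) x@tentative)
#' @rdname boruta-accessors
setMethod("selectionHistory", "BorutaResult", function(x) x@history)

#' Metric accessors for MetricsReport
#'
#' @param x a \linkS4class{MetricsReport}.
#' @return \code{foldMetrics}: per-fold data.frame; \code{meanMetrics}:
#'   named numeric vector of fold means.
#' @name metrics-accessors
NULL

#' @rdname metrics-accessors
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))
#' @rdname metrics-accessors
#' @export
setGeneric("meanMetrics", function(x) standardGeneric("meanMetrics"))

#' @rdname metrics-accessors
setMethod("foldMetrics", "MetricsReport", function(x) x@folds)
#' @rdname metrics-accessors
setMethod("meanMetrics", "MetricsReport", function(x) x@means)

#' Label accessors for LabelVector
#'
#' @param x a \linkS4class{LabelVector}.
#' @return \code{labelValues}: named factor of labels;
#'   \code{labelThreshold}: the IC50 threshold used.
#' @name label-accessors
NULL

#' @rdname label-accessors
#' @export
setGeneric("labelValues", function(x) standardGeneric("labelValues"))
#' @rdname label-accessors
#' @export
setGeneric("labelThreshold", function(x) standardGeneric("labelThreshold"))

#' @rdname label-accessors
setMethod("labelValues", "LabelVector", function(x) x@labels)
#' @rdname label-accessors
setMethod("labelThreshold", "LabelVector", function(x) x@threshold)
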