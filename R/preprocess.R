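#' @include AllClasses.R
NULL

.check_aligned_cells <- function(features, response) {
  cells <- cellLines(features[[1L]])
  for (fm in features)
    if (!identical(cellLines(fm), cells))
      stop("feature matrices must share one cell-line set in one order",
           call. = FALSE)
  if (!is.null(response) && !identical(cellLines(response), cells))
    stop("response table cell lines must match the feature matrices",
         call. = FALSE)
  cells
}

#' Align feature matrices and a response table on common cell lines
#'
#' Restricts every table to the intersection of their cell-line sets, in
#' the order of the first feature matrix. Tables from different sources
#' rarely cover identical cell-line panels; downstream functions require
#' one shared ordered set.
#'
#' @param features named list of \linkS4class{FeatureMatrix} objects.
#' @param response a \linkS4class{ResponseTable}.
#' @return list with elements \code{features} and \code{response}.
#' @export
alignCellLines <- function(features, response) {
  common <- Reduce(intersect, lapply(features, cellLines))
  common <- intersect(common, cellLines(response))
  if (length(common) < 2L)
    stop("fewer than 2 cell lines shared across input tables", call. = FALSE)
  features <- lapply(features, function(fm) fm[common, ])
  response <- ResponseTable(ic50Values(response)[, common, drop = FALSE])
  list(features = features, response = response)
}

#' Apply the 50% missingness filters
#'
#' Two-stage filter: first drop feature columns (and, analogously, drugs
#' in the response table) whose missing fraction exceeds
#' \code{feature_threshold} strictly; then drop cell lines whose missing
#' fraction across the remaining CNA/SNV features (and, by default, the
#' remaining drugs' IC50 values) exceeds \code{cell_threshold} strictly.
#' Both comparisons are strict, so a column missing exactly half its
#' values is kept.
#'
#' @param features named list of \linkS4class{FeatureMatrix} objects
#'   sharing one cell-line set.
#' @param response a \linkS4class{ResponseTable} over the same cell lines.
#' @param feature_threshold,cell_threshold missing-fraction cutoffs in
#'   (0, 1].
#' @param joint_response include response missingness in the cell-line
#'   filter (default TRUE).
#' @return list with elements \code{features}, \code{response} and
#'   \code{removed} (a record of dropped feature/drug/cell ids).
#' @export
filterMissing <- function(features, response, feature_threshold = 0.5,
                          cell_threshold = 0.5, joint_response = TRUE) {
  stopifnot(feature_threshold > 0, feature_threshold <= 1,
            cell_threshold > 0, cell_threshold <= 1)
  cells <- .check_aligned_cells(features, response)

  removed <- list(features = character(), drugs = character(),
                  cells = character())

  # stage 1: features (and drugs) with too many missing cell lines
  features <- lapply(features, function(fm) {
    v <- featureValues(fm)
    miss <- colMeans(is.na(v))
    drop <- miss > feature_threshold
    removed$features <<- c(removed$features, colnames(v)[drop])
    if (all(drop))
      stop("all ", featureKind(fm), " features removed by the missingness filter",
           call. = FALSE)
    fm[, !drop]
  })
  ic <- ic50Values(response)
  drug_miss <- rowMeans(is.na(ic))
  drop_drug <- drug_miss > feature_threshold
  removed$drugs <- rownames(ic)[drop_drug]
  ic <- ic[!drop_drug, , drop = FALSE]
  if (nrow(ic) == 0L)
    stop("all drugs removed by the missingness filter", call. = FALSE)

  # stage 2: cell lines with too many missing entries among what remains
  miss_counts <- rep(0, length(cells))
  totals <- rep(0, length(cells))
  for (fm in features) {
    v <- featureValues(fm)
    miss_counts <- miss_counts + rowSums(is.na(v))
    totals <- totals + ncol(v)
  }
  if (joint_response) {
    miss_counts <- miss_counts + colSums(is.na(ic))
    totals <- totals + nrow(ic)
  }
  cell_frac <- miss_counts / totals
  drop_cell <- cell_frac > cell_threshold
  removed$cells <- cells[drop_cell]
  if (all(drop_cell))
    stop("all cell lines removed by the missingness filter", call. = FALSE)
  keep <- !drop_cell
  features <- lapply(features, function(fm) fm[keep, ])
  response <- ResponseTable(ic[, keep, drop = FALSE])
  list(features = features, response = response, removed = removed)
}

#' Squared Euclidean distance between two cell lines' expression profiles
#'
#' Cell-line diversity for the KNN imputation is measured on the complete
#' expression table as the squared L2 distance.
#'
#' @param c,k cell-line identifiers.
#' @param expression an expression \linkS4class{FeatureMatrix} with no
#'   missing values.
#' @return a nonnegative number; 0 for identical profiles.
#' @export
cellDistance <- function(c, k, expression) {
  v <- featureValues(expression)
  if (anyNA(v))
    stop("expression matrix must be complete to measure distances",
         call. = FALSE)
  if (!all(c(c, k) %in% rownames(v)))
    stop("unknown cell line id", call. = FALSE)
  sum((v[c, ] - v[k, ])^2)
}

.distance_row <- function(expr_values, c) {
  d <- expr_values - matrix(expr_values[c, ], nrow(expr_values),
                            ncol(expr_values), byrow = TRUE)
  rowSums(d * d)
}

#' Find the K nearest candidate cell lines for one missing entry
#'
#' Candidates must have an observed value for the variable being imputed;
#' the target cell is excluded. Distances are squared Euclidean on the
#' expression profiles. If fewer than K candidates exist all are returned
#' with a warning. Ties at the K-th distance break by the candidates'
#' input order.
#'
#' @param c target cell-line id.
#' @param candidates cell-line ids with an observed value for the target
#'   variable.
#' @param K number of neighbours to return.
#' @param expression complete expression \linkS4class{FeatureMatrix}.
#' @return list with \code{ids} and nondecreasing \code{distances}.
#' @export
findNeighbors <- function(c, candidates, K, expression) {
  candidates <- setdiff(candidates, c)
  if (length(candidates) == 0L)
    stop("no candidate neighbours with an observed value for cell ", c,
         call. = FALSE)
  v <- featureValues(expression)
  if (anyNA(v))
    stop("expression matrix must be complete to measure distances",
         call. = FALSE)
  d <- .distance_row(v, c)[candidates]
  if (length(candidates) < K)
    abrfLog("only %d candidate neighbours (K = %d) for cell %s",
            length(candidates), K, c, level = "warn")
  ord <- order(d)  # stable: ties keep candidate input order
  take <- ord[seq_len(min(K, length(candidates)))]
  list(ids = candidates[take], distances = unname(d[take]))
}

#' Weighted-mean imputation of a real-valued entry
#'
#' Imputes a missing IC50 or CNA value as a weighted mean of the
#' neighbours' observed values. \code{weight_mode = "inverse_distance"}
#' (default) weights neighbours by 1 / (d + 1e-8), normalised to sum to 1;
#' \code{"as_printed"} weights by d / sum(d), which gives farther
#' neighbours more weight. If every distance is zero the weights are
#' uniform. Either way the result is a convex combination of neighbour
#' values.
#'
#' @param values observed neighbour values.
#' @param distances matching nonnegative distances.
#' @param weight_mode \code{"inverse_distance"} or \code{"as_printed"}.
#' @return the imputed value.
#' @examples
#' imputeReal(c(10, 20), c(1, 3), "as_printed")        # 17.5
#' imputeReal(c(10, 20), c(1, 3), "inverse_distance")  # 12.5
#' @export
imputeReal <- function(values, distances,
                       weight_mode = c("inverse_distance", "as_printed")) {
  weight_mode <- match.arg(weight_mode)
  if (length(values) == 0L) stop("empty neighbour set", call. = FALSE)
  stopifnot(length(values) == length(distances), all(distances >= 0))
  if (all(distances == 0)) {
    w <- rep(1 / length(values), length(values))
  } else if (weight_mode == "as_printed") {
    w <- distances / sum(distances)
  } else {
    w <- 1 / (distances + 1e-8)
    w <- w / sum(w)
  }
  sum(w * values)
}

#' Majority-vote imputation of a binary (SNV) entry
#'
#' Returns 1 iff strictly more neighbours carry the mutation than not;
#' ties and minorities give 0 (wild type).
#'
#' @param values observed neighbour values in \{0, 1\}.
#' @return 0 or 1.
#' @export
imputeBinary <- function(values) {
  if (length(values) == 0L) stop("empty neighbour set", call. = FALSE)
  stopifnot(all(values %in% c(0, 1)))
  as.numeric(sum(values == 1) > sum(values == 0))
}

#' Impute every missing entry of the CNA/SNV/response tables
#'
#' For each missing entry, the K cell lines nearest in expression space
#' among those with an observed value for that variable supply a weighted
#' mean (real variables) or majority vote (SNV). Observed entries are
#' never modified. Run \code{\link{filterMissing}} first.
#'
#' @param features named list of \linkS4class{FeatureMatrix} objects; the
#'   expression matrix must be complete.
#' @param response a \linkS4class{ResponseTable} over the same cell lines.
#' @param K number of neighbours (default 10).
#' @param weight_mode passed to \code{\link{imputeReal}}.
#' @return list with completed \code{features} and \code{response}.
#' @export
imputeAll <- function(features, response, K = 10L,
                      weight_mode = c("inverse_distance", "as_printed")) {
  weight_mode <- match.arg(weight_mode)
  cells <- .check_aligned_cells(features, response)
  expr <- NULL
  for (fm in features) if (featureKind(fm) == "expression") expr <- fm
  if (is.null(expr)) stop("an expression matrix is required", call. = FALSE)
  ev <- featureValues(expr)
  if (anyNA(ev))
    stop("expression matrix must be complete (no missing values)",
         call. = FALSE)

  dist_cache <- new.env(parent = emptyenv())
  dists_for <- function(c) {
    if (is.null(dist_cache[[c]])) dist_cache[[c]] <- .distance_row(ev, c)
    dist_cache[[c]]
  }

  impute_column <- function(col, binary) {
    miss <- which(is.na(col))
    if (!length(miss)) return(col)
    obs_cells <- cells[!is.na(col)]
    if (!length(obs_cells))
      stop("variable with no observed values cannot be imputed",
           call. = FALSE)
    for (i in miss) {
      c_id <- cells[i]
      cand <- setdiff(obs_cells, c_id)
      if (!length(cand))
        stop("no candidate neighbours for cell ", c_id, call. = FALSE)
      d <- dists_for(c_id)[cand]
      ord <- order(d)
      take <- ord[seq_len(min(K, length(cand)))]
      vals <- col[match(cand[take], cells)]
      col[i] <- if (binary) imputeBinary(vals)
                else imputeReal(vals, unname(d[cand[take]]), weight_mode)
    }
    col
  }

  features <- lapply(features, function(fm) {
    v <- featureValues(fm)
    if (!anyNA(v)) return(fm)
    binary <- featureKind(fm) == "snv"
    for (j in seq_len(ncol(v)))
      if (anyNA(v[, j])) v[, j] <- impute_column(v[, j], binary)
    FeatureMatrix(v, featureKind(fm))
  })
  ic <- ic50Values(response)
  for (r in seq_len(nrow(ic)))
    if (anyNA(ic[r, ])) ic[r, ] <- impute_column(ic[r, ], binary = FALSE)
  list(features = features, response = ResponseTable(ic))
}
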