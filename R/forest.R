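#' @include AllClasses.R
NULL

.as_label_factor <- function(y) {
  if (is(y, "LabelVector")) y <- labelValues(y)
  if (!is.factor(y)) y <- factor(y, levels = .LABEL_LEVELS)
  if (!identical(levels(y), .LABEL_LEVELS))
    stop("labels must have levels non_sensitive, sensitive", call. = FALSE)
  y
}

.feature_matrix_input <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyNA(X)) stop("feature table must be complete", call. = FALSE)
  X
}

#' Train a random forest of CART trees
#'
#' Grows \code{n_trees} CARTs, each on an independent subsample of
#' \code{ceiling(bootstrap_fraction * N)} cell lines (without replacement
#' by default), with Gini splits over \code{mtry} randomly chosen features
#' per node, grown to purity. Out-of-bag sample ids are stored per tree
#' for permutation importance.
#'
#' @param X numeric matrix or data.frame, samples x features.
#' @param y labels: a \linkS4class{LabelVector} or a factor with levels
#'   \code{non_sensitive}, \code{sensitive}.
#' @param n_trees number of trees (default 1000).
#' @param bootstrap_fraction per-tree subsample fraction (default 0.632).
#' @param replace draw the per-tree sample with replacement.
#' @param mtry features tried per split; default \code{ceiling(sqrt(p))}.
#' @param min_leaf minimum samples per leaf.
#' @param seed RNG seed for bootstraps and split sampling.
#' @return a \linkS4class{ForestModel}.
#' @export
trainForest <- function(X, y, n_trees = 1000L, bootstrap_fraction = 0.632,
                        replace = FALSE, mtry = NULL, min_leaf = 1L,
                        seed = 1L) {
  X <- .feature_matrix_input(X)
  y <- .as_label_factor(y)
  stopifnot(nrow(X) == length(y))
  if (any(table(y) < 2L))
    stop("need at least 2 samples of each class to train", call. = FALSE)
  if (is.null(mtry)) mtry <- as.integer(ceiling(sqrt(ncol(X))))
  yi <- as.integer(y) - 1L  # 0 = non_sensitive, 1 = sensitive
  fit <- cpp_train_forest(X, yi, as.integer(n_trees), as.integer(mtry),
                          bootstrap_fraction, isTRUE(replace),
                          as.integer(min_leaf), as.integer(seed))
  new("ForestModel", trees = fit$trees, oob = fit$oob,
      feature_ids = colnames(X), n_trees = as.integer(n_trees),
      bootstrap_size = as.integer(fit$bootstrap_size),
      seed = as.integer(seed))
}

#' Predict by tree (or sub-forest) voting
#'
#' For a \linkS4class{ForestModel}, the score is the fraction of trees
#' voting \code{sensitive} and the label is \code{sensitive} only when
#' that fraction exceeds 1/2 -- an exact tie yields \code{non_sensitive},
#' the majority-class default. For an \linkS4class{EasyEnsembleModel},
#' the label is the majority vote of the sub-forest labels (even ties
#' again \code{non_sensitive}) and the score the mean of the sub-forest
#' vote fractions.
#'
#' @param model a \linkS4class{ForestModel} or
#'   \linkS4class{EasyEnsembleModel}.
#' @param X samples x features table with the training columns.
#' @return data.frame with columns \code{label} (factor) and \code{score}
#'   (sensitive-vote fraction in [0, 1]).
#' @export
setGeneric("predictVote", function(model, X) standardGeneric("predictVote"))

#' @rdname predictVote
setMethod("predictVote", "ForestModel", function(model, X) {
  X <- .feature_matrix_input(X)
  if (!identical(colnames(X), model@feature_ids))
    stop("feature columns do not match the training schema", call. = FALSE)
  frac <- cpp_forest_vote(model@trees, X)
  data.frame(
    label = factor(ifelse(frac > 0.5, "sensitive", "non_sensitive"),
                   levels = .LABEL_LEVELS),
    score = frac, row.names = rownames(X))
})

#' @rdname predictVote
setMethod("predictVote", "EasyEnsembleModel", function(model, X) {
  preds <- lapply(model@forests, function(f) predictVote(f, X))
  votes <- vapply(preds, function(p) as.integer(p$label) - 1L,
                  integer(nrow(as.matrix(X))))
  votes <- matrix(votes, ncol = length(preds))
  scores <- vapply(preds, function(p) p$score, numeric(nrow(votes)))
  scores <- matrix(scores, ncol = length(preds))
  sens_votes <- rowSums(votes)
  n_forest <- length(model@forests)
  data.frame(
    label = factor(ifelse(sens_votes > n_forest / 2, "sensitive",
                          "non_sensitive"), levels = .LABEL_LEVELS),
    score = rowMeans(scores),
    row.names = rownames(as.matrix(X)))
})

#' Train the imbalance-aware classifier
#'
#' Computes the imbalance ratio IR = |non-sensitive| / |sensitive|. When
#' IR is at most \code{ir_threshold} (default 2) a single
#' \code{\link{trainForest}} on all data is returned. Otherwise the
#' majority class is partitioned at random into \code{T = floor(IR)}
#' disjoint subsets whose sizes differ by at most one, and one forest is
#' trained per subset together with the full minority class
#' (EasyEnsemble undersampling).
#'
#' @inheritParams trainForest
#' @param ir_threshold imbalance ratio above which EasyEnsemble engages.
#' @return a \linkS4class{ForestModel} (IR below threshold) or an
#'   \linkS4class{EasyEnsembleModel}.
#' @export
trainEasyEnsemble <- function(X, y, n_trees = 1000L,
                              bootstrap_fraction = 0.632, replace = FALSE,
                              mtry = NULL, min_leaf = 1L, ir_threshold = 2,
                              seed = 1L) {
  X <- .feature_matrix_input(X)
  y <- .as_label_factor(y)
  ir <- imbalanceRatio(y)
  if (ir <= ir_threshold) {
    return(trainForest(X, y, n_trees = n_trees,
                       bootstrap_fraction = bootstrap_fraction,
                       replace = replace, mtry = mtry, min_leaf = min_leaf,
                       seed = seed))
  }
  T_sub <- floor(ir)
  maj <- which(y == "non_sensitive")
  mino <- which(y == "sensitive")
  maj_perm <- .with_seed(deriveSeed(seed, "easyensemble_partition"),
                         sample(maj))
  base <- length(maj) %/% T_sub
  extra <- length(maj) %% T_sub
  sizes <- rep(base, T_sub) + c(rep(1L, extra), rep(0L, T_sub - extra))
  bounds <- cumsum(c(0L, sizes))
  partition <- lapply(seq_len(T_sub), function(i)
    maj_perm[(bounds[i] + 1L):bounds[i + 1L]])

  forests <- lapply(seq_len(T_sub), function(i) {
    idx <- c(partition[[i]], mino)
    if (sum(y[idx] == "sensitive") < 2L || sum(y[idx] == "non_sensitive") < 2L)
      stop("degenerate EasyEnsemble subset: fewer than 2 samples per class",
           call. = FALSE)
    trainForest(X[idx, , drop = FALSE], y[idx], n_trees = n_trees,
                bootstrap_fraction = bootstrap_fraction, replace = replace,
                mtry = mtry, min_leaf = min_leaf,
                seed = deriveSeed(seed, paste0("easyensemble_forest_", i)))
  })
  part_ids <- lapply(partition, function(ix) {
    ids <- rownames(X)[ix]
    if (is.null(ids)) as.character(ix) else ids
  })
  new("EasyEnsembleModel", forests = forests, partition = part_ids, ir = ir)
}

#' Serialize / restore a forest model as JSON text
#'
#' Trees are stored as plain integer/real tables, so models can be
#' re-scored later without retraining.
#'
#' @param model a \linkS4class{ForestModel}.
#' @param path output (input) file path.
#' @return \code{writeForestModel}: invisibly, \code{path};
#'   \code{readForestModel}: a \linkS4class{ForestModel}.
#' @export
writeForestModel <- function(model, path) {
  stopifnot(is(model, "ForestModel"))
  obj <- list(feature_ids = model@feature_ids, n_trees = model@n_trees,
              bootstrap_size = model@bootstrap_size, seed = model@seed,
              oob = model@oob, trees = model@trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeForestModel
#' @export
readForestModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  trees <- lapply(obj$trees, function(tr) {
    out <- list()
    for (f in c("var", "left", "right", "pred", "n0", "n1"))
      out[[f]] <- as.integer(unlist(tr[[f]]))
    out$val <- as.numeric(unlist(tr$val))
    out[c("var", "val", "left", "right", "pred", "n0", "n1")]
  })
  oob <- lapply(obj$oob, function(o) as.integer(unlist(o)))
  new("ForestModel", trees = trees, oob = oob,
      feature_ids = as.character(unlist(obj$feature_ids)),
      n_trees = as.integer(obj$n_trees),
      bootstrap_size = as.integer(obj$bootstrap_size),
      seed = as.integer(obj$seed))
}
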