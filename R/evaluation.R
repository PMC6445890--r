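#' @include boruta.R
NULL

#' Confusion-matrix classification metrics
#'
#' Computes accuracy, recall (sensitivity), specificity, F1 and the
#' Matthews correlation coefficient from the four confusion counts, with
#' \code{sensitive} as the positive class. Any metric whose denominator
#' is zero is defined as 0 and listed in the \code{"flagged"} attribute.
#'
#' @param TP,FP,FN,TN nonnegative integer confusion counts.
#' @return named numeric vector (ACC, REC, SPC, F1, MCC) with attribute
#'   \code{flagged}.
#' @examples
#' computeMetrics(TP = 40, FP = 10, FN = 20, TN = 30)
#' @export
computeMetrics <- function(TP, FP, FN, TN) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(counts < 0)) stop("confusion counts must be nonnegative",
                            call. = FALSE)
  if (sum(counts) == 0) stop("no evaluated samples", call. = FALSE)
  flagged <- character()
  safe_div <- function(num, den, name) {
    if (den == 0) {
      flagged <<- c(flagged, name)
      return(0)
    }
    num / den
  }
  acc <- (TP + TN) / sum(counts)
  rec <- safe_div(TP, TP + FN, "REC")
  spc <- safe_div(TN, TN + FP, "SPC")
  f1 <- safe_div(2 * TP, 2 * TP + FP + FN, "F1")
  mcc_den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
             sqrt(as.numeric(FP + TN)) * sqrt(as.numeric(FN + TN))
  mcc <- if (mcc_den == 0) {
    flagged <- c(flagged, "MCC")
    0
  } else {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  }
  out <- c(ACC = acc, REC = rec, SPC = spc, F1 = f1, MCC = mcc)
  attr(out, "flagged") <- flagged
  out
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random
#' sensitive sample scores above a random non-sensitive one, with tied
#' scores counting one half.
#'
#' @param scores continuous sensitive-vote fractions (or any scores).
#' @param labels factor or \linkS4class{LabelVector}; both classes must
#'   be present.
#' @return AUC in [0, 1].
#' @export
computeAUC <- function(scores, labels) {
  y <- .as_label_factor(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == "sensitive")
  n_neg <- sum(y == "non_sensitive")
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == "sensitive"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  .with_seed(seed, {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- ((seq_along(idx) - 1L) %% n_folds) + 1L
    }
  })
  fold
}

.select_features <- function(X, y, config, seed) {
  res <- borutaRun(X, y, max_iter = config@boruta_max_iter,
                   alpha = config@boruta_alpha,
                   n_trees = config@boruta_trees,
                   bootstrap_fraction = config@bootstrap_fraction,
                   replace = config@bootstrap_replace,
                   min_leaf = config@min_leaf, seed = seed)
  selected <- confirmedFeatures(res)
  if (config@keep_tentative)
    selected <- c(selected, tentativeFeatures(res))
  list(result = res, selected = selected)
}

#' Cross-validated evaluation of the selection + classification pipeline
#'
#' Stratified seeded partition into \code{config@cv_folds} near-equal
#' folds. For each fold, Boruta feature selection (by default) and
#' forest/EasyEnsemble training run on the nine training folds only and
#' the held-out fold is scored; test folds never influence selection or
#' training. With \code{select_per_fold = FALSE} selection runs once on
#' the full data before the loop (a leakier protocol, provided for
#' comparison). If a fold's selection confirms nothing, all candidate
#' features are used for that fold and a warning is logged.
#'
#' @param X complete numeric matrix, samples x features, rownames = cell
#'   lines.
#' @param y labels (factor or \linkS4class{LabelVector}).
#' @param config a \linkS4class{PipelineConfig}.
#' @param seed master seed; defaults to \code{config@seed}.
#' @param drug drug id recorded in the report.
#' @return a \linkS4class{MetricsReport}.
#' @export
crossValidate <- function(X, y, config = pipelineConfig(),
                          seed = config@seed, drug = "drug") {
  X <- .feature_matrix_input(X)
  y <- .as_label_factor(y)
  stopifnot(nrow(X) == length(y))
  n_folds <- config@cv_folds
  if (any(table(y) < n_folds))
    abrfLog("a class has fewer samples (%d) than folds (%d)",
            min(table(y)), n_folds, level = "warn")
  fold <- .stratified_folds(y, n_folds, deriveSeed(seed, "cv_folds"))

  selection_once <- NULL
  if (!config@select_per_fold)
    selection_once <- .select_features(X, y, config,
                                       deriveSeed(seed, "select_global"))

  rows <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    te <- !tr
    y_tr <- y[tr]
    if (length(unique(y_tr)) < 2L)
      stop("stratification failed: a class is absent from training fold ", k,
           call. = FALSE)
    sel <- if (config@select_per_fold)
      .select_features(X[tr, , drop = FALSE], y_tr, config,
                       deriveSeed(seed, paste0("select_fold_", k)))
    else selection_once
    feats <- sel$selected
    if (length(feats) == 0L) {
      abrfLog("fold %d: no features selected; falling back to all %d candidates",
              k, ncol(X), level = "warn")
      feats <- colnames(X)
    }
    model <- trainEasyEnsemble(X[tr, feats, drop = FALSE], y_tr,
                               n_trees = config@rf_trees,
                               bootstrap_fraction = config@bootstrap_fraction,
                               replace = config@bootstrap_replace,
                               min_leaf = config@min_leaf,
                               ir_threshold = config@ir_threshold,
                               seed = deriveSeed(seed, paste0("forest_fold_", k)))
    pred <- predictVote(model, X[te, feats, drop = FALSE])
    y_te <- y[te]
    TP <- sum(y_te == "sensitive" & pred$label == "sensitive")
    FP <- sum(y_te == "non_sensitive" & pred$label == "sensitive")
    FN <- sum(y_te == "sensitive" & pred$label == "non_sensitive")
    TN <- sum(y_te == "non_sensitive" & pred$label == "non_sensitive")
    m <- computeMetrics(TP, FP, FN, TN)
    auc <- if (length(unique(y_te)) < 2L) NA_real_
           else computeAUC(pred$score, y_te)
    rows[[k]] <- data.frame(fold = k, TP = TP, FP = FP, FN = FN, TN = TN,
                            ACC = m[["ACC"]], REC = m[["REC"]],
                            SPC = m[["SPC"]], F1 = m[["F1"]],
                            MCC = m[["MCC"]], AUC = auc)
  }
  folds_df <- do.call(rbind, rows)
  metric_cols <- c("ACC", "REC", "SPC", "F1", "MCC", "AUC")
  means <- colMeans(folds_df[, metric_cols, drop = FALSE], na.rm = TRUE)
  fold_names <- rownames(X)
  if (is.null(fold_names)) fold_names <- as.character(seq_len(nrow(X)))
  new("MetricsReport", drug = drug, folds = folds_df, means = means,
      fold_assignment = setNames(as.integer(fold), fold_names),
      seed = as.integer(seed))
}

#' Significance of selected features against the class labels
#'
#' Real-valued features (expression, CNA) are tested with the two-sided
#' Wilcoxon rank-sum test between sensitive and non-sensitive cell lines;
#' binary SNV features with the two-sided Fisher exact test on the 2 x 2
#' mutation-by-class table. P values are reported raw (no multiplicity
#' correction). Features constant across cell lines get p = 1 and a flag.
#'
#' @param features character vector of selected feature ids.
#' @param labels a \linkS4class{LabelVector} or named factor.
#' @param feature_matrices named list of complete
#'   \linkS4class{FeatureMatrix} objects in which to look the features up.
#' @return data.frame with columns \code{feature}, \code{kind},
#'   \code{p_value}, \code{flagged}.
#' @export
biomarkerSignificance <- function(features, labels, feature_matrices) {
  lab <- if (is(labels, "LabelVector")) labelValues(labels) else labels
  if (is.null(names(lab))) stop("labels must be named by cell line",
                                call. = FALSE)
  if (length(unique(lab)) < 2L)
    stop("both classes must be present", call. = FALSE)
  out <- lapply(features, function(f) {
    fm <- NULL
    for (m in feature_matrices) if (f %in% featureIds(m)) { fm <- m; break }
    if (is.null(fm)) stop("feature not found in any matrix: ", f,
                          call. = FALSE)
    v <- featureValues(fm)[names(lab), f]
    if (anyNA(v)) stop("feature ", f, " has missing values; impute first",
                       call. = FALSE)
    if (length(unique(v)) < 2L)
      return(data.frame(feature = f, kind = featureKind(fm), p_value = 1,
                        flagged = TRUE, stringsAsFactors = FALSE))
    p <- if (featureKind(fm) == "snv") {
      tab <- table(factor(v, levels = c(0, 1)), lab)
      fisher.test(tab)$p.value
    } else {
      suppressWarnings(
        wilcox.test(v[lab == "sensitive"],
                    v[lab == "non_sensitive"])$p.value)
    }
    data.frame(feature = f, kind = featureKind(fm), p_value = p,
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
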