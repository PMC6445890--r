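#' @include forest.R
NULL

#' Extend a feature table with shadow features
#'
#' Appends one shadow per original column: an independent row permutation
#' of that column, which preserves the marginal distribution but destroys
#' any association with the labels. Shadow columns are named
#' \code{shadow__<feature>}. Original columns are returned untouched.
#' Following the original Boruta algorithm, when fewer than
#' \code{min_shadows} columns are available the sources are recycled so
#' that at least that many shadows enter the comparison (the maximum
#' shadow Z score is a poor bar when drawn from one or two shadows).
#'
#' @param X complete numeric matrix (samples x features) or
#'   \linkS4class{FeatureMatrix}.
#' @param seed RNG seed for the shuffles.
#' @param min_shadows minimum number of shadow columns (default 5).
#' @return a matrix with the original columns followed by
#'   \code{max(ncol(X), min_shadows)} shadow columns.
#' @export
makeShadow <- function(X, seed = 1L, min_shadows = 5L) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  X <- .feature_matrix_input(X)
  src <- X
  copy <- 1L
  while (ncol(src) < min_shadows) {
    copy <- copy + 1L
    extra <- X
    colnames(extra) <- paste0(colnames(X), "__", copy)
    src <- cbind(src, extra)
  }
  shadows <- .with_seed(seed, apply(src, 2L, sample))
  colnames(shadows) <- paste0("shadow__", colnames(src))
  cbind(X, shadows)
}

#' Permutation-importance Z scores of every feature
#'
#' Trains a random forest on the (typically shadow-extended) table, then
#' measures, per feature and per tree, the out-of-bag accuracy before
#' minus after reading that feature through a random row permutation.
#' MDA is the mean per-tree loss and Z = MDA / sd(per-tree losses), with
#' the convention Z = 0 when the sd is 0 (e.g. a feature no tree uses).
#'
#' @param X complete numeric matrix, samples x features (originals plus
#'   shadows).
#' @param y labels (factor or \linkS4class{LabelVector}); both classes
#'   must be present.
#' @param n_trees internal forest size (default 250).
#' @param bootstrap_fraction,replace,mtry,min_leaf forest settings as in
#'   \code{\link{trainForest}}.
#' @param seed RNG seed (forest bootstraps and importance permutations).
#' @return data.frame with columns \code{feature}, \code{mda}, \code{sd},
#'   \code{z}.
#' @export
importanceZScores <- function(X, y, n_trees = 250L,
                              bootstrap_fraction = 0.632, replace = FALSE,
                              mtry = NULL, min_leaf = 1L, seed = 1L) {
  X <- .feature_matrix_input(X)
  y <- .as_label_factor(y)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (any(table(y) < 2L))
    stop("need at least 2 samples of each class", call. = FALSE)
  if (is.null(mtry)) mtry <- as.integer(ceiling(sqrt(ncol(X))))
  imp <- cpp_boruta_importance(X, as.integer(y) - 1L, as.integer(n_trees),
                               as.integer(mtry), bootstrap_fraction,
                               isTRUE(replace), as.integer(min_leaf),
                               deriveSeed(seed, "importance_forest"),
                               deriveSeed(seed, "importance_perm"))
  data.frame(feature = colnames(X), mda = imp$mda, sd = imp$sd, z = imp$z,
             stringsAsFactors = FALSE)
}

#' Boruta all-relevant feature selection
#'
#' Iterates: rebuild shadow features, compute permutation-importance Z
#' scores, find the maximum Z among the shadows (MZSA), and record a
#' "hit" for every real feature whose Z exceeds the MZSA. A two-sided
#' binomial test (success probability 1/2) on each still-undecided
#' feature's cumulative hit count confirms features with significantly
#' many hits and rejects those with significantly few. Rejected features
#' leave the dataset permanently; shadows are rebuilt every iteration as
#' fresh permutations of the \emph{full} input feature set, so the MZSA
#' bar stays calibrated to the original dimensionality even after most
#' features are rejected (a shrinking shadow pool would let surviving
#' chance correlates clear an ever-lower bar). The loop stops when no
#' feature is left tentative or after \code{max_iter} iterations; it also
#' stops early, with an identical final partition, as soon as no
#' tentative feature could reach either decision boundary by
#' \code{max_iter} even under an all-hit or all-miss future.
#'
#' Following the original Boruta algorithm, the decision test is
#' Bonferroni-adjusted for the number of features under selection
#' (\code{mc_adjust = TRUE}, the default), since every feature is tested
#' at every iteration.
#'
#' @param X complete numeric matrix, samples x features (at least 2).
#' @param y labels (factor or \linkS4class{LabelVector}).
#' @param max_iter iteration cap (default 200).
#' @param alpha level of the binomial decision test (default 0.01).
#' @param mc_adjust divide \code{alpha} by the number of features
#'   (Bonferroni) before comparing.
#' @param shadow_pool \code{"full"} (default): shadows are rebuilt from
#'   every input feature each iteration, keeping the MZSA bar calibrated
#'   to the original dimensionality; \code{"active"}: shadows copy only
#'   the not-yet-rejected features (the shrinking pool of the original
#'   Boruta implementation, more sensitive but able to promote surviving
#'   chance correlates once the bar drops).
#' @param n_trees internal forest size per iteration (default 250).
#' @param bootstrap_fraction,replace,mtry,min_leaf forest settings.
#' @param seed master seed; shadows, forests and permutations draw
#'   per-iteration seeds derived from it.
#' @return a \linkS4class{BorutaResult}.
#' @export
borutaRun <- function(X, y, max_iter = 200L, alpha = 0.01, n_trees = 250L,
                      bootstrap_fraction = 0.632, replace = FALSE,
                      mtry = NULL, min_leaf = 1L, mc_adjust = TRUE,
                      shadow_pool = c("full", "active"), seed = 1L) {
  shadow_pool <- match.arg(shadow_pool)
  X <- .feature_matrix_input(X)
  y <- .as_label_factor(y)
  if (ncol(X) < 2L) stop("need at least 2 features", call. = FALSE)
  stopifnot(max_iter >= 1L, alpha > 0, alpha < 1)
  level <- if (isTRUE(mc_adjust)) alpha / ncol(X) else alpha

  ids <- colnames(X)
  status <- setNames(rep("tentative", length(ids)), ids)
  hits <- setNames(rep(0L, length(ids)), ids)
  history <- vector("list", max_iter)
  iter <- 0L

  while (iter < max_iter && any(status == "tentative")) {
    iter <- iter + 1L
    active <- ids[status != "rejected"]
    src <- if (shadow_pool == "full") X else X[, active, drop = FALSE]
    sh <- makeShadow(src, seed = deriveSeed(seed, paste0("shadow_", iter)))
    ext <- cbind(X[, active, drop = FALSE],
                 sh[, setdiff(colnames(sh), ids), drop = FALSE])
    imp <- importanceZScores(ext, y, n_trees = n_trees,
                             bootstrap_fraction = bootstrap_fraction,
                             replace = replace, mtry = mtry,
                             min_leaf = min_leaf,
                             seed = deriveSeed(seed, paste0("imp_", iter)))
    is_shadow <- startsWith(imp$feature, "shadow__")
    mzsa <- max(imp$z[is_shadow])
    z_real <- setNames(imp$z[!is_shadow], imp$feature[!is_shadow])
    hit <- z_real > mzsa
    hits[active] <- hits[active] + as.integer(hit[active])

    for (f in active[status[active] == "tentative"]) {
      p_hi <- pbinom(hits[[f]] - 1L, iter, 0.5, lower.tail = FALSE)
      p_lo <- pbinom(hits[[f]], iter, 0.5)
      p_two <- min(1, 2 * min(p_hi, p_lo))
      if (p_two < level)
        status[[f]] <- if (hits[[f]] > iter / 2) "confirmed" else "rejected"
    }
    history[[iter]] <- data.frame(
      iteration = iter, feature = active, z = unname(z_real[active]),
      mzsa = mzsa, hit = unname(hit[active]),
      cumulative_hits = unname(hits[active]),
      decision = unname(status[active]), stringsAsFactors = FALSE)

    # outcome-equivalent early stop: if no tentative feature can reach
    # either decision boundary by max_iter even under an all-hit or
    # all-miss future, every remaining status is already final
    tent <- ids[status == "tentative"]
    if (length(tent) && iter < max_iter) {
      reachable <- vapply(tent, function(f) {
        h <- hits[[f]]
        conf <- 2 * pbinom(h + (max_iter - iter) - 1L, max_iter, 0.5,
                           lower.tail = FALSE) < level
        rej <- 2 * pbinom(h, max_iter, 0.5) < level
        conf || rej
      }, logical(1L))
      if (!any(reachable)) break
    }
  }

  n_conf <- sum(status == "confirmed")
  if (n_conf == 0L)
    abrfLog("Boruta confirmed no features after %d iterations", iter)
  new("BorutaResult",
      confirmed = ids[status == "confirmed"],
      rejected = ids[status == "rejected"],
      tentative = ids[status == "tentative"],
      history = do.call(rbind, history[seq_len(iter)]),
      iterations_run = iter)
}
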