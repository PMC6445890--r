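#' @include AllClasses.R
NULL

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Train a single-hidden-layer tanh autoencoder
#'
#' Fits x -> tanh(x W + b_h) -> linear reconstruction by full-batch
#' gradient descent on the mean squared reconstruction error. Inputs are
#' standardised per feature internally (tanh saturates on raw scales);
#' the stored center/scale make the model self-contained. Training stops
#' at \code{epochs} or earlier when the loss plateaus (relative
#' improvement below 1e-6 over 20 epochs).
#'
#' @param x a complete \linkS4class{FeatureMatrix} of kind
#'   \code{expression} or \code{cna}.
#' @param hidden_size number of hidden units; default
#'   \code{min(128, ceiling(G / 4))}.
#' @param epochs gradient-descent epochs (0 returns the initial weights).
#' @param learning_rate step size.
#' @param seed RNG seed for weight initialisation.
#' @return an \linkS4class{AutoencoderModel}.
#' @export
trainAutoencoder <- function(x, hidden_size = NA, epochs = 500L,
                             learning_rate = 0.05, seed = 1L) {
  stopifnot(is(x, "FeatureMatrix"))
  if (!featureKind(x) %in% c("expression", "cna"))
    stop("autoencoder screening applies to expression or cna features only",
         call. = FALSE)
  v <- featureValues(x)
  if (anyNA(v)) stop("matrix must be complete (impute first)", call. = FALSE)
  G <- ncol(v)
  n <- nrow(v)
  K <- if (is.na(hidden_size)) min(128L, as.integer(ceiling(G / 4)))
       else as.integer(hidden_size)
  stopifnot(K >= 1L, epochs >= 0L, learning_rate > 0)

  ctr <- colMeans(v)
  scl <- apply(v, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(v, 2L, ctr), 2L, scl, "/")

  .with_seed(seed, {
    W <- matrix(runif(G * K, -1, 1) / sqrt(G), G, K)
    V <- matrix(runif(K * G, -1, 1) / sqrt(K), K, G)
  })
  b_h <- numeric(K)
  b_o <- numeric(G)

  loss_of <- function() {
    H <- tanh(sweep(xs %*% W, 2L, b_h, "+"))
    O <- sweep(H %*% V, 2L, b_o, "+")
    mean((O - xs)^2)
  }
  initial_loss <- loss_of()
  loss <- initial_loss
  trail <- rep(NA_real_, 20L)
  epochs_run <- 0L

  for (e in seq_len(epochs)) {
    H <- tanh(sweep(xs %*% W, 2L, b_h, "+"))
    O <- sweep(H %*% V, 2L, b_o, "+")
    E <- O - xs
    loss <- mean(E * E)
    if (!is.finite(loss))
      stop("autoencoder training diverged at epoch ", e,
           " (loss non-finite); lower the learning rate", call. = FALSE)
    dO <- (2 / (n * G)) * E
    dV <- crossprod(H, dO)
    db_o <- colSums(dO)
    dZ <- (dO %*% t(V)) * (1 - H * H)
    dW <- crossprod(xs, dZ)
    db_h <- colSums(dZ)
    W <- W - learning_rate * dW
    V <- V - learning_rate * dV
    b_h <- b_h - learning_rate * db_h
    b_o <- b_o - learning_rate * db_o
    epochs_run <- e
    prev <- trail[((e - 1L) %% 20L) + 1L]
    trail[((e - 1L) %% 20L) + 1L] <- loss
    if (e > 20L && is.finite(prev) &&
        (prev - loss) / max(prev, .Machine$double.eps) < 1e-6) break
  }
  final_loss <- loss_of()
  if (!is.finite(final_loss))
    stop("autoencoder training diverged (final loss non-finite)",
         call. = FALSE)
  new("AutoencoderModel", W = W, V = V, b_h = b_h, b_o = b_o,
      center = ctr, scale = scl, epochs_run = epochs_run,
      initial_loss = initial_loss, final_loss = final_loss,
      seed = as.integer(seed))
}

#' Gedeon proportional contributions of autoencoder inputs
#'
#' Ranks inputs by how much absolute weight mass they push through the
#' hidden layer: P_ik = |W_ik| / sum_i |W_ik| (input to hidden),
#' P_kj = |V_kj| / sum_k |V_kj| (hidden to output),
#' Q_ij = sum_k P_ik P_kj (input to output), and the total contribution
#' q_i = sum_j Q_ij / sum_i Q_ij. Biases are excluded. Because each Q
#' column sums to 1 by construction, q sums to the number of inputs.
#'
#' @param model an \linkS4class{AutoencoderModel}.
#' @param feature_ids optional input names; defaults to rownames of the
#'   encoder weights or \code{f1..fG}.
#' @return a \linkS4class{ContributionScores}.
#' @export
gedeonContributions <- function(model, feature_ids = NULL) {
  stopifnot(is(model, "AutoencoderModel"))
  W <- abs(model@W)
  V <- abs(model@V)
  G <- nrow(W)
  if (is.null(feature_ids))
    feature_ids <- if (!is.null(rownames(model@W))) rownames(model@W)
                   else paste0("f", seq_len(G))
  hid_norm <- colSums(W)
  if (any(hid_norm == 0))
    stop("degenerate network: a hidden unit receives all-zero weights",
         call. = FALSE)
  out_norm <- colSums(V)
  if (any(out_norm == 0))
    stop("degenerate network: an output receives all-zero weights",
         call. = FALSE)
  P <- sweep(W, 2L, hid_norm, "/")          # G x K, columns sum to 1
  P_dec <- sweep(V, 2L, out_norm, "/")      # K x G, columns sum to 1
  Q <- P %*% P_dec                          # G x G
  q <- rowSums(sweep(Q, 2L, colSums(Q), "/"))
  new("ContributionScores", feature_ids = feature_ids, P = P, Q = Q, q = q)
}

#' Screen features by contribution rank and correlation pruning
#'
#' Two passes: (1) rank features by total contribution q descending and
#' drop the bottom \code{floor((1 - keep_fraction) * G)}; (2) walk the
#' survivors in ascending-q order and prune each feature whose absolute
#' Pearson correlation with the retained survivors exceeds
#' \code{corr_threshold} strictly (\code{corr_method = "pairwise"},
#' default: the maximum pairwise correlation; \code{"mean"}: the mean
#' correlation over all other retained survivors). Lower-contribution
#' members of correlated groups are therefore removed first. Data values
#' are returned unchanged, in the original column order.
#'
#' @param x a complete \linkS4class{FeatureMatrix}.
#' @param scores \linkS4class{ContributionScores} aligned with the columns
#'   of \code{x}.
#' @param keep_fraction fraction of features kept by the ranking cut.
#' @param corr_threshold strict pruning threshold on |r|.
#' @param corr_method \code{"pairwise"} or \code{"mean"}.
#' @return a column-subset \linkS4class{FeatureMatrix}.
#' @export
screenFeatures <- function(x, scores, keep_fraction = 0.5,
                           corr_threshold = 0.95,
                           corr_method = c("pairwise", "mean")) {
  corr_method <- match.arg(corr_method)
  stopifnot(is(x, "FeatureMatrix"), is(scores, "ContributionScores"),
            keep_fraction > 0, keep_fraction <= 1)
  if (!identical(featureIds(x), scores@feature_ids))
    stop("scores are not aligned with the matrix columns", call. = FALSE)
  v <- featureValues(x)
  if (anyNA(v)) stop("matrix must be complete", call. = FALSE)
  G <- ncol(v)
  q <- scores@q

  n_drop <- floor((1 - keep_fraction) * G)
  surv <- sort(order(q, decreasing = TRUE)[seq_len(G - n_drop)])
  if (length(surv) < 2L)
    stop("fewer than 2 features survive the contribution cut", call. = FALSE)

  cm <- suppressWarnings(abs(cor(v[, surv, drop = FALSE])))
  cm[!is.finite(cm)] <- 0  # constant columns correlate with nothing
  diag(cm) <- 0
  retained <- rep(TRUE, length(surv))
  for (i in order(q[surv])) {           # ascending contribution
    others <- retained
    others[i] <- FALSE
    if (!any(others)) next
    r <- cm[i, others]
    stat <- if (corr_method == "pairwise") max(r) else mean(r)
    if (stat > corr_threshold) retained[i] <- FALSE
  }
  kept <- surv[retained]
  if (length(kept) < 2L)
    stop("fewer than 2 features survive the correlation pruning",
         call. = FALSE)
  x[, kept]
}
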