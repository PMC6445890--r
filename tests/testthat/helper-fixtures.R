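# Small in-code fixtures shared across test files.

label_levels <- c("non_sensitive", "sensitive")

make_fm <- function(values, kind = "expression", cells = NULL, feats = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- if (is.null(cells)) sprintf("c%d", seq_len(nrow(values))) else cells
  if (is.null(colnames(values)))
    colnames(values) <- if (is.null(feats)) sprintf("g%d", seq_len(ncol(values))) else feats
  FeatureMatrix(values, kind)
}

make_labels <- function(x) factor(x, levels = label_levels)

# hand-buildable tree table: a stump splitting feature `var0` at `val`
stump <- function(var0, val, pred_left, pred_right) {
  list(var = c(as.integer(var0), -1L, -1L), val = c(val, 0, 0),
       left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
       pred = c(0L, as.integer(pred_left), as.integer(pred_right)),
       n0 = c(0L, 0L, 0L), n1 = c(0L, 0L, 0L))
}

hand_forest <- function(stumps, feature_ids, n_samples) {
  new("ForestModel", trees = stumps,
      oob = rep(list(integer()), length(stumps)),
      feature_ids = feature_ids, n_trees = length(stumps),
      bootstrap_size = as.integer(ceiling(0.632 * n_samples)), seed = 0L)
}

# independent Gedeon oracle: explicit triple loop over the printed formulas
gedeon_oracle <- function(W, V) {
  G <- nrow(W); K <- ncol(W)
  P_enc <- matrix(0, G, K)
  for (k in seq_len(K)) {
    denom <- sum(abs(W[, k]))
    for (i in seq_len(G)) P_enc[i, k] <- abs(W[i, k]) / denom
  }
  P_dec <- matrix(0, K, G)
  for (j in seq_len(G)) {
    denom <- sum(abs(V[, j]))
    for (k in seq_len(K)) P_dec[k, j] <- abs(V[k, j]) / denom
  }
  Q <- matrix(0, G, G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    acc <- 0
    for (k in seq_len(K)) acc <- acc + P_enc[i, k] * P_dec[k, j]
    Q[i, j] <- acc
  }
  q <- numeric(G)
  for (i in seq_len(G)) {
    acc <- 0
    for (j in seq_len(G)) acc <- acc + Q[i, j] / sum(Q[, j])
    q[i] <- acc
  }
  list(P = P_enc, Q = Q, q = q)
}

# independent per-entry KNN imputation oracle
impute_oracle <- function(features, response, K = 10, weight_mode = "inverse_distance") {
  expr <- featureValues(features$expression)
  cells <- rownames(expr)
  dist2 <- function(a, b) sum((expr[a, ] - expr[b, ])^2)
  fill_one <- function(col, i, binary) {
    cand <- cells[!is.na(col) & cells != cells[i]]
    d <- vapply(cand, function(k) dist2(cells[i], k), numeric(1))
    ord <- order(d)[seq_len(min(K, length(cand)))]
    vals <- col[match(cand[ord], cells)]
    dd <- unname(d[ord])
    if (binary) return(as.numeric(sum(vals == 1) > sum(vals == 0)))
    w <- if (all(dd == 0)) rep(1 / length(dd), length(dd))
         else if (weight_mode == "as_printed") dd / sum(dd)
         else { wi <- 1 / (dd + 1e-8); wi / sum(wi) }
    sum(w * vals)
  }
  out_feats <- lapply(features, function(fm) {
    v <- featureValues(fm)
    binary <- featureKind(fm) == "snv"
    for (j in seq_len(ncol(v))) for (i in seq_len(nrow(v)))
      if (is.na(v[i, j])) v[i, j] <- fill_one(featureValues(fm)[, j], i, binary)
    FeatureMatrix(v, featureKind(fm))
  })
  ic <- ic50Values(response)
  for (r in seq_len(nrow(ic))) for (i in seq_len(ncol(ic)))
    if (is.na(ic[r, i])) ic[r, i] <- fill_one(ic50Values(response)[r, ], i, FALSE)
  list(features = out_feats, response = ResponseTable(ic))
}

# brute-force AUC by pair counting (ties count 1/2)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "sensitive"]
  neg <- scores[labels == "non_sensitive"]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}
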