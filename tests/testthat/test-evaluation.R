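test_that("metric formulas match hand values and handle edge cases", {
  m <- computeMetrics(TP = 1, FP = 0, FN = 0, TN = 1)
  expect_equal(unname(m[c("ACC", "REC", "SPC", "F1", "MCC")]),
               c(1, 1, 1, 1, 1))
  m2 <- computeMetrics(TP = 25, FP = 25, FN = 25, TN = 25)
  expect_equal(m2[["ACC"]], 0.5)
  expect_equal(m2[["MCC"]], 0)
  m3 <- computeMetrics(TP = 40, FP = 10, FN = 20, TN = 30)
  expect_equal(m3[["ACC"]], 0.7)
  expect_equal(m3[["REC"]], 2 / 3)
  expect_equal(m3[["SPC"]], 0.75)
  expect_equal(m3[["F1"]], 80 / 110)
  expect_equal(m3[["MCC"]], 1000 / sqrt(50 * 60 * 40 * 50))
  expect_error(computeMetrics(-1, 0, 0, 2), "nonnegative")
})

test_that("zero-denominator metrics are zeroed and flagged", {
  m <- computeMetrics(TP = 0, FP = 0, FN = 0, TN = 10)
  expect_equal(m[["REC"]], 0)
  expect_equal(m[["F1"]], 0)
  expect_true(all(c("REC", "F1", "MCC") %in% attr(m, "flagged")))
})

test_that("metrics agree with direct formula evaluation on random counts", {
  set.seed(21)
  for (i in 1:300) {
    cnt <- as.numeric(sample(0:60, 4, replace = TRUE))
    if (sum(cnt) == 0) cnt[1] <- 1
    TP <- cnt[1]; FP <- cnt[2]; FN <- cnt[3]; TN <- cnt[4]
    m <- computeMetrics(TP, FP, FN, TN)
    expect_equal(m[["ACC"]], (TP + TN) / sum(cnt), tolerance = 1e-12)
    if (TP + FN > 0) expect_equal(m[["REC"]], TP / (TP + FN), tolerance = 1e-12)
    if (TN + FP > 0) expect_equal(m[["SPC"]], TN / (TN + FP), tolerance = 1e-12)
    if (2 * TP + FP + FN > 0)
      expect_equal(m[["F1"]], 2 * TP / (2 * TP + FP + FN), tolerance = 1e-12)
    den <- sqrt((TP + FP) * (TP + FN) * (FP + TN) * (FN + TN))
    if (den > 0)
      expect_equal(m[["MCC"]], (TP * TN - FP * FN) / den, tolerance = 1e-12)
  }
})

test_that("AUC handles separation, ties and inversions", {
  y <- make_labels(rep(c("non_sensitive", "sensitive"), each = 3))
  expect_equal(computeAUC(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9), y), 1)
  expect_equal(computeAUC(rep(0.5, 6), y), 0.5)
  s <- c(0.1, 0.9, 0.3, 0.7, 0.8, 0.2)  # inversions present
  expect_equal(computeAUC(s, y), auc_oracle(s, y))
  expect_error(computeAUC(1:3, make_labels(rep("sensitive", 3))), "AUC")
})

test_that("AUC equals brute-force pair counting and reverses correctly", {
  set.seed(22)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    y <- make_labels(sample(label_levels, n, replace = TRUE,
                            prob = c(0.5, 0.5)))
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(computeAUC(s, y), auc_oracle(s, y), tolerance = 1e-12)
    expect_equal(computeAUC(-s, y), 1 - computeAUC(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random score vectors", {
  skip_if_not_installed("pROC")
  set.seed(25)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    y <- make_labels(c("sensitive", "non_sensitive",
                       sample(label_levels, n - 2, replace = TRUE)))
    s <- round(runif(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = s, levels = label_levels,
      direction = "<", quiet = TRUE)))
    expect_equal(computeAUC(s, y), ref, tolerance = 1e-12)
  }
})

test_that("stratified folds partition the samples near-evenly", {
  y <- make_labels(rep(c("non_sensitive", "sensitive"), each = 50))
  fold <- abrf:::.stratified_folds(y, 10L, 99L)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(all(table(fold) == 10))
  for (k in 1:10) expect_equal(sum(y[fold == k] == "sensitive"), 5L)
})

test_that("cross-validation on an easy drug scores well out of fold", {
  set.seed(23)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(paste0("c", 1:n),
                                                  paste0("f", 1:6)))
  latent <- 2 * X[, 1] - 2 * X[, 2] + rnorm(n, sd = 0.3)
  y <- make_labels(ifelse(latent < median(latent), "sensitive",
                          "non_sensitive"))
  cfg <- pipelineConfig(cv_folds = 5L, rf_trees = 200L, boruta_trees = 150L,
                        boruta_max_iter = 40L, seed = 5L)
  rep <- crossValidate(X, y, cfg, drug = "toy")
  expect_s4_class(rep, "MetricsReport")
  expect_equal(nrow(foldMetrics(rep)), 5L)
  expect_gt(meanMetrics(rep)[["AUC"]], 0.8)
  # per-fold confusion counts sum to the dataset size
  expect_equal(sum(foldMetrics(rep)[, c("TP", "FP", "FN", "TN")]), n)
  # fold assignment is a partition
  expect_equal(sort(unique(foldMetrics(rep)$fold)), 1:5)
  expect_length(rep@fold_assignment, n)
})

test_that("wilcoxon and fisher feature tests match stats oracles", {
  set.seed(24)
  n <- 20
  lab <- make_labels(rep(c("sensitive", "non_sensitive"), each = 10))
  names(lab) <- paste0("c", 1:n)
  expr_v <- matrix(rnorm(n * 2), n, 2,
                   dimnames = list(names(lab), c("e1", "e2")))
  expr_v[, 1] <- expr_v[, 1] + ifelse(lab == "sensitive", 3, 0)
  snv_v <- matrix(c(rep(1, 10), rep(0, 10),
                    rbinom(n, 1, 0.5)), n, 2,
                  dimnames = list(names(lab), c("s1", "s2")))
  mats <- list(expression = FeatureMatrix(expr_v, "expression"),
               snv = FeatureMatrix(snv_v, "snv"))
  res <- biomarkerSignificance(c("e1", "e2", "s1"), lab, mats)
  # perfectly separated mutation: two-sided fisher p = 2 / choose(20, 10)
  expect_equal(res$p_value[res$feature == "s1"], 2 / choose(20, 10),
               tolerance = 1e-10)
  expect_lt(res$p_value[res$feature == "e1"], 1e-3)
  expect_gt(res$p_value[res$feature == "e2"], 0.05)
  expect_equal(res$p_value[res$feature == "e1"],
               wilcox.test(expr_v[lab == "sensitive", 1],
                           expr_v[lab == "non_sensitive", 1])$p.value)
})

test_that("constant features get p = 1 with a flag", {
  lab <- make_labels(rep(c("sensitive", "non_sensitive"), each = 5))
  names(lab) <- paste0("c", 1:10)
  v <- matrix(1, 10, 1, dimnames = list(names(lab), "flat"))
  res <- biomarkerSignificance("flat", lab,
                               list(cna = FeatureMatrix(v, "cna")))
  expect_equal(res$p_value, 1)
  expect_true(res$flagged)
})
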