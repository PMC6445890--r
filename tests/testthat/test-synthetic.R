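small_cfg <- function(...) {
  syntheticConfig(n_cells = 80L, n_expression = 30L, n_cna = 20L,
                  n_snv = 10L, n_informative = 3L, ...)
}

test_that("generation is deterministic per seed and structurally sound", {
  d1 <- generateDataset(small_cfg(seed = 4L))
  d2 <- generateDataset(small_cfg(seed = 4L))
  expect_identical(lapply(d1$features, featureValues),
                   lapply(d2$features, featureValues))
  expect_identical(ic50Values(d1$response), ic50Values(d2$response))
  expect_identical(d1$truth, d2$truth)
  d3 <- generateDataset(small_cfg(seed = 5L))
  expect_false(identical(ic50Values(d1$response), ic50Values(d3$response)))

  expect_equal(dim(d1$features$expression), c(80L, 30L))
  expect_false(anyNA(featureValues(d1$features$expression)))  # never missing
  expect_true(all(featureValues(d1$features$snv) %in% c(0, 1, NA)))
  expect_length(d1$truth$informative$expression, 3L)
})

test_that("missingness rates land within binomial tolerance", {
  cfg <- syntheticConfig(n_cells = 400L, n_expression = 50L, n_cna = 100L,
                         n_snv = 50L, n_informative = 2L,
                         missing_ic50 = 0.15, missing_cna = 0.08,
                         missing_snv = 0.05, seed = 6L)
  d <- generateDataset(cfg)
  p_cna <- mean(is.na(featureValues(d$features$cna)))
  p_snv <- mean(is.na(featureValues(d$features$snv)))
  p_ic <- mean(is.na(ic50Values(d$response)))
  expect_lt(abs(p_cna - 0.08), 3 * sqrt(0.08 * 0.92 / (400 * 100)))
  expect_lt(abs(p_snv - 0.05), 4 * sqrt(0.05 * 0.95 / (400 * 50)))
  expect_lt(abs(p_ic - 0.15), 4 * sqrt(0.15 * 0.85 / 400))
})

test_that("correlated blocks give the pruning rule work at r = 0.98", {
  d <- generateDataset(syntheticConfig(n_cells = 300L, n_expression = 9L,
                                       n_cna = 0L, n_snv = 0L,
                                       n_informative = 0L, block_size = 3L,
                                       block_cor = 0.98, seed = 7L))
  v <- featureValues(d$features$expression)
  within <- abs(cor(v[, 1], v[, 2]))
  across <- abs(cor(v[, 1], v[, 4]))
  expect_gt(within, 0.95)
  expect_lt(across, 0.3)
})

test_that("informative features out-correlate noise features with IC50", {
  cfg <- syntheticConfig(n_cells = 1000L, n_expression = 100L, n_cna = 100L,
                         n_snv = 50L, n_informative = 5L, block_size = 1L,
                         missing_ic50 = 0, missing_cna = 0, missing_snv = 0,
                         seed = 8L)
  d <- generateDataset(cfg)
  ic <- ic50Values(d$response)[1L, ]
  cors <- function(kind) {
    v <- featureValues(d$features[[kind]])
    info <- d$truth$informative[[kind]]
    list(info = abs(cor(v[, info], ic)),
         noise = abs(cor(v[, setdiff(colnames(v), info)], ic)))
  }
  for (kind in c("expression", "cna", "snv")) {
    cc <- cors(kind)
    expect_gt(mean(cc$info), mean(cc$noise))
    expect_gt(min(cc$info), stats::quantile(cc$noise, 0.95))
  }
})

test_that("a zero effect size yields labels independent of features", {
  d <- generateDataset(small_cfg(seed = 9L, effect_size = 0,
                                 missing_ic50 = 0))
  ic <- ic50Values(d$response)[1L, ]
  lab <- labelValues(assignLabels(ic, "drug1"))
  v <- featureValues(d$features$expression)
  # point-biserial correlations stay at noise level
  r <- abs(cor(v, as.integer(lab)))
  expect_lt(max(r), 4 / sqrt(nrow(v)))
})

test_that("the generator's own logistic refit separates the classes", {
  d <- generateDataset(syntheticConfig(seed = 1L))
  ic <- ic50Values(d$response)[1L, ]
  obs <- !is.na(ic)
  lab <- labelValues(assignLabels(ic[obs], "drug1"))
  info_cols <- do.call(cbind, lapply(names(d$features), function(k) {
    v <- featureValues(d$features[[k]])[obs, d$truth$informative[[k]],
                                        drop = FALSE]
    v
  }))
  info_cols[is.na(info_cols)] <- 0
  fit <- glm(lab ~ info_cols, family = binomial())
  expect_gt(computeAUC(predict(fit), lab), 0.9)
})

test_that("imbalance targeting sets a threshold achieving the target IR", {
  d <- generateDataset(small_cfg(seed = 10L, missing_ic50 = 0))
  imb <- makeImbalanced(d, 0.8)
  ic <- ic50Values(imb$response)[1L, ]
  lab <- assignLabels(ic, "drug1", threshold = imb$truth$threshold)
  ir <- imbalanceRatio(lab)
  expect_gt(ir, 3)
  expect_lt(ir, 5)
  imb2 <- makeImbalanced(d, 0.6)
  lab2 <- assignLabels(ic, "drug1", threshold = imb2$truth$threshold)
  expect_lt(imbalanceRatio(lab2), 2)  # bypass territory
  expect_error(makeImbalanced(d, 0.5), "0.5, 1")
  expect_error(makeImbalanced(d, 1), "0.5, 1")
})

test_that("degenerate configs are rejected", {
  expect_error(syntheticConfig(n_cells = 2), "n_cells")
  expect_error(syntheticConfig(n_expression = 10, n_cna = 0, n_snv = 0,
                               n_informative = 11), "n_informative")
  expect_error(syntheticConfig(missing_ic50 = 1), "missing_ic50")
  expect_error(syntheticConfig(noise_sd = 0), "noise_sd")
})

test_that("datasets write to the standard file set and read back", {
  d <- generateDataset(small_cfg(seed = 11L))
  dir <- withr::local_tempdir()
  paths <- writeDataset(d, dir)
  expect_true(file.exists(paths$truth))
  back <- readFeatureMatrix(paths$expression, "expression")
  expect_equal(featureValues(back), featureValues(d$features$expression),
               tolerance = 1e-12)
  rt <- readResponseTable(paths$response)
  expect_equal(ic50Values(rt), ic50Values(d$response), tolerance = 1e-12)
})
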