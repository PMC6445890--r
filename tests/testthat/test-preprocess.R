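test_that("missingness filters drop strictly-above-threshold columns then cells", {
  # 4-cell columns: g1 has 3/4 missing (dropped), g2 has 2/4 (kept, strict >)
  cna <- make_fm(rbind(c(NA, 1), c(NA, NA), c(NA, 1), c(1, NA)), "cna")
  expr <- make_fm(matrix(rnorm(8), 4, 2), "expression")
  ic <- matrix(rnorm(4), 1, 4, dimnames = list("d1", cellLines(expr)))
  out <- filterMissing(list(expression = expr, cna = cna), ResponseTable(ic))
  expect_identical(featureIds(out$features$cna), "g2")
  expect_identical(out$removed$features, "g1")
  expect_length(out$removed$cells, 0L)
})

test_that("filter survivors on a 6x6 pattern match hand enumeration", {
  # features: columns 1-6 with 4,3,2,1,0,6 missing of 6 (> 3 dropped: f1, f6)
  v <- matrix(0, 6, 6, dimnames = list(paste0("c", 1:6), paste0("f", 1:6)))
  v[1:4, 1] <- NA; v[1:3, 2] <- NA; v[1:2, 3] <- NA; v[1, 4] <- NA
  v[, 6] <- NA
  expr <- make_fm(matrix(rnorm(36), 6, 6), "expression",
                  cells = paste0("c", 1:6))
  ic <- matrix(rnorm(6), 1, 6, dimnames = list("d1", paste0("c", 1:6)))
  out <- filterMissing(list(expression = expr, cna = FeatureMatrix(v, "cna")),
                       ResponseTable(ic))
  # after dropping f1/f6, remaining cna missing per cell over 4 cols + 1 ic50
  # + 6 expression: c1 misses f2,f3,f4 = 3/11; nobody exceeds 50%
  expect_identical(featureIds(out$features$cna), paste0("f", 2:5))
  expect_identical(cellLines(out$features$cna), paste0("c", 1:6))

  # filtering is idempotent
  again <- filterMissing(out$features, out$response)
  expect_identical(featureValues(again$features$cna),
                   featureValues(out$features$cna))
})

test_that("cell filter counts response missingness jointly and can drop cells", {
  expr <- make_fm(matrix(rnorm(8), 4, 2), "expression")
  cells <- cellLines(expr)
  cna_v <- matrix(rnorm(8), 4, 2, dimnames = list(cells, c("a", "b")))
  cna_v[1, ] <- NA                      # cell c1 misses both cna features
  ic <- matrix(rnorm(8), 2, 4, dimnames = list(c("d1", "d2"), cells))
  ic[, 1] <- NA                         # and both drugs: 4/4 non-expression
  out <- filterMissing(list(expression = expr,
                            cna = FeatureMatrix(cna_v, "cna")),
                       ResponseTable(ic))
  expect_identical(out$removed$cells, "c1")
  expect_identical(cellLines(out$features$expression), cells[-1])
})

test_that("cell distance is squared euclidean on expression", {
  expr <- make_fm(rbind(c(0, 0), c(1, 2), c(0, 0)), "expression")
  expect_equal(cellDistance("c1", "c2", expr), 5)
  expect_equal(cellDistance("c1", "c3", expr), 0)
  expect_equal(cellDistance("c2", "c1", expr), cellDistance("c1", "c2", expr))
  set.seed(4)
  rexpr <- make_fm(matrix(rnorm(5 * 3), 5, 3), "expression")
  v <- featureValues(rexpr)
  for (a in 1:5) for (b in 1:5)
    expect_equal(cellDistance(rownames(v)[a], rownames(v)[b], rexpr),
                 sum((v[a, ] - v[b, ])^2))
})

test_that("neighbour search ranks by distance, truncates, breaks ties stably", {
  expr <- make_fm(matrix(c(0, 1, 2, 3, 1), 5, 1), "expression")
  nb <- findNeighbors("c1", paste0("c", 2:5), K = 2, expr)
  expect_setequal(nb$ids, c("c2", "c5"))        # both at distance 1
  expect_identical(nb$ids, c("c2", "c5"))       # tie kept in input order
  expect_equal(nb$distances, c(1, 1))

  expect_warning(nb3 <- findNeighbors("c1", c("c2", "c3"), K = 10, expr),
                 "candidate")
  expect_length(nb3$ids, 2L)
  expect_error(suppressWarnings(findNeighbors("c1", "c1", K = 1, expr)),
               "candidate")
})

test_that("real imputation matches the two weighting conventions", {
  expect_equal(imputeReal(c(10, 20), c(1, 3), "as_printed"), 17.5)
  expect_equal(imputeReal(c(10, 20), c(1, 3), "inverse_distance"), 12.5,
               tolerance = 1e-7)
  for (mode in c("as_printed", "inverse_distance")) {
    expect_equal(imputeReal(rep(5, 4), c(0, 1, 2, 3), mode), 5)
    expect_equal(imputeReal(c(2, 8), c(0, 0), mode), 5)  # zero distances
  }
  expect_error(imputeReal(numeric(), numeric()), "empty")
})

test_that("binary imputation is majority with ties to wild type", {
  expect_equal(imputeBinary(c(rep(1, 7), rep(0, 3))), 1)
  expect_equal(imputeBinary(c(rep(1, 5), rep(0, 5))), 0)
  expect_equal(imputeBinary(rep(0, 4)), 0)
  expect_error(imputeBinary(numeric()), "empty")
})

test_that("imputeAll equals the per-entry oracle on random fixtures", {
  for (s in 1:4) {
    set.seed(100 + s)
    n <- sample(8:20, 1)
    expr <- make_fm(matrix(rnorm(n * 6), n, 6), "expression")
    cells <- cellLines(expr)
    cna <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(cells, paste0("cn", 1:5)))
    cna[matrix(runif(length(cna)) < 0.2, n, 5)] <- NA
    snv <- matrix(rbinom(n * 4, 1, 0.3), n, 4,
                  dimnames = list(cells, paste0("sv", 1:4)))
    snv[matrix(runif(length(snv)) < 0.2, n, 4)] <- NA
    ic <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("d1", "d2"), cells))
    ic[matrix(runif(length(ic)) < 0.2, 2, n)] <- NA
    feats <- list(expression = expr, cna = FeatureMatrix(cna, "cna"),
                  snv = FeatureMatrix(snv, "snv"))
    rt <- ResponseTable(ic)
    for (mode in c("inverse_distance", "as_printed")) {
      got <- imputeAll(feats, rt, K = 4, weight_mode = mode)
      want <- impute_oracle(feats, rt, K = 4, weight_mode = mode)
      expect_equal(featureValues(got$features$cna),
                   featureValues(want$features$cna), tolerance = 1e-12)
      expect_identical(featureValues(got$features$snv),
                       featureValues(want$features$snv))
      expect_equal(ic50Values(got$response), ic50Values(want$response),
                   tolerance = 1e-12)
      # observed entries untouched; snv stays binary; masks cleared
      obs <- !is.na(cna)
      expect_identical(featureValues(got$features$cna)[obs], cna[obs])
      expect_true(all(featureValues(got$features$snv) %in% c(0, 1)))
      expect_false(anyNA(ic50Values(got$response)))
    }
  }
})

test_that("imputed reals are convex combinations of neighbour values", {
  set.seed(77)
  n <- 15
  expr <- make_fm(matrix(rnorm(n * 4), n, 4), "expression")
  cna <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(cellLines(expr), paste0("cn", 1:3)))
  miss <- matrix(runif(length(cna)) < 0.25, n, 3)
  cna[miss] <- NA
  got <- imputeAll(list(expression = expr, cna = FeatureMatrix(cna, "cna")),
                   ResponseTable(matrix(rnorm(n), 1, n,
                                        dimnames = list("d", cellLines(expr)))),
                   K = 5)
  gv <- featureValues(got$features$cna)
  for (j in 1:3) {
    rng <- range(cna[, j], na.rm = TRUE)
    expect_true(all(gv[miss[, j], j] >= rng[1] - 1e-12 &
                    gv[miss[, j], j] <= rng[2] + 1e-12))
  }
})

test_that("complete input passes through imputation unchanged", {
  set.seed(5)
  expr <- make_fm(matrix(rnorm(20), 5, 4), "expression")
  rt <- ResponseTable(matrix(rnorm(5), 1, 5,
                             dimnames = list("d", cellLines(expr))))
  out <- imputeAll(list(expression = expr), rt)
  expect_identical(featureValues(out$features$expression),
                   featureValues(expr))
  expect_identical(ic50Values(out$response), ic50Values(rt))
})
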