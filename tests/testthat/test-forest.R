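sep_data <- function(n = 40, seed = 1) {
  set.seed(seed)
  X <- cbind(a = c(rnorm(n / 2, -3), rnorm(n / 2, 3)), b = rnorm(n))
  rownames(X) <- paste0("c", seq_len(n))
  y <- make_labels(rep(c("non_sensitive", "sensitive"), each = n / 2))
  list(X = X, y = y)
}

test_that("every tree trains on ceiling(0.632 N) samples", {
  d <- sep_data(26)
  fm <- trainForest(d$X, d$y, n_trees = 20, seed = 2)
  expect_equal(fm@bootstrap_size, as.integer(ceiling(0.632 * 26)))
  # without replacement: OOB size is exactly N - bootstrap size
  for (o in fm@oob) expect_length(o, 26L - fm@bootstrap_size)
})

test_that("a deep forest separates noiseless separable data perfectly", {
  d <- sep_data(40)
  fm <- trainForest(d$X, d$y, n_trees = 100, seed = 5)
  p <- predictVote(fm, d$X)
  expect_equal(mean(p$label == d$y), 1)
  expect_true(all(p$score >= 0 & p$score <= 1))
})

test_that("null-label OOB accuracy sits near the class prior", {
  set.seed(6)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- make_labels(sample(rep(c("non_sensitive", "sensitive"), c(72, 48))))
  fm <- trainForest(X, y, n_trees = 300, seed = 7)
  votes <- abrf:::cpp_forest_predict_all(fm@trees, X)
  oob_correct <- oob_total <- 0
  for (t in seq_len(fm@n_trees)) {
    o <- fm@oob[[t]]
    oob_correct <- oob_correct + sum(votes[o, t] == (as.integer(y[o]) - 1L))
    oob_total <- oob_total + length(o)
  }
  expect_lt(abs(oob_correct / oob_total - 0.6), 0.15)
})

test_that("training is deterministic per seed and seed-sensitive", {
  d <- sep_data(30, seed = 3)
  f1 <- trainForest(d$X, d$y, n_trees = 25, seed = 11)
  f2 <- trainForest(d$X, d$y, n_trees = 25, seed = 11)
  f3 <- trainForest(d$X, d$y, n_trees = 25, seed = 12)
  expect_identical(f1@trees, f2@trees)
  expect_identical(f1@oob, f2@oob)
  expect_false(identical(f1@trees, f3@trees))
})

test_that("single-class input is refused", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(trainForest(X, make_labels(rep("sensitive", 10))),
               "each class")
})

test_that("hand-built stumps vote as counted by hand", {
  # three stumps on feature 0: thresholds 0, 1, -1; left=class0, right=class1
  trees <- list(stump(0, 0, 0, 1), stump(0, 1, 0, 1), stump(0, -1, 0, 1))
  fm <- hand_forest(trees, c("x1", "x2"), n_samples = 10)
  X <- cbind(x1 = c(-2, 0.5, 2), x2 = c(0, 0, 0))
  p <- predictVote(fm, X)
  # x1=-2: votes (0,0,0) -> 0/3; x1=0.5: (1,0,1) -> 2/3; x1=2: (1,1,1)
  expect_equal(p$score, c(0, 2 / 3, 1))
  expect_equal(as.character(p$label),
               c("non_sensitive", "sensitive", "sensitive"))
})

test_that("an exact vote tie resolves to non-sensitive", {
  # at x1 = 5 the first stump votes sensitive, the second wild-type
  trees <- list(stump(0, 0, 0, 1), stump(0, 10, 0, 1))
  fm <- hand_forest(trees, "x1", n_samples = 4)
  p <- predictVote(fm, matrix(5, 1, 1, dimnames = list(NULL, "x1")))
  expect_equal(p$score, 0.5)
  expect_equal(as.character(p$label), "non_sensitive")
})

test_that("prediction refuses mismatched feature columns", {
  d <- sep_data(20)
  fm <- trainForest(d$X, d$y, n_trees = 5, seed = 1)
  bad <- d$X
  colnames(bad) <- c("a", "zz")
  expect_error(predictVote(fm, bad), "schema|match")
})

test_that("easy-ensemble partitions 95/20 into subsets 24,24,24,23", {
  set.seed(8)
  n <- 115
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("c", 1:n), paste0("f", 1:4)))
  y <- make_labels(rep(c("non_sensitive", "sensitive"), c(95, 20)))
  m <- trainEasyEnsemble(X, y, n_trees = 30, seed = 9)
  expect_s4_class(m, "EasyEnsembleModel")
  expect_equal(m@ir, 4.75)
  expect_length(m@forests, 4L)
  sizes <- sort(lengths(m@partition), decreasing = TRUE)
  expect_equal(sizes, c(24L, 24L, 24L, 23L))
  # disjoint subsets whose union is the majority class
  ids <- unlist(m@partition)
  expect_false(anyDuplicated(ids) > 0)
  expect_setequal(ids, rownames(X)[y == "non_sensitive"])
  p <- predictVote(m, X)
  expect_true(all(p$score >= 0 & p$score <= 1))
})

test_that("balanced problems bypass the ensemble wrapper", {
  set.seed(10)
  n <- 100
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- make_labels(rep(c("non_sensitive", "sensitive"), c(60, 40)))  # IR 1.5
  m <- trainEasyEnsemble(X, y, n_trees = 20, seed = 3)
  expect_s4_class(m, "ForestModel")
})

test_that("ensemble score is the mean of sub-forest scores", {
  set.seed(11)
  n <- 90
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(paste0("c", 1:n), paste0("f", 1:3)))
  y <- make_labels(rep(c("non_sensitive", "sensitive"), c(70, 20)))
  m <- trainEasyEnsemble(X, y, n_trees = 40, seed = 13)
  p <- predictVote(m, X)
  per <- vapply(m@forests, function(f) predictVote(f, X)$score, numeric(n))
  expect_equal(p$score, rowMeans(per), tolerance = 1e-12)
})

test_that("forest models survive JSON serialization round-trips", {
  d <- sep_data(24, seed = 5)
  fm <- trainForest(d$X, d$y, n_trees = 8, seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  writeForestModel(fm, path)
  back <- readForestModel(path)
  expect_identical(back@trees, fm@trees)
  expect_identical(back@oob, fm@oob)
  expect_identical(predictVote(back, d$X), predictVote(fm, d$X))
})

test_that("forest accuracy is comparable to randomForest on the same task", {
  skip_if_not_installed("randomForest")
  set.seed(30)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  latent <- X[, 1] - X[, 2] + rnorm(n, sd = 0.8)
  y <- make_labels(ifelse(latent > 0, "sensitive", "non_sensitive"))
  test_idx <- 101:150
  fm <- trainForest(X[1:100, ], y[1:100], n_trees = 300, seed = 3)
  acc_ours <- mean(predictVote(fm, X[test_idx, ])$label == y[test_idx])
  rf <- randomForest::randomForest(X[1:100, ], y[1:100], ntree = 300)
  acc_rf <- mean(predict(rf, X[test_idx, ]) == y[test_idx])
  expect_gt(acc_ours, acc_rf - 0.1)
})
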