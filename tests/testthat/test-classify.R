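test_that("split_dataset gives exact, disjoint, stratified partitions", {
  data <- make_clouds(100)
  p <- split_dataset(data, seed = 4)
  sizes <- vapply(p$indices, length, integer(1))
  expect_equal(unname(sizes), c(20, 15, 65))
  all_idx <- sort(unname(unlist(p$indices)))
  expect_identical(all_idx, 1:100)            # exhaustive and disjoint
  # stratified: both labels present everywhere
  for (part in c("train", "validation", "test"))
    expect_setequal(as.character(unique(p[[part]]$labels)), c("LWL", "HWL"))
  # reproducible under the seed
  p2 <- split_dataset(data, seed = 4)
  expect_identical(p$indices, p2$indices)
  p3 <- split_dataset(data, seed = 5)
  expect_false(identical(p$indices, p3$indices))
  expect_error(split_dataset(make_clouds(2), seed = 1), "too few rows")
})

test_that("RBF SVM separates well-separated clouds", {
  data <- make_clouds(200, d = 8, sep = 5)
  p <- split_dataset(data, seed = 1)
  model <- train_svm_rbf(p$train)
  expect_gte(evaluate_classifier(model, p$test)$accuracy, 95)
  expect_gte(model$train_accuracy, 95)
})

test_that("contradictory duplicated points are not separable", {
  x <- rbind(matrix(rnorm(40), ncol = 2), c(0, 0), c(0, 0))
  lab <- c(rep(c("LWL", "HWL"), 10), "LWL", "HWL")
  model <- train_svm_rbf(labeled_features(x, lab))
  expect_lt(model$train_accuracy, 100)
  expect_error(train_svm_rbf(labeled_features(x, rep("LWL", 22))),
               "both")
})

test_that("predictions are invariant to consistent feature rescaling", {
  data <- make_clouds(120, d = 4, sep = 3, seed = 2)
  p <- split_dataset(data, seed = 2)
  scale_cols <- function(lf, k) labeled_features(
    sweep(lf$x, 2, k, "*"), lf$labels)
  k <- c(100, 0.01, 7, 1)
  m1 <- train_svm_rbf(p$train)
  m2 <- train_svm_rbf(scale_cols(p$train, k))
  expect_identical(as.character(predict(m1, p$test)),
                   as.character(predict(m2, scale_cols(p$test, k))))
})

test_that("backprop network learns linear and XOR structure", {
  data <- make_clouds(200, d = 8, sep = 5, seed = 3)
  p <- split_dataset(data, seed = 3)
  nn <- train_nn(p$train, p$validation, seed = 3)
  expect_gte(evaluate_classifier(nn, p$test)$accuracy, 95)

  set.seed(17)
  n <- 200
  cx <- sample(0:1, n, TRUE); cy <- sample(0:1, n, TRUE)
  x <- cbind(cx + rnorm(n, sd = 0.15), cy + rnorm(n, sd = 0.15))
  lab <- ifelse(xor(cx, cy), "HWL", "LWL")
  nn2 <- train_nn(labeled_features(x, lab), NULL,
                  config = nn_config_default(hidden = 8), seed = 5)
  expect_gte(nn2$train_accuracy, 95)
})

test_that("network training is deterministic under a fixed seed", {
  data <- make_clouds(80, d = 3, sep = 2, seed = 6)
  p <- split_dataset(data, seed = 6)
  a <- train_nn(p$train, p$validation, seed = 11)
  b <- train_nn(p$train, p$validation, seed = 11)
  expect_identical(a$w1, b$w1)
  expect_identical(a$w2, b$w2)
  c_ <- train_nn(p$train, p$validation, seed = 12)
  expect_false(identical(a$w1, c_$w1))
})

test_that("evaluation reports consistent accuracy and confusion counts", {
  data <- make_clouds(100, sep = 6, seed = 8)
  p <- split_dataset(data, seed = 8)
  model <- train_svm_rbf(p$train)
  res <- evaluate_classifier(model, p$test)
  expect_equal(sum(res$confusion), res$n)
  expect_equal(res$accuracy,
               100 * sum(diag(res$confusion)) / sum(res$confusion))
  # all-HWL test slice: accuracy equals HWL recall
  hwl_only <- subset_idx <- which(p$test$labels == "HWL")
  test_hwl <- labeled_features(p$test$x[subset_idx, , drop = FALSE],
                               p$test$labels[subset_idx])
  res2 <- evaluate_classifier(model, test_hwl)
  expect_equal(res2$accuracy,
               100 * res2$confusion["HWL", "HWL"] / sum(res2$confusion))
  wrong_dim <- labeled_features(matrix(rnorm(20), ncol = 2),
                                rep(c("LWL", "HWL"), 5))
  expect_error(evaluate_classifier(model, wrong_dim), "dimension")
})

test_that("swapping the label coding swaps the confusion quadrants", {
  data <- make_clouds(120, d = 4, sep = 4, seed = 9)
  p <- split_dataset(data, seed = 9)
  swap <- function(lf) labeled_features(
    lf$x, ifelse(lf$labels == "LWL", "HWL", "LWL"))
  m1 <- train_svm_rbf(p$train)
  m2 <- train_svm_rbf(swap(p$train))
  r1 <- evaluate_classifier(m1, p$test)
  r2 <- evaluate_classifier(m2, swap(p$test))
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$confusion["LWL", "LWL"], r2$confusion["HWL", "HWL"])
  expect_equal(r1$confusion["LWL", "HWL"], r2$confusion["HWL", "LWL"])
})

test_that("workload classification emits one row per cell and classifier", {
  # compact hand-built feature table with a real EI contrast
  set.seed(33)
  grid <- expand.grid(subject = sprintf("S%02d", 1:6),
                      group = "experimental", session = "pre",
                      condition = c("LWL", "HWL"),
                      channel = frontal_channels(),
                      epoch = 1:12, stringsAsFactors = FALSE)
  grid$ei <- rnorm(nrow(grid), 0.4, 0.08) +
    ifelse(grid$condition == "HWL", 0.25, 0)
  acc <- run_workload_classification(grid, seed = 2)
  expect_equal(nrow(acc), 2)                  # one cell x two classifiers
  expect_setequal(acc$classifier, c("svm", "nn"))
  expect_true(all(acc$accuracy >= 0 & acc$accuracy <= 100))
  expect_equal(acc$n_train + acc$n_validation + acc$n_test,
               rep(6 * 2 * 12, 2))
  expect_true(all(acc$accuracy > 75))         # clear built-in contrast
  acc2 <- run_workload_classification(grid, seed = 2)
  expect_identical(acc, acc2)                 # deterministic end to end
})
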