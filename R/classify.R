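#' Labeled feature set for workload classification
#'
#' @param x numeric feature matrix, one row per epoch (columns are typically
#'   the per-channel engagement indices).
#' @param labels factor or character with exactly the two levels
#'   "LWL" and "HWL".
#' @param tags optional data.frame of row metadata (group, session, ...).
#' @return list of class `labeled_features`.
#' @export
labeled_features <- function(x, labels, tags = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values")
  labels <- factor(as.character(labels), levels = c("LWL", "HWL"))
  if (any(is.na(labels))) stop("labels must be LWL or HWL")
  if (length(labels) != nrow(x)) stop("labels/feature row mismatch")
  structure(list(x = x, labels = labels, tags = tags),
            class = "labeled_features")
}

subset_lf <- function(data, idx) {
  labeled_features(data$x[idx, , drop = FALSE], data$labels[idx],
                   if (!is.null(data$tags)) data$tags[idx, , drop = FALSE])
}

#' Split a labeled feature set into train / validation / test partitions
#'
#' Label-stratified random partition with the study's 20/15/65 fractions by
#' default. Partitions are disjoint, exhaustive and reproducible under the
#' seed; overall partition sizes are exactly `round(fraction * n)` (largest
#' partition absorbs the rounding remainder), allocated across labels by
#' largest remainder.
#'
#' @param data a [labeled_features()].
#' @param fractions numeric length-3 (train, validation, test), summing to 1.
#' @param seed integer seed.
#' @return list with elements `train`, `validation`, `test` (each a
#'   `labeled_features`) and `indices` (the row indices of each partition).
#' @export
split_dataset <- function(data, fractions = c(train = 0.20,
                                              validation = 0.15,
                                              test = 0.65),
                          seed = 1L) {
  stopifnot(inherits(data, "labeled_features"))
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three numbers summing to 1")
  n <- nrow(data$x)
  targets <- c(round(fractions[1] * n), round(fractions[2] * n), 0)
  targets[3] <- n - targets[1] - targets[2]
  if (any(targets < 1))
    stop("too few rows (", n, ") for a nonempty three-way split; need at ",
         "least ", ceiling(1 / min(fractions)), " rows")
  set.seed(seed)
  assign <- integer(n)             # 1 train, 2 validation, 3 test
  remaining <- targets
  lab_levels <- levels(data$labels)
  for (lv in lab_levels) {
    idx <- sample(which(data$labels == lv))
    nl <- length(idx)
    if (nl == 0) next
    ideal <- fractions * nl
    take <- floor(ideal)
    rem <- ideal - take
    for (k in order(rem, decreasing = TRUE)) {
      if (sum(take) == nl) break
      take[k] <- take[k] + 1
    }
    take <- pmin(take, remaining)  # respect global targets
    while (sum(take) < nl) {       # give leftovers to partitions with room
      room <- which(remaining - take > 0)
      k <- room[which.max(remaining[room] - take[room])]
      take[k] <- take[k] + 1
    }
    assign[idx] <- rep(1:3, times = take)
    remaining <- remaining - take
  }
  parts <- lapply(1:3, function(k) which(assign == k))
  names(parts) <- c("train", "validation", "test")
  for (nm in names(parts))
    if (!length(parts[[nm]])) stop("partition '", nm, "' is empty")
  list(train = subset_lf(data, parts$train),
       validation = subset_lf(data, parts$validation),
       test = subset_lf(data, parts$test),
       indices = parts)
}

# z-score standardization fitted on training data, applied consistently
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(scaler, x)
  sweep(sweep(x, 2, scaler$mu), 2, scaler$sd, "/")

#' Train an RBF-kernel support vector machine
#'
#' Soft-margin SVM with the Gaussian radial basis kernel
#' `k(x, x') = exp(-gamma ||x - x'||^2)`, fitted with `e1071::svm`
#' (libsvm). Features are z-scored on training statistics; the scaler is
#' stored in the model and reapplied at prediction time.
#'
#' @param train a [labeled_features()] containing both classes.
#' @param cost soft-margin regularization C (default 1).
#' @param gamma kernel bandwidth; default `1 / (n_features * mean feature
#'   variance)` computed on the standardized training matrix (the libsvm
#'   "scale" heuristic).
#' @return list of class `svm_workload_model` with the fitted model, the
#'   scaler and the training accuracy (%).
#' @export
train_svm_rbf <- function(train, cost = 1, gamma = NULL) {
  stopifnot(inherits(train, "labeled_features"))
  if (nlevels(droplevels(train$labels)) < 2)
    stop("training set must contain both LWL and HWL epochs")
  scaler <- fit_scaler(train$x)
  xs <- apply_scaler(scaler, train$x)
  if (is.null(gamma)) {
    v <- mean(apply(xs, 2, stats::var))
    gamma <- 1 / (ncol(xs) * max(v, .Machine$double.eps))
  }
  fit <- e1071::svm(xs, train$labels, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  acc <- 100 * mean(stats::predict(fit, xs) == train$labels)
  structure(list(fit = fit, scaler = scaler, cost = cost, gamma = gamma,
                 train_accuracy = acc),
            class = "svm_workload_model")
}

#' @export
predict.svm_workload_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "labeled_features")) newdata$x else
    as.matrix(newdata)
  stats::predict(object$fit, apply_scaler(object$scaler, x))
}

#' Evaluate a classifier on a test partition
#'
#' @param model an `svm_workload_model` or `nn_workload_model`.
#' @param test a [labeled_features()] of matching feature dimension.
#' @return list of class `classification_result`: `accuracy` (%),
#'   `confusion` (2x2 table, truth in rows), `n`, `model` identifier.
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(test, "labeled_features"))
  dim_model <- length(model$scaler$mu)
  if (ncol(test$x) != dim_model)
    stop("feature dimension mismatch: model expects ", dim_model,
         ", test set has ", ncol(test$x))
  pred <- stats::predict(model, test)
  confusion <- table(truth = test$labels, predicted = pred)
  structure(
    list(accuracy = 100 * mean(pred == test$labels), confusion = confusion,
         n = nrow(test$x),
         model = if (inherits(model, "svm_workload_model")) "svm" else "nn"),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result: %s, accuracy %.1f%% on n = %d>\n",
              x$model, x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Run LWL-vs-HWL classification for every group x session cell
#'
#' Builds, per group x session, a feature matrix of per-channel engagement
#' indices (one row per epoch, one column per channel), splits it with
#' [split_dataset()] (20/15/65 by default), and trains and evaluates both
#' the RBF SVM and the backprop network.
#'
#' @param features an `eeg_feature_table` covering LWL and HWL epochs.
#' @param fractions split fractions, as in [split_dataset()].
#' @param seed master seed; per-cell seeds are derived deterministically.
#' @param svm_cost,svm_gamma passed to [train_svm_rbf()].
#' @param nn_config passed to [train_nn()] as `config`.
#' @return data.frame of class `workload_accuracy_table`: one row per
#'   (group, session, classifier) with test accuracy (%), per-class recall
#'   (%), and partition sizes.
#' @export
run_workload_classification <- function(features,
                                        fractions = c(0.20, 0.15, 0.65),
                                        seed = 1L, svm_cost = 1,
                                        svm_gamma = NULL,
                                        nn_config = nn_config_default()) {
  stopifnot(inherits(features, "data.frame"))
  task <- features[features$condition %in% c("LWL", "HWL"), ]
  if (!nrow(task)) stop("feature table has no LWL/HWL rows")
  out <- list()
  for (grp in unique(task$group)) for (ses in unique(task$session)) {
    cell <- task[task$group == grp & task$session == ses, ]
    if (!nrow(cell)) next
    wide <- stats::reshape(
      cell[, c("subject", "condition", "epoch", "channel", "ei")],
      idvar = c("subject", "condition", "epoch"),
      timevar = "channel", direction = "wide")
    feat_cols <- grep("^ei\\.", names(wide), value = TRUE)
    ok <- stats::complete.cases(wide[, feat_cols])
    wide <- wide[ok, ]
    if (length(unique(wide$condition)) < 2) next
    data <- labeled_features(as.matrix(wide[, feat_cols]), wide$condition,
                             tags = wide[, c("subject", "epoch")])
    cell_seed <- hash_seed(grp, ses, master = seed)
    parts <- split_dataset(data, fractions, seed = cell_seed)
    svm <- train_svm_rbf(parts$train, cost = svm_cost, gamma = svm_gamma)
    nn <- train_nn(parts$train, parts$validation, config = nn_config,
                   seed = cell_seed)
    for (model in list(svm, nn)) {
      res <- evaluate_classifier(model, parts$test)
      cm <- res$confusion
      out[[length(out) + 1]] <- data.frame(
        group = grp, session = ses, classifier = res$model,
        accuracy = res$accuracy,
        recall_lwl = 100 * cm["LWL", "LWL"] / sum(cm["LWL", ]),
        recall_hwl = 100 * cm["HWL", "HWL"] / sum(cm["HWL", ]),
        n_train = nrow(parts$train$x), n_validation = nrow(parts$validation$x),
        n_test = res$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("workload_accuracy_table", "data.frame")
  out
}
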