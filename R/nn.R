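#' Default backprop network configuration
#'
#' Single hidden layer of 10 logistic units, logistic output, mean
#' cross-entropy loss, full-batch gradient descent with classical momentum,
#' and validation-based early stopping.
#'
#' @param hidden hidden-layer size.
#' @param learning_rate gradient-descent step size on the mean-loss
#'   gradient.
#' @param momentum classical momentum coefficient.
#' @param max_epochs training epoch cap.
#' @param patience early stopping: epochs without validation-loss
#'   improvement before training halts.
#' @return named list.
#' @export
nn_config_default <- function(hidden = 10, learning_rate = 0.5,
                              momentum = 0.9, max_epochs = 500,
                              patience = 20) {
  list(hidden = hidden, learning_rate = learning_rate, momentum = momentum,
       max_epochs = max_epochs, patience = patience)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

nn_forward <- function(w, x) {
  h <- sigmoid(cbind(1, x) %*% w$w1)      # n x hidden
  p <- sigmoid(cbind(1, h) %*% w$w2)      # n x 1
  list(h = h, p = as.numeric(p))
}

nn_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Train a feed-forward network by error back-propagation
#'
#' One hidden layer of logistic units and a logistic output trained on the
#' binary cross-entropy by full-batch gradient descent with momentum
#' (weights move along the negative gradient; momentum accumulates it).
#' The validation partition drives early stopping: training halts after
#' `patience` epochs without improvement of the validation loss, and the
#' best-validation weights are kept. Features are z-scored on training
#' statistics, stored with the model. Deterministic under the seed.
#'
#' @param train a [labeled_features()] with both classes.
#' @param validation a [labeled_features()] used only for early stopping;
#'   NULL trains for `max_epochs` (a non-convergence flag is set if the
#'   gradient has not levelled off).
#' @param config a [nn_config_default()] list.
#' @param seed integer seed for weight initialization.
#' @return list of class `nn_workload_model`: weights `w1` (bias+inputs x
#'   hidden), `w2` (bias+hidden x 1), the scaler, `epochs_run`,
#'   `train_accuracy` (%), `converged`.
#' @export
train_nn <- function(train, validation = NULL, config = nn_config_default(),
                     seed = 1L) {
  stopifnot(inherits(train, "labeled_features"))
  if (nlevels(droplevels(train$labels)) < 2)
    stop("training set must contain both LWL and HWL epochs")
  scaler <- fit_scaler(train$x)
  x <- apply_scaler(scaler, train$x)
  y <- as.numeric(train$labels == "HWL")
  d <- ncol(x); nh <- config$hidden
  set.seed(seed)
  w <- list(w1 = matrix(stats::rnorm((d + 1) * nh, sd = 0.5), d + 1, nh),
            w2 = matrix(stats::rnorm(nh + 1, sd = 0.5), nh + 1, 1))
  v <- list(w1 = 0 * w$w1, w2 = 0 * w$w2)
  xv <- if (!is.null(validation)) apply_scaler(scaler, validation$x)
  yv <- if (!is.null(validation)) as.numeric(validation$labels == "HWL")
  best <- list(loss = Inf, w = w, epoch = 0L)
  stall <- 0L
  n <- nrow(x)
  epochs_run <- 0L
  grad_norm <- Inf
  for (epoch in seq_len(config$max_epochs)) {
    fwd <- nn_forward(w, x)
    delta_out <- (fwd$p - y) / n                       # d(mean CE)/d(z_out)
    g_w2 <- crossprod(cbind(1, fwd$h), delta_out)
    delta_h <- (delta_out %*% t(w$w2[-1, , drop = FALSE])) *
      fwd$h * (1 - fwd$h)
    g_w1 <- crossprod(cbind(1, x), delta_h)
    v$w1 <- config$momentum * v$w1 - config$learning_rate * g_w1
    v$w2 <- config$momentum * v$w2 - config$learning_rate * g_w2
    w$w1 <- w$w1 + v$w1
    w$w2 <- w$w2 + v$w2
    epochs_run <- epoch
    grad_norm <- sqrt(sum(g_w1^2) + sum(g_w2^2))
    if (!is.null(validation)) {
      vl <- nn_loss(nn_forward(w, xv)$p, yv)
      if (vl < best$loss - 1e-8) {
        best <- list(loss = vl, w = w, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  }
  if (!is.null(validation) && is.finite(best$loss)) w <- best$w
  converged <- if (!is.null(validation)) stall >= config$patience ||
    epochs_run < config$max_epochs else grad_norm < 1e-3
  p_tr <- nn_forward(w, x)$p
  structure(
    list(w1 = w$w1, w2 = w$w2, scaler = scaler, config = config,
         epochs_run = epochs_run,
         train_accuracy = 100 * mean((p_tr > 0.5) == (y == 1)),
         converged = converged, seed = as.integer(seed)),
    class = "nn_workload_model")
}

#' @export
predict.nn_workload_model <- function(object, newdata, type = "class", ...) {
  x <- if (inherits(newdata, "labeled_features")) newdata$x else
    as.matrix(newdata)
  p <- nn_forward(list(w1 = object$w1, w2 = object$w2),
                  apply_scaler(object$scaler, x))$p
  if (type == "prob") p
  else factor(ifelse(p > 0.5, "HWL", "LWL"), levels = c("LWL", "HWL"))
}
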