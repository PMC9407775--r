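#' CNN configuration
#'
#' The fixed backbone is six 3x3 same-padding convolutions with
#' (32, 32, 64, 64, 128, 128) filters, a 2x2 max pool after each pair, then
#' two ReLU dense layers (each followed by dropout) and a sigmoid (binary)
#' or softmax (multi-class) head. Dense-layer weights carry L1 and L2
#' penalties. Training uses Adam on cross-entropy.
#'
#' @param dense_sizes widths of the two dense layers.
#' @param l1_penalty,l2_penalty dense-layer weight penalties.
#' @param dropout_rate dropout after each dense layer, in \[0, 1).
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs (500 for full runs; tests use far fewer).
#' @param batch_size minibatch size.
#' @param seed integer seed for weight init, shuffling and dropout.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(dense_sizes = c(64L, 32L), l1_penalty = 1e-5,
                       l2_penalty = 1e-4, dropout_rate = 0.4,
                       learning_rate = 1e-4, epochs = 500L,
                       batch_size = 32L, seed = 1L) {
  stopifnot(length(dense_sizes) == 2L, all(dense_sizes >= 1L),
            dropout_rate >= 0, dropout_rate < 1, epochs >= 1L,
            batch_size >= 1L)
  structure(list(conv_filters = c(32L, 32L, 64L, 64L, 128L, 128L),
                 dense_sizes = as.integer(dense_sizes),
                 l1_penalty = l1_penalty, l2_penalty = l2_penalty,
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Build an untrained CNN
#'
#' @param config a [cnn_config()].
#' @param image_shape integer `c(height, width)`; both must be >= 8 so three
#'   2x2 poolings leave at least one spatial cell.
#' @param n_classes number of classes (>= 2); 2 gives a single sigmoid
#'   output unit, more gives a softmax over `n_classes` units.
#' @return A `cnn_model` (weights + architecture metadata).
#' @export
build_model <- function(config, image_shape, n_classes = 2L) {
  stopifnot(inherits(config, "cnn_config"), n_classes >= 2L)
  h <- as.integer(image_shape[1L]); w <- as.integer(image_shape[2L])
  if (h < 8L || w < 8L)
    stop("shape error: image must be at least 8 x 8 for three poolings",
         call. = FALSE)
  m <- .cnn_init(h, w, as.integer(n_classes), config$conv_filters,
                 config$dense_sizes[1L], config$dense_sizes[2L], config$seed)
  structure(list(weights = m, config = config, classes = NULL),
            class = "cnn_model")
}

#' Number of CNN parameters
#'
#' @param model a `cnn_model`.
#' @return Named numeric vector with `conv` (the six-convolution backbone),
#'   `dense` and `total` parameter counts.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  unlist(.cnn_n_params(model$weights))
}

#' Train a CNN on an image stack
#'
#' Minimizes binary or categorical cross-entropy with Adam; per-epoch
#' shuffling and dropout are driven by the config seed, so a rerun with the
#' same seed reproduces the loss history.
#'
#' Inputs are centered by subtracting the training-set mean image (stored
#' with the model and reused at prediction time), the standard CNN
#' preprocessing step: it removes the class-correlated brightness
#' common-mode so the decision threshold stays calibrated even on short
#' training schedules.
#'
#' @param model a `cnn_model` from [build_model()].
#' @param stack an image stack from [image_stack()] (fields `x`, `labels`).
#' @param config optional [cnn_config()] overriding the model's.
#' @return The trained `cnn_model`, with a `loss_history` field (length =
#'   epochs) and the class-level order used for encoding.
#' @export
train_model <- function(model, stack, config = model$config) {
  stopifnot(inherits(model, "cnn_model"))
  classes <- levels(stack$labels)
  if (length(classes) < 2L)
    stop("degenerate-label error: training set has a single class",
         call. = FALSE)
  y <- as.integer(stack$labels) - 1L
  center <- apply(stack$x, c(1L, 2L), mean)
  x <- sweep(stack$x, c(1L, 2L), center)
  res <- .cnn_train(model$weights, x, y, config$epochs,
                    config$batch_size, config$learning_rate,
                    config$l1_penalty, config$l2_penalty,
                    config$dropout_rate, config$seed)
  model$center <- center
  model$weights <- res$model
  model$loss_history <- as.numeric(res$loss_history)
  model$classes <- classes
  model$config <- config
  model
}

#' Predict class scores for an image stack
#'
#' @param model a trained `cnn_model`.
#' @param stack an image stack.
#' @return For binary models, a vector of positive-class (second class
#'   level) probabilities; otherwise an n x k matrix of softmax
#'   probabilities with class-named columns.
#' @export
predict_scores <- function(model, stack) {
  stopifnot(inherits(model, "cnn_model"))
  x <- if (is.null(model$center)) stack$x
       else sweep(stack$x, c(1L, 2L), model$center)
  s <- .cnn_predict(model$weights, x)
  if (ncol(s) == 1L) as.numeric(s) else {
    colnames(s) <- model$classes
    s
  }
}

#' Evaluate a trained CNN on a labeled image stack
#'
#' Accuracy uses the 0.5 threshold (binary) or arg-max (multi-class). For
#' binary tasks the ROC curve is traced over all score thresholds and the
#' AUC is the trapezoidal area under it. The confusion matrix is
#' row-normalized by true class; a class absent from the evaluation set
#' yields an all-NA row.
#'
#' @param model a trained `cnn_model`.
#' @param stack a labeled image stack.
#' @return An `eval_report`: `accuracy`, `auc` (binary, else NA),
#'   `roc_points` (data.frame fpr/tpr), `confusion` (row-normalized),
#'   `per_class_counts`.
#' @export
evaluate_model <- function(model, stack) {
  scores <- predict_scores(model, stack)
  truth <- factor(as.character(stack$labels), levels = model$classes)
  if (anyNA(truth))
    stop("evaluation labels outside the trained class set", call. = FALSE)
  if (is.matrix(scores)) {
    pred <- factor(model$classes[max.col(scores, ties.method = "first")],
                   levels = model$classes)
    auc <- NA_real_
    roc <- NULL
  } else {
    pred <- factor(model$classes[1L + (scores >= 0.5)],
                   levels = model$classes)
    roc <- roc_curve(scores, truth == model$classes[2L])
    auc <- auc_trapezoid(roc)
  }
  eval_report(pred, truth, auc = auc, roc = roc)
}

#' Assemble an evaluation report from predictions
#'
#' @param pred,truth factors over the same class levels.
#' @param auc optional AUC; `roc` optional ROC points data.frame.
#' @return An `eval_report` list.
#' @export
eval_report <- function(pred, truth, auc = NA_real_, roc = NULL) {
  stopifnot(identical(levels(pred), levels(truth)))
  cm <- table(truth = truth, pred = pred)
  counts <- rowSums(cm)
  conf <- sweep(unclass(cm), 1L, ifelse(counts > 0, counts, NA), "/")
  structure(list(accuracy = mean(pred == truth),
                 auc = auc,
                 roc_points = roc,
                 confusion = conf,
                 per_class_counts = counts),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: accuracy %.3f", x$accuracy))
  if (!is.na(x$auc)) cat(sprintf(", AUC %.3f", x$auc))
  cat("\nrow-normalized confusion matrix:\n")
  print(round(x$confusion, 3))
  invisible(x)
}

#' ROC curve of a score vector
#'
#' Sweeps the decision threshold over all distinct scores, from +Inf (no
#' positives called) down to -Inf, yielding points from (0, 0) to (1, 1)
#' that are non-decreasing in both coordinates.
#'
#' @param scores numeric scores, larger meaning "more positive".
#' @param positive logical vector of true positive-class membership.
#' @return A data.frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L)
    stop("ROC needs both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(positive[ord])
  fp <- cumsum(!positive[ord])
  # collapse ties: keep the last point of each distinct score
  keep <- c(diff(scores[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / nn), tpr = c(0, tp[keep] / np))
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc a data.frame from [roc_curve()].
#' @return The AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Save / load CNN model weights
#'
#' Weights are stored with `saveRDS` (the package's native checkpoint
#' format).
#'
#' @param model a `cnn_model`.
#' @param path checkpoint path.
#' @return `path` invisibly, or the restored `cnn_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cnn_model"))
  model
}
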