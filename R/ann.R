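# Single-hidden-layer feed-forward classifier trained by back-propagation.
#
# Architecture: input layer -> one logistic-sigmoid hidden layer -> softmax
# output layer; loss is the multinomial cross-entropy. Inputs are z-scored
# with constants estimated from the training portion only. Optimisation is
# plain mini-batch gradient descent with per-epoch reshuffling; the data
# are split 50/25/25 into training / validation / testing, the validation
# loss drives early stopping, and the returned weights are the snapshot
# from the best-validation epoch. Everything stochastic (split, weight
# initialisation, shuffling) is derived from one seed, so a fit is
# bit-reproducible.

#' Fit a feed-forward neural-network classifier
#'
#' @param x numeric matrix of features, one row per sample.
#' @param y class labels (factor or character), at least two classes.
#' @param hidden number of hidden units; default 10.
#' @param learning_rate gradient-descent step size; default 0.05.
#' @param max_epochs maximum training epochs; default 500.
#' @param patience early-stopping patience: training stops after this many
#'   epochs without a new best validation loss; default 25.
#' @param batch_size mini-batch size; default 32.
#' @param split fractions of the data assigned to training, validation and
#'   testing (stratified by class); must sum to 1. Default
#'   `c(0.50, 0.25, 0.25)`. With a zero validation fraction the training
#'   loss drives early stopping instead.
#' @param seed integer seed governing the split, the weight initialisation
#'   and the epoch shuffles.
#' @return object of class `"fdnn"`: weights (`w1`, `b1`, `w2`, `b2`),
#'   normalisation constants (`center`, `scale`), class `levels`, the
#'   per-epoch `history` (train/validation loss), the sample `assignment`
#'   (1 train / 2 validation / 3 test), held-out `test` metrics when a test
#'   portion exists, and the call configuration.
#' @seealso [predict.fdnn()], [cross_validate()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 3), 30))
#' y <- rep(c("a", "b"), each = 30)
#' fit <- fdnn(x, y, hidden = 4, max_epochs = 100, seed = 7)
#' mean(predict(fit, x) == y)
#' @export
fdnn <- function(x, y, hidden = 10, learning_rate = 0.05, max_epochs = 500,
                 patience = 25, batch_size = 32,
                 split = c(0.50, 0.25, 0.25), seed = 1) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) stopf("`x` contains non-finite values")
  y <- factor(y)
  if (nlevels(y) < 2) stopf("need at least two classes to fit a classifier")
  if (nrow(x) != length(y)) stopf("`x` and `y` lengths differ")
  if (nrow(x) < 20) stopf("need at least 20 samples")
  if (abs(sum(split) - 1) > 1e-8 || any(split < 0) || length(split) != 3)
    stopf("`split` must be three nonnegative fractions summing to 1")
  if (split[1] <= 0) stopf("training fraction must be positive")

  assignment <- stratified_assignment(y, split, derive_seed(seed, "split"))
  tr <- assignment == 1L
  if (!all(table(y[tr]) > 0)) stopf("a class is absent from the training split")

  center <- colMeans(x[tr, , drop = FALSE])
  scale_ <- apply(x[tr, , drop = FALSE], 2, sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  net <- init_network(c(ncol(x), hidden, nlevels(y)),
                      seed = derive_seed(seed, "init"))
  tmat <- diag(nlevels(y))[as.integer(y), , drop = FALSE]  # one-hot targets

  xt <- xs[tr, , drop = FALSE]; tt <- tmat[tr, , drop = FALSE]
  va <- assignment == 2L
  xv <- xs[va, , drop = FALSE]; tv <- tmat[va, , drop = FALSE]
  monitor_val <- nrow(xv) > 0

  best <- net; best_loss <- Inf; best_epoch <- 0L; stall <- 0L
  hist_tr <- hist_va <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    ord <- with_seed(derive_seed(seed, "epoch", epoch),
                     sample.int(nrow(xt)))
    for (start in seq(1L, nrow(xt), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, nrow(xt))]
      g <- nn_gradient(net, xt[idx, , drop = FALSE], tt[idx, , drop = FALSE])
      net$w1 <- net$w1 - learning_rate * g$w1
      net$b1 <- net$b1 - learning_rate * g$b1
      net$w2 <- net$w2 - learning_rate * g$w2
      net$b2 <- net$b2 - learning_rate * g$b2
    }
    ltr <- nn_loss(net, xt, tt)
    lva <- if (monitor_val) nn_loss(net, xv, tv) else ltr
    hist_tr <- c(hist_tr, ltr); hist_va <- c(hist_va, lva)
    if (lva < best_loss - 1e-12) {
      best <- net; best_loss <- lva; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  fit <- structure(list(
    w1 = best$w1, b1 = best$b1, w2 = best$w2, b2 = best$b2,
    center = center, scale = scale_, levels = levels(y),
    history = data.frame(epoch = seq_along(hist_tr),
                         train_loss = hist_tr, validation_loss = hist_va),
    best_epoch = best_epoch, assignment = assignment,
    config = list(hidden = hidden, learning_rate = learning_rate,
                  max_epochs = max_epochs, patience = patience,
                  batch_size = batch_size, split = split, seed = seed)),
    class = "fdnn")

  te <- assignment == 3L
  if (any(te)) {
    pred <- predict(fit, x[te, , drop = FALSE])
    cm <- confusion_matrix(pred, y[te], levels(y))
    fit$test <- list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
  }
  fit
}

#' Predict from a fitted network
#'
#' @param object an `"fdnn"` fit.
#' @param newdata numeric matrix (or vector for one sample) of raw,
#'   unstandardised features; the fit's stored normalisation is applied.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix, or
#'   `"prediction"` for a per-sample list carrying the label, the
#'   probability score (100 x the winning softmax activation, the
#'   percentage of the ideal score) and the raw output activations.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.fdnn <- function(object, newdata,
                         type = c("class", "prob", "prediction"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center))
    stopf("feature length %d does not match the %d inputs of the model",
          ncol(newdata), length(object$center))
  if (anyNA(newdata) || any(!is.finite(newdata)))
    stopf("`newdata` contains non-finite values")
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  p <- nn_forward(object, xs)
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  lab <- object$levels[max.col(p, ties.method = "first")]
  if (type == "class") return(lab)
  lapply(seq_len(nrow(p)), function(i) {
    structure(list(label = lab[i],
                   probability_score = 100 * max(p[i, ]),
                   raw_outputs = p[i, ]),
              class = "fdnn_prediction")
  })
}

#' @export
print.fdnn_prediction <- function(x, ...) {
  cat(sprintf("%s (probability score %.1f%%)\n", x$label,
              x$probability_score))
  invisible(x)
}

#' @export
print.fdnn <- function(x, ...) {
  cat(sprintf(
    "feed-forward network %d-%d-%d (sigmoid hidden, softmax output)\n",
    length(x$center), nrow(x$w1), length(x$levels)))
  cat(sprintf("classes: %s\n", paste(x$levels, collapse = ", ")))
  cat(sprintf("trained %d epochs, best validation epoch %d\n",
              nrow(x$history), x$best_epoch))
  if (!is.null(x$test))
    cat(sprintf("held-out test accuracy: %.3f (n = %d)\n",
                x$test$accuracy, sum(x$test$confusion)))
  invisible(x)
}

#' @export
summary.fdnn <- function(object, ...) {
  print(object)
  cat(sprintf("loss at best epoch: train %.4f, validation %.4f\n",
              object$history$train_loss[object$best_epoch],
              object$history$validation_loss[object$best_epoch]))
  if (!is.null(object$test)) {
    cat("held-out confusion matrix (rows = assigned, cols = true):\n")
    print(object$test$confusion)
  }
  invisible(object)
}

#' @export
coef.fdnn <- function(object, ...) {
  list(w1 = object$w1, b1 = object$b1, w2 = object$w2, b2 = object$b2)
}

#' Initialise a network
#'
#' Weights are drawn from a symmetric uniform distribution scaled by the
#' fan-in of each layer; biases start at zero. The same seed always gives
#' the same model.
#'
#' @param layer_sizes integer vector `(inputs, hidden, outputs)`, all >= 1.
#' @param seed integer seed.
#' @return list with weight matrices `w1` (hidden x inputs), `w2`
#'   (outputs x hidden) and bias vectors `b1`, `b2`.
#' @export
init_network <- function(layer_sizes, seed = 1) {
  if (length(layer_sizes) != 3 || any(layer_sizes < 1))
    stopf("`layer_sizes` must be three positive integers")
  n_in <- layer_sizes[1]; n_h <- layer_sizes[2]; n_out <- layer_sizes[3]
  with_seed(seed, {
    r1 <- 1 / sqrt(n_in); r2 <- 1 / sqrt(n_h)
    list(w1 = matrix(runif(n_h * n_in, -r1, r1), n_h, n_in),
         b1 = rep(0, n_h),
         w2 = matrix(runif(n_out * n_h, -r2, r2), n_out, n_h),
         b2 = rep(0, n_out))
  })
}

# ---- forward / backward passes (samples in rows) --------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)          # shift for numerical stability
  ez <- exp(z)
  ez / rowSums(ez)
}

# softmax output activations, one row per sample of (standardised) x
nn_forward <- function(net, x) {
  h <- sigmoid(x %*% t(net$w1) + rep(net$b1, each = nrow(x)))
  softmax_rows(h %*% t(net$w2) + rep(net$b2, each = nrow(x)))
}

# mean cross-entropy of one-hot targets tmat
nn_loss <- function(net, x, tmat) {
  p <- nn_forward(net, x)
  -mean(rowSums(tmat * log(pmax(p, 1e-300))))
}

# analytic gradient of nn_loss with respect to all weights and biases
nn_gradient <- function(net, x, tmat) {
  n <- nrow(x)
  h <- sigmoid(x %*% t(net$w1) + rep(net$b1, each = n))
  p <- softmax_rows(h %*% t(net$w2) + rep(net$b2, each = n))
  d2 <- (p - tmat) / n                       # n x n_out
  dh <- (d2 %*% net$w2) * h * (1 - h)        # n x n_hidden
  list(w1 = t(dh) %*% x, b1 = colSums(dh),
       w2 = t(d2) %*% h, b2 = colSums(d2))
}

# ---- data partitioning ----------------------------------------------------

# Stratified assignment of samples to portions with the given fractions.
# Returns an integer vector in 1..length(fractions); within each class the
# portion sizes match the fractions to within one sample.
stratified_assignment <- function(y, fractions, seed) {
  y <- factor(y)
  out <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      n <- length(idx)
      # largest-remainder apportionment of n samples to the fractions
      quota <- n * fractions
      sizes <- floor(quota)
      rem <- n - sum(sizes)
      if (rem > 0) {
        extra <- order(quota - sizes, decreasing = TRUE)[seq_len(rem)]
        sizes[extra] <- sizes[extra] + 1
      }
      out[idx] <- rep(seq_along(fractions), times = sizes)
    }
  })
  out
}

# Stratified k-fold labels in 1..k, balanced within class to +/- 1.
stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  out <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      out[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  out
}

#' Stratified k-fold cross-validation of the network
#'
#' Splits the data into `folds` class-stratified folds; each fold is
#' predicted once by a network trained on the remaining folds (which are
#' further split 75/25 internally so validation-based early stopping still
#' operates). Predictions are pooled into one confusion matrix, so every
#' sample contributes exactly one out-of-fold prediction.
#'
#' @param x,y features and labels as in [fdnn()].
#' @param folds number of folds, default 10.
#' @param seed seed for fold assignment and per-fold fits.
#' @param ... further arguments passed to [fdnn()] (e.g. `hidden`,
#'   `learning_rate`, `max_epochs`).
#' @return object of class `"fdnn_cv"`: `fold` assignment, per-fold
#'   accuracy, pooled `confusion` matrix (rows = assigned, cols = true)
#'   and pooled `accuracy`.
#' @export
cross_validate <- function(x, y, folds = 10, seed = 1, ...) {
  x <- as.matrix(x); y <- factor(y)
  if (nrow(x) < folds) stopf("fewer samples than folds")
  fold <- stratified_folds(y, folds, derive_seed(seed, "folds"))
  pred <- character(length(y))
  acc <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- fold != k
    fit <- fdnn(x[tr, , drop = FALSE], y[tr],
                split = c(0.75, 0.25, 0), seed = derive_seed(seed, "fold", k),
                ...)
    pred[!tr] <- predict(fit, x[!tr, , drop = FALSE])
    acc[k] <- mean(pred[!tr] == as.character(y[!tr]))
  }
  cm <- confusion_matrix(pred, y, levels(y))
  structure(list(fold = fold, fold_accuracy = acc, confusion = cm,
                 accuracy = sum(diag(cm)) / sum(cm)),
            class = "fdnn_cv")
}

#' @export
print.fdnn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: pooled accuracy %.3f\n",
              length(x$fold_accuracy), x$accuracy))
  print(x$confusion)
  invisible(x)
}

# ---- model serialisation --------------------------------------------------

#' Write a fitted network to JSON
#'
#' Stores layer sizes, row-major weight matrices, biases, normalisation
#' constants, class levels and the training configuration, so a model can
#' be reloaded and applied elsewhere.
#'
#' @param fit an `"fdnn"` object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_fdnn <- function(fit, path) {
  stopifnot(inherits(fit, "fdnn"))
  obj <- list(
    layer_sizes = c(length(fit$center), nrow(fit$w1), length(fit$levels)),
    w1 = as.vector(t(fit$w1)), b1 = fit$b1,
    w2 = as.vector(t(fit$w2)), b2 = fit$b2,
    center = fit$center, scale = fit$scale, levels = fit$levels,
    hidden_activation = "sigmoid", output_activation = "softmax",
    config = fit$config)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fitted network from JSON
#'
#' @param path file written by [write_fdnn()].
#' @return an `"fdnn"` object usable with [predict.fdnn()].
#' @export
read_fdnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls_ <- obj$layer_sizes
  structure(list(
    w1 = matrix(obj$w1, ls_[2], ls_[1], byrow = TRUE), b1 = obj$b1,
    w2 = matrix(obj$w2, ls_[3], ls_[2], byrow = TRUE), b2 = obj$b2,
    center = obj$center, scale = obj$scale, levels = obj$levels,
    history = NULL, best_epoch = NA_integer_, assignment = NULL,
    config = obj$config), class = "fdnn")
}
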