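#' Configuration of the fully connected classifier
#'
#' Architecture fixed to the study design: input layer (fingerprint
#' intensities), two hidden layers of 64 relu neurons with dropout,
#' softmax output over two classes, cross-entropy loss, adam optimizer.
#' Training stops when the epoch training criterion falls below
#' `error_threshold` (1%): interpreted as mean cross-entropy loss by
#' default (`threshold_mode = "loss"`), or as the training
#' misclassification rate (`threshold_mode = "error_rate"`).
#'
#' @param hidden_sizes hidden layer widths (default `c(64, 64)`).
#' @param dropout_rate dropout probability on hidden activations during
#'   training (default 0.2).
#' @param learning_rate adam step size (default 0.001).
#' @param batch_size mini-batch size (default 16).
#' @param max_epochs training epoch cap (default 500).
#' @param error_threshold stopping threshold (default 0.01).
#' @param threshold_mode `"loss"` or `"error_rate"`.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return list of class `ann_config`.
#' @export
ann_config <- function(hidden_sizes = c(64, 64), dropout_rate = 0.2,
                       learning_rate = 0.001, batch_size = 16,
                       max_epochs = 500, error_threshold = 0.01,
                       threshold_mode = c("loss", "error_rate"),
                       seed = 1L) {
  stopifnot(all(hidden_sizes >= 1), dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            error_threshold > 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 error_threshold = error_threshold,
                 threshold_mode = match.arg(threshold_mode),
                 seed = as.integer(seed)),
            class = "ann_config")
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train the fully connected classifier
#'
#' Mini-batch adam on cross-entropy; He-normal initialization;
#' deterministic given `config$seed` (single-threaded R RNG drives
#' initialization, shuffling and dropout masks).
#'
#' @param X samples-by-feature matrix of preprocessed spectra.
#' @param labels per-sample class labels (exactly two classes present).
#' @param config an [ann_config()].
#' @param positive label treated as the positive class (first output
#'   unit); default: first label in sorted order.
#' @return list of class `ann_model` with `weights`, `config`,
#'   `input_width`, `classes`, `training_history`.
#' @export
train_ann <- function(X, labels, config = ann_config(), positive = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("training set must contain exactly 2 classes")
  if (is.null(positive)) positive <- cls[1]
  classes <- c(positive, setdiff(cls, positive))
  y <- match(labels, classes)           # 1 = positive, 2 = negative
  n <- nrow(X); p <- ncol(X)
  set.seed(config$seed)
  sizes <- c(p, config$hidden_sizes, 2L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                  sqrt(2 / sizes[l])),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0
  L <- length(W)
  onehot <- matrix(0, n, 2); onehot[cbind(seq_len(n), y)] <- 1
  history <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      A <- list(X[idx, , drop = FALSE])
      masks <- list()
      for (l in seq_len(L)) {
        Z <- A[[l]] %*% W[[l]] + rep(b[[l]], each = length(idx))
        if (l < L) {
          H <- relu(Z)
          if (config$dropout_rate > 0) {
            msk <- matrix(stats::rbinom(length(H), 1, 1 - config$dropout_rate),
                          nrow = nrow(H)) / (1 - config$dropout_rate)
            H <- H * msk
            masks[[l]] <- msk
          }
          A[[l + 1]] <- H
        } else {
          A[[l + 1]] <- softmax_rows(Z)
        }
      }
      delta <- (A[[L + 1]] - onehot[idx, , drop = FALSE]) / length(idx)
      tstep <- tstep + 1
      for (l in rev(seq_len(L))) {
        gW <- t(A[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(W[[l]])
          if (config$dropout_rate > 0) delta <- delta * masks[[l - 1]]
          delta <- delta * (A[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^tstep; corr2 <- 1 - beta2^tstep
        W[[l]] <- W[[l]] - config$learning_rate * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - config$learning_rate * (mb[[l]] / corr1) /
          (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    # epoch-end training criterion on the full set, dropout off
    P <- forward_proba(X, W, b)
    loss <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
    if (!is.finite(loss))
      stop("non-finite training loss at epoch ", epoch)
    history <- c(history, loss)
    crit <- if (config$threshold_mode == "loss") loss
            else mean(max.col(P) != y)
    if (crit <= config$error_threshold) break
  }
  structure(list(weights = list(W = W, b = b), config = config,
                 input_width = p, classes = classes,
                 training_history = history),
            class = "ann_model")
}

forward_proba <- function(X, W, b) {
  A <- X
  L <- length(W)
  for (l in seq_len(L)) {
    Z <- A %*% W[[l]] + rep(b[[l]], each = nrow(A))
    A <- if (l < L) relu(Z) else softmax_rows(Z)
  }
  A
}

#' Class probabilities from a trained classifier
#'
#' Deterministic forward pass (no dropout); rows sum to 1.
#'
#' @param model an `ann_model`.
#' @param X samples-by-feature matrix; width must equal the training
#'   width.
#' @return matrix of probabilities with columns named by class
#'   (positive class first).
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_width)
    stop("input width ", ncol(X), " does not match model width ",
         model$input_width)
  P <- forward_proba(X, model$weights$W, model$weights$b)
  colnames(P) <- model$classes
  P
}

#' Predicted class labels at the 0.5 threshold
#' @inheritParams predict_proba
#' @return character vector of labels.
#' @export
predict_class <- function(model, X) {
  P <- predict_proba(model, X)
  model$classes[ifelse(P[, 1] >= 0.5, 1L, 2L)]
}
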