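#' CNN architecture configuration
#'
#' The network is: input batch-normalisation, then `k` blocks of
#' (batch normalisation, 2D convolution with `filters` kernels of size
#' `kernel` and `stride`, leaky rectifier), then a flatten and a single
#' sigmoid output unit giving Pr[AI]. There are no pooling layers; the
#' 2x2 stride halves both dimensions per block instead.
#'
#' @param m number of genomic bins of the input matrix.
#' @param k number of convolution blocks; must satisfy
#'   `k <= floor(log2(min(n, m)))` for the input shape `n` columns x `m`
#'   bins.
#' @param filters convolution filters per block.
#' @param kernel kernel size (h, w).
#' @param stride stride (h, w).
#' @param leaky_slope negative slope of the leaky rectifier.
#' @export
model_config <- function(m = 256, k = 7, filters = 16, kernel = c(4, 4),
                         stride = c(2, 2), leaky_slope = 0.2) {
  stopifnot(m >= 2, k >= 0, filters >= 1)
  structure(list(m = m, k = k, filters = filters, kernel = kernel,
                 stride = stride, leaky_slope = leaky_slope),
            class = "model_config")
}

#' Build an untrained classifier
#'
#' @param cfg a [model_config()].
#' @param input_shape integer (bins m, columns n) of the input matrices.
#' @return object of class `introscan_cnn` (untrained). Weight
#'   initialisation draws from R's RNG; seed with `set.seed` for
#'   reproducibility.
#' @export
build_model <- function(cfg, input_shape) {
  stopifnot(inherits(cfg, "model_config"), length(input_shape) == 2)
  H <- as.integer(input_shape[1]); W <- as.integer(input_shape[2])
  stopifnot(H == cfg$m)
  if (cfg$k > floor(log2(min(H, W)))) {
    stop("k = ", cfg$k, " too deep for input ", H, "x", W)
  }
  layers <- list(.layer_bn(1L))
  h <- H; w <- W; C <- 1L
  for (b in seq_len(cfg$k)) {
    if (b > 1) layers <- c(layers, list(.layer_bn(C)))
    cv <- .layer_conv(h, w, C, cfg$filters, cfg$kernel, cfg$stride)
    layers <- c(layers, list(cv, .layer_lrelu(cfg$leaky_slope)))
    h <- cv$plan$oh; w <- cv$plan$ow; C <- cfg$filters
  }
  layers <- c(layers, list(.layer_dense(h * w * C)))
  structure(list(cfg = cfg, input_shape = c(H, W), layers = layers,
                 trained = FALSE, history = NULL),
            class = "introscan_cnn")
}

#' @export
print.introscan_cnn <- function(x, ...) {
  cat(sprintf("<introscan_cnn> input %dx%d, k=%d blocks, %d filters, %s\n",
              x$input_shape[1], x$input_shape[2], x$cfg$k, x$cfg$filters,
              if (x$trained) "trained" else "untrained"))
  cat(" parameters:", n_parameters(x), "\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param net an `introscan_cnn`.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$layers, function(l) {
    switch(l$type,
           bn = 2 * l$C,
           conv = length(l$W) + length(l$b),
           dense = length(l$W) + 1,
           0) * 1.0
  }, 0))
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param split training fraction for [split_train_val()].
#' @export
training_config <- function(epochs = 3, batch_size = 64, lr = 1e-3,
                            split = 0.9) {
  stopifnot(epochs >= 1, batch_size >= 1, split > 0, split < 1)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 split = split), class = "training_config")
}

#' Stack encoded matrices into a training array
#'
#' @param mats list of [resized_matrix()] (identical shapes).
#' @return numeric array (bins m, columns n, batch).
#' @export
stack_matrices <- function(mats) {
  dims <- vapply(mats, function(x) dim(x$mat), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("matrices have mismatched shapes")
  }
  arr <- array(0, c(dims[1, 1], dims[2, 1], length(mats)))
  for (i in seq_along(mats)) arr[, , i] <- mats[[i]]$mat
  arr
}

#' Class-stratified train/validation split
#'
#' @param labels binary labels (or any class vector).
#' @param fraction training fraction.
#' @return list with integer index vectors `train` and `val` (disjoint,
#'   exhaustive). Reproducible under `set.seed`.
#' @export
split_train_val <- function(labels, fraction = 0.9) {
  stopifnot(fraction > 0, fraction < 1)
  idx <- seq_along(labels)
  train <- integer(0)
  for (cl in unique(labels)) {
    ii <- idx[labels == cl]
    n_tr <- round(fraction * length(ii))
    train <- c(train, sample(ii, n_tr))
  }
  train <- sort(train)
  list(train = train, val = sort(setdiff(idx, train)))
}

# flatten an (H, W, B) array into the (H*W) x B activation layout
.flatten_batch <- function(x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  matrix(x, nrow = dim(x)[1] * dim(x)[2])
}

#' Train the classifier
#'
#' Binary cross-entropy on the sigmoid output (AI = 1), Adam optimiser,
#' minibatch updates. Inputs are consumed as raw (8-bit) counts; all
#' normalisation is learned by the in-network batch-normalisation layers.
#'
#' @param net an untrained (or trained) `introscan_cnn`.
#' @param x array (m, n, B) of encoded matrices ([stack_matrices()]).
#' @param labels binary vector of length B.
#' @param cfg a [training_config()].
#' @param x_val,labels_val optional validation data evaluated after each
#'   epoch.
#' @param quiet suppress per-epoch messages.
#' @return the trained network, with `$history` (per-epoch loss/accuracy).
#' @export
train_classifier <- function(net, x, labels, cfg = training_config(),
                             x_val = NULL, labels_val = NULL, quiet = TRUE) {
  stopifnot(inherits(net, "introscan_cnn"))
  xb <- .flatten_batch(x)
  if (any(dim(x)[1:2] != net$input_shape)) stop("input shape mismatch")
  B <- ncol(xb)
  stopifnot(length(labels) == B, all(labels %in% c(0, 1)))
  state <- .adam_init(net)
  step <- 0
  hist <- NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(B)
    ep_loss <- 0; ep_n <- 0; ep_correct <- 0
    for (start in seq(1, B, by = cfg$batch_size)) {
      ii <- ord[start:min(start + cfg$batch_size - 1, B)]
      xm <- xb[, ii, drop = FALSE]
      y <- labels[ii]
      fw <- .net_forward(net, xm, train = TRUE)
      net <- fw$net
      p <- stats::plogis(fw$logits)
      # BCE-with-logits gradient: dL/dlogit = (p - y) / batch
      dlog <- (p - y) / length(y)
      bw <- .net_backward(net, fw$caches, dlog, train = TRUE)
      step <- step + 1
      ad <- .adam_step(net, bw$grads, state, step, lr = cfg$lr)
      net <- ad$net; state <- ad$state
      eps <- 1e-12
      ep_loss <- ep_loss - sum(y * log(p + eps) + (1 - y) * log(1 - p + eps))
      ep_correct <- ep_correct + sum((p > 0.5) == (y == 1))
      ep_n <- ep_n + length(y)
    }
    row <- data.frame(epoch = ep, loss = ep_loss / ep_n,
                      accuracy = ep_correct / ep_n,
                      val_loss = NA_real_, val_accuracy = NA_real_)
    if (!is.null(x_val)) {
      pv <- predict(net, x_val)
      eps <- 1e-12
      row$val_loss <- -mean(labels_val * log(pv + eps) +
                              (1 - labels_val) * log(1 - pv + eps))
      row$val_accuracy <- mean((pv > 0.5) == (labels_val == 1))
    }
    hist <- rbind(hist, row)
    if (!quiet) {
      message(sprintf("epoch %d: loss %.4f acc %.3f val_acc %.3f",
                      ep, row$loss, row$accuracy, row$val_accuracy))
    }
  }
  net$trained <- TRUE
  net$history <- hist
  net
}

#' Predict Pr[AI] for encoded matrices
#'
#' Deterministic given the fitted weights (batch normalisation uses running
#' statistics in inference mode, so batching does not affect predictions).
#'
#' @param object a trained `introscan_cnn`.
#' @param x array (m, n, B), a single matrix (m, n), or a
#'   [resized_matrix()].
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.introscan_cnn <- function(object, x, ...) {
  if (inherits(x, "resized_matrix")) x <- x$mat
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  if (any(dim(x)[1:2] != object$input_shape)) stop("input shape mismatch")
  xb <- .flatten_batch(x)
  # chunk to bound memory on large scans
  out <- numeric(ncol(xb))
  for (start in seq(1, ncol(xb), by = 512)) {
    ii <- start:min(start + 511, ncol(xb))
    fw <- .net_forward(object, xb[, ii, drop = FALSE], train = FALSE)
    out[ii] <- stats::plogis(fw$logits)
  }
  out
}

#' Save / load a trained classifier
#'
#' Weights and running statistics are serialised with R's native format.
#'
#' @param net an `introscan_cnn`.
#' @param path file path.
#' @export
save_classifier <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "introscan_cnn"))
  net
}
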