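#' @useDynLib omicsgsn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- array helpers -------------------------------------------------------

# (H, W, C, N) array -> (H*W*N) x C matrix grouping values by channel
chan_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3L])
}

unchan_mat <- function(m, d) {
  aperm(array(m, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
}

conv_out_dim <- function(h) h - 2L                      # 3x3 valid conv
pool_out_dim <- function(h, stride) (h - 2L) %/% stride + 1L  # 2x2 pool

#' Spatial output size of the three-block conv/pool stack
#'
#' Blocks 1-2: 3x3 valid convolution then 2x2 max-pool with stride 1;
#' block 3: 3x3 convolution then 2x2 max-pool with stride 2. Closed form
#' per axis: `floor((h - 10) / 2) + 1` for `h >= 10`.
#'
#' @param h,w Input height and width in pixels.
#' @return Integer vector `c(height, width)` after the conv/pool stack.
#' @export
cnn_output_shape <- function(h, w) {
  step <- function(x) {
    x <- conv_out_dim(x); if (x < 2L) abort_validation("input too small at conv/pool block 1.")
    x <- pool_out_dim(x, 1L)
    x <- conv_out_dim(x); if (x < 2L) abort_validation("input too small at conv/pool block 2.")
    x <- pool_out_dim(x, 1L)
    x <- conv_out_dim(x); if (x < 2L) abort_validation("input too small at conv/pool block 3.")
    pool_out_dim(x, 2L)
  }
  c(step(as.integer(h)), step(as.integer(w)))
}

# ---- model construction --------------------------------------------------

#' Build the three-block image-classification CNN
#'
#' Architecture: three convolutional blocks, each 32 filters of size 3x3
#' (valid padding) with ReLU, followed by 2x2 max pooling (stride 1x1 in
#' blocks 1-2, stride 2x2 in block 3), a batch-normalization layer, and
#' dropout (rates 0.20, 0.20, 0.50); then flatten and a dense softmax layer
#' over the classes. Weight initialization is seeded, so two models built
#' from the same seed have identical initial weights.
#'
#' @param input_shape Integer `c(H, W, 3)` image shape.
#' @param n_classes Number of output classes (>= 2).
#' @param filters Convolution filters per block (default 32).
#' @param dropout Length-3 dropout rates (default `c(0.2, 0.2, 0.5)`).
#' @param seed Integer seed for weight initialization.
#' @return A `gsn_cnn` model object.
#' @export
build_cnn <- function(input_shape, n_classes, filters = 32L,
                      dropout = c(0.2, 0.2, 0.5), seed = 1L) {
  stopifnot(length(input_shape) == 3L, input_shape[3L] == 3L,
            is_count(n_classes, 2L), length(dropout) == 3L)
  H <- as.integer(input_shape[1L]); W <- as.integer(input_shape[2L])
  out_hw <- cnn_output_shape(H, W)   # errors if too small, naming the block
  flat_dim <- out_hw[1L] * out_hw[2L] * filters
  chans <- c(3L, filters, filters)
  with_seed(seed, {
    params <- list()
    for (b in 1:3) {
      fan_in <- 9L * chans[b]
      params[[paste0("w", b)]] <- matrix(
        stats::rnorm(fan_in * filters, sd = sqrt(2 / fan_in)), fan_in, filters)
      params[[paste0("b", b)]] <- numeric(filters)
      params[[paste0("gamma", b)]] <- rep(1, filters)
      params[[paste0("beta", b)]] <- numeric(filters)
    }
    lim <- sqrt(6 / (flat_dim + n_classes))
    params$w_dense <- matrix(stats::runif(flat_dim * n_classes, -lim, lim),
                             flat_dim, n_classes)
    params$b_dense <- numeric(n_classes)
    structure(list(
      input_shape = c(H, W, 3L), n_classes = as.integer(n_classes),
      filters = as.integer(filters), dropout = dropout,
      out_hw = out_hw, flat_dim = flat_dim,
      params = params,
      bn_running = lapply(1:3, function(b) list(mean = numeric(filters),
                                                var = rep(1, filters))),
      bn_eps = 1e-3, bn_momentum = 0.9, seed = as.integer(seed)
    ), class = "gsn_cnn")
  })
}

#' @export
print.gsn_cnn <- function(x, ...) {
  cat(sprintf(
    "<gsn_cnn> input %dx%dx3, 3 conv blocks (%d filters 3x3, dropout %.2f/%.2f/%.2f), dense softmax over %d classes (%d features)\n",
    x$input_shape[1L], x$input_shape[2L], x$filters,
    x$dropout[1L], x$dropout[2L], x$dropout[3L], x$n_classes, x$flat_dim))
  invisible(x)
}

# ---- forward / backward --------------------------------------------------

bn_forward <- function(x, gamma, beta, running, eps, momentum, training) {
  if (training) {
    st <- bn_stats(x)
    mu <- st$mean
    va <- st$var
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * va
  } else {
    mu <- running$mean
    va <- running$var
  }
  istd <- 1 / sqrt(va + eps)
  ap <- bn_apply(x, gamma, beta, mu, istd)
  list(out = ap$out, cache = list(xhat = ap$xhat, istd = istd),
       running = running)
}

bn_backward <- function(dout, gamma, cache) {
  bn_backward_cpp(dout, cache$xhat, gamma, cache$istd)
}

# One full forward pass over a batch; caches kept only when training.
cnn_forward <- function(model, x, training = FALSE) {
  p <- model$params
  strides <- c(1L, 1L, 2L)
  caches <- list()
  a <- x
  for (b in 1:3) {
    z <- conv2d_forward(a, p[[paste0("w", b)]], p[[paste0("b", b)]], 3L, 3L,
                        relu = TRUE)
    pool <- maxpool_forward(z, 2L, strides[b])
    bn <- bn_forward(pool$out, p[[paste0("gamma", b)]], p[[paste0("beta", b)]],
                     model$bn_running[[b]], model$bn_eps, model$bn_momentum,
                     training)
    if (training) model$bn_running[[b]] <- bn$running
    h <- bn$out
    if (training && model$dropout[b] > 0) {
      mask <- (stats::runif(length(h)) >= model$dropout[b]) / (1 - model$dropout[b])
      dim(mask) <- dim(h)
      h <- h * mask
    } else {
      mask <- NULL
    }
    if (training) {
      caches[[b]] <- list(a_in = a, z_act = z,
                          argmax = pool$argmax, z_dim = dim(z),
                          bn_cache = bn$cache, drop_mask = mask)
    }
    a <- h
  }
  n <- dim(a)[4L]
  flat <- t(matrix(a, nrow = model$flat_dim, ncol = n))   # n x D
  z <- sweep(flat %*% p$w_dense, 2L, p$b_dense, `+`)
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(probs = probs, flat = flat, caches = caches, model = model,
       a_dim = dim(a))
}

# Backward pass from softmax cross-entropy; returns gradient list matching
# model$params.
cnn_backward <- function(model, fwd, y_onehot) {
  p <- model$params
  n <- nrow(y_onehot)
  grads <- list()
  dz <- (fwd$probs - y_onehot) / n                      # n x K
  grads$w_dense <- crossprod(fwd$flat, dz)
  grads$b_dense <- colSums(dz)
  dflat <- dz %*% t(p$w_dense)                          # n x D
  da <- array(t(dflat), dim = fwd$a_dim)
  strides <- c(1L, 1L, 2L)
  for (b in 3:1) {
    cc <- fwd$caches[[b]]
    if (!is.null(cc$drop_mask)) da <- da * cc$drop_mask
    bnb <- bn_backward(da, p[[paste0("gamma", b)]], cc$bn_cache)
    grads[[paste0("gamma", b)]] <- bnb$dgamma
    grads[[paste0("beta", b)]] <- bnb$dbeta
    dz_conv <- maxpool_backward(bnb$dx, cc$argmax, cc$z_dim, gate = cc$z_act)
    convb <- conv2d_backward(cc$a_in, p[[paste0("w", b)]], dz_conv, 3L, 3L)
    grads[[paste0("w", b)]] <- convb$dw
    grads[[paste0("b", b)]] <- convb$db
    da <- convb$dx
  }
  grads
}

# ---- training ------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the reference setting for this model family: Adam with
#' learning rate 0.05, 80 epochs, a 70/30 train/test split and batches
#' of 32.
#'
#' @param learning_rate Adam step size (> 0, or 0 for a no-op run).
#' @param epochs Number of passes over the training data (>= 1).
#' @param train_fraction Fraction of samples used for training.
#' @param seed Integer seed (weight init uses the model's own seed; this one
#'   governs shuffling and dropout).
#' @param batch_size Mini-batch size.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.05, epochs = 80L,
                         train_fraction = 0.7, seed = 1L, batch_size = 32L) {
  stopifnot(learning_rate >= 0, is_count(epochs, 1L),
            train_fraction > 0, train_fraction < 1, is_count(batch_size, 1L))
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 batch_size = as.integer(batch_size)),
            class = "train_config")
}

#' Split samples into train and test sets
#'
#' Stratified by default: each class contributes `round(fraction * n_class)`
#' training samples; otherwise a plain random split of size
#' `round(fraction * n)`. Disjoint and exhaustive, reproducible given the
#' seed.
#'
#' @param labels Integer class indices (0-based) per sample.
#' @param train_fraction Fraction of samples in the training set.
#' @param seed Integer seed.
#' @param stratified Stratify by class (default `TRUE`).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_fraction = 0.7, seed = 1L,
                             stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- length(labels)
  with_seed(seed, {
    if (stratified) {
      train <- integer(0)
      for (k in sort(unique(labels))) {
        idx <- which(labels == k)
        n_tr <- round(train_fraction * length(idx))
        if (n_tr == 0L) {
          abort_validation(sprintf(
            "class %s would have no training samples under the stratified split.", k))
        }
        train <- c(train, sample(idx, n_tr))
      }
      train <- sort(train)
    } else {
      train <- sort(sample(n, round(train_fraction * n)))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Train the CNN with Adam on softmax cross-entropy
#'
#' Minimizes categorical cross-entropy over one-hot labels with the Adam
#' optimizer (moment decays 0.9/0.999). The per-epoch history reports loss
#' and accuracy from a clean inference-mode pass (dropout off, running
#' batch-norm statistics) over the training set, and over `validation` when
#' supplied.
#'
#' @param model A [build_cnn()] model.
#' @param images `H x W x 3 x N` numeric array of training images in
#'   \[0, 1\].
#' @param labels Integer class indices (0-based), length N.
#' @param config A [train_config()].
#' @param validation Optional `list(images =, labels =)` evaluated each
#'   epoch.
#' @return The trained `gsn_cnn`; its `history` attribute is a tibble with
#'   one row per epoch (`epoch`, `loss`, `accuracy`, `val_loss`,
#'   `val_accuracy`).
#' @export
train_cnn <- function(model, images, labels, config = train_config(),
                      validation = NULL) {
  stopifnot(inherits(model, "gsn_cnn"))
  d <- dim(images)
  if (length(d) != 4L || !all(d[1:3] == model$input_shape)) {
    abort_validation("image array shape does not match the model input shape.")
  }
  n <- d[4L]
  if (n < 1L) abort_validation("no training images.")
  if (length(labels) != n) abort_validation("labels length != image count.")
  K <- model$n_classes
  if (any(labels < 0L | labels >= K)) abort_validation("label index out of range.")
  onehot <- diag(K)[labels + 1L, , drop = FALSE]
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-7
  adam_m <- lapply(model$params, function(p) p * 0)
  adam_v <- adam_m
  step <- 0L
  hist <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- images[, , , idx, drop = FALSE]
        fwd <- cnn_forward(model, xb, training = TRUE)
        model <- fwd$model   # updated batch-norm running stats
        if (!all(is.finite(fwd$probs))) {
          abort_runtime(sprintf("non-finite training loss at epoch %d.", epoch))
        }
        grads <- cnn_backward(model, fwd, onehot[idx, , drop = FALSE])
        step <- step + 1L
        for (nm in names(model$params)) {
          g <- grads[[nm]]
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g * g
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          model$params[[nm]] <- model$params[[nm]] -
            lr * mhat / (sqrt(vhat) + adam_eps)
        }
      }
      tr <- evaluate_pass(model, images, labels)
      if (!is.finite(tr$loss)) {
        abort_runtime(sprintf("non-finite training loss at epoch %d.", epoch))
      }
      va <- if (!is.null(validation)) {
        evaluate_pass(model, validation$images, validation$labels)
      } else list(loss = NA_real_, accuracy = NA_real_)
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = tr$loss, accuracy = tr$accuracy,
        val_loss = va$loss, val_accuracy = va$accuracy)
    }
  })
  attr(model, "history") <- do.call(rbind, hist)
  model
}

# Inference-mode loss/accuracy over a (possibly large) image array, batched
# to bound memory.
evaluate_pass <- function(model, images, labels, batch_size = 64L) {
  probs <- predict(model, images, batch_size = batch_size)
  n <- nrow(probs)
  py <- probs[cbind(seq_len(n), labels + 1L)]
  list(loss = -mean(log(pmax(py, 1e-12))),
       accuracy = mean(max.col(probs, ties.method = "first") - 1L == labels))
}

#' Predict class probabilities for images
#'
#' Forward pass in inference mode: dropout disabled, batch normalization
#' using running statistics; deterministic.
#'
#' @param object A (trained) `gsn_cnn`.
#' @param images `H x W x 3 x N` array (or a single `H x W x 3` image).
#' @param batch_size Images per forward batch.
#' @param ... Unused.
#' @return `N x K` matrix of class probabilities; rows sum to 1.
#' @export
predict.gsn_cnn <- function(object, images, batch_size = 64L, ...) {
  d <- dim(images)
  if (length(d) == 3L) {
    dim(images) <- c(d, 1L)
    d <- dim(images)
  }
  if (length(d) != 4L || !all(d[1:3] == object$input_shape)) {
    abort_validation("image array shape does not match the model input shape.")
  }
  n <- d[4L]
  out <- matrix(NA_real_, n, object$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- cnn_forward(object, images[, , , idx, drop = FALSE], training = FALSE)
    out[idx, ] <- fwd$probs
  }
  out
}

#' Per-epoch training history as a tibble
#'
#' @param x A trained `gsn_cnn`.
#' @param ... Unused.
#' @return Tibble `epoch`, `loss`, `accuracy`, `val_loss`, `val_accuracy`.
#' @export
tidy.gsn_cnn <- function(x, ...) {
  h <- attr(x, "history")
  if (is.null(h)) abort_validation("model has no training history yet.")
  h
}

#' One-row training summary
#'
#' @param x A trained `gsn_cnn`.
#' @param ... Unused.
#' @return One-row tibble with the final epoch's metrics.
#' @export
glance.gsn_cnn <- function(x, ...) {
  h <- tidy(x)
  out <- h[nrow(h), , drop = FALSE]
  names(out)[1L] <- "epochs"
  out
}
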