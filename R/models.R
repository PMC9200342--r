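#' Hyperparameter specification for the dual-branch deep classifier
#'
#' The architecture follows the published design: a raw-sequence branch of
#' two 1-D convolutional blocks (convolution, batch normalisation, ReLU,
#' max-pooling) feeding an LSTM, and a scaleogram branch of two 2-D
#' convolutional blocks; the branch outputs are concatenated and passed
#' through a fully connected layer, dropout and a 3-way softmax. L2 weight
#' decay is attached to the convolutional, LSTM and dense kernels. Filter
#' counts, LSTM width, dropout, decay and optimiser settings are tunable
#' defaults, not reported values.
#'
#' @param conv1d_filters Filters of the two 1-D conv blocks (default 32, 64).
#' @param conv1d_kernel Odd 1-D kernel size (default 3).
#' @param lstm_units LSTM width (default 64).
#' @param conv2d_filters Filters of the two 2-D conv blocks (default 16, 32).
#' @param conv2d_kernel Odd 2-D kernel (default `c(3, 3)`).
#' @param dense_units Fully connected width after concatenation (default 64).
#' @param dropout_rate Dropout rate in `[0, 1)` (default 0.3).
#' @param l2_lambda L2 weight-decay coefficient (default 1e-3).
#' @param learning_rate,batch_size,epochs Adam optimiser settings.
#' @param seed Integer seed for initialisation, shuffling and dropout.
#' @return A list of class `hc_deep_spec`.
#' @export
deep_model_spec <- function(conv1d_filters = c(32, 64), conv1d_kernel = 3,
                            lstm_units = 64, conv2d_filters = c(16, 32),
                            conv2d_kernel = c(3, 3), dense_units = 64,
                            dropout_rate = 0.3, l2_lambda = 1e-3,
                            learning_rate = 1e-3, batch_size = 64,
                            epochs = 100, seed = 1L) {
  stopifnot(length(conv1d_filters) == 2, length(conv2d_filters) == 2,
            dropout_rate >= 0, dropout_rate < 1, l2_lambda >= 0)
  structure(as.list(environment()), class = "hc_deep_spec")
}

#' @rdname deep_model_spec
#' @param hidden_units Sizes of the two hidden dense layers (default 32, 32).
#' @return For `ffnn_spec()`: a list of class `hc_ffnn_spec`.
#' @export
ffnn_spec <- function(hidden_units = c(32, 32), learning_rate = 1e-3,
                      batch_size = 32, epochs = 100, l2_lambda = 0,
                      seed = 1L) {
  stopifnot(length(hidden_units) == 2)
  structure(as.list(environment()), class = "hc_ffnn_spec")
}

#' One 1-D convolutional block
#'
#' Applies the published block in order: convolution over the time axis
#' ('same' padding, stride 1), batch normalisation, ReLU activation and
#' max-pooling with pool size 2 (halving the time dimension). Provided as a
#' standalone, seeded operation for inspecting the block's stages; the full
#' model wires the same layers internally.
#'
#' @param x A `time x channels` numeric matrix.
#' @param filters Number of convolution filters.
#' @param kernel_size Odd kernel width (default 3).
#' @param seed Seed for the kernel initialisation.
#' @return The pooled feature map (`floor(time/2) x filters`), with the
#'   intermediate stages attached as attributes `preactivation` (conv
#'   output), `normalized` (after BN) and `activation` (after ReLU).
#' @export
conv_block_1d <- function(x, filters, kernel_size = 3, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < kernel_size) {
    abort("Input is shorter than the convolution kernel.")
  }
  withr::with_seed(seed, {
    conv <- layer_conv1d(nrow(x), ncol(x), filters, kernel_size)
    bn <- layer_bn(filters)
    pool <- layer_pool1d(nrow(x))
    y <- conv1d_fwd(conv, x, 1L)
    s_buf <- bn_fwd(bn, y, training = TRUE)
    s <- s_buf + 0           # snapshot: the activation is applied in place
    relu <- layer_relu()
    h <- relu_fwd(relu, s_buf)
    f <- pool1d_fwd(pool, h, 1L)
    attr(f, "preactivation") <- y
    attr(f, "normalized") <- s
    attr(f, "activation") <- h
    f
  })
}

#' Build the dual-branch deep classifier
#'
#' Constructs the untrained network for a given input geometry: raw
#' sequences of shape `seq_shape` (time x channels) and scaleograms of shape
#' `scaleo_shape` (scales x time x channels). Identical specs and seeds give
#' identical initial weights.
#'
#' @param seq_shape Length-2 integer vector, default `c(48, 4)`.
#' @param scaleo_shape Length-3 integer vector, default `c(8, 48, 4)`.
#' @param spec An [deep_model_spec()].
#' @return An object of class `hc_nn` (untrained).
#' @export
build_deep_model <- function(seq_shape = c(48, 4), scaleo_shape = c(8, 48, 4),
                             spec = deep_model_spec()) {
  stopifnot(inherits(spec, "hc_deep_spec"))
  l2 <- spec$l2_lambda
  withr::with_seed(spec$seed, {
    len <- seq_shape[1]
    # conv biases are omitted: each convolution feeds a batch-norm layer,
    # whose centring makes a bias an exact no-op
    ca <- layer_conv1d(len, seq_shape[2], spec$conv1d_filters[1],
                       spec$conv1d_kernel, l2, use_bias = FALSE)
    pa <- layer_pool1d(len)
    cb <- layer_conv1d(pa$out_len, spec$conv1d_filters[1],
                       spec$conv1d_filters[2], spec$conv1d_kernel, l2,
                       use_bias = FALSE)
    pb <- layer_pool1d(pa$out_len)
    lstm <- layer_lstm(pb$out_len, spec$conv1d_filters[2], spec$lstm_units, l2)
    h <- scaleo_shape[1]; w <- scaleo_shape[2]
    da <- layer_conv2d(h, w, scaleo_shape[3], spec$conv2d_filters[1],
                       spec$conv2d_kernel, l2, use_bias = FALSE)
    qa <- layer_pool2d(h, w)
    db <- layer_conv2d(qa$oh, qa$ow, spec$conv2d_filters[1],
                       spec$conv2d_filters[2], spec$conv2d_kernel, l2,
                       use_bias = FALSE)
    qb <- layer_pool2d(qa$oh, qa$ow)
    flat <- layer_flatten(qb$oh * qb$ow, spec$conv2d_filters[2])
    concat_dim <- spec$lstm_units + qb$oh * qb$ow * spec$conv2d_filters[2]
    layers <- list(
      conv1a = ca, bn1a = layer_bn(spec$conv1d_filters[1]),
      relu1a = layer_relu(), pool1a = pa,
      conv1b = cb, bn1b = layer_bn(spec$conv1d_filters[2]),
      relu1b = layer_relu(), pool1b = pb,
      lstm = lstm,
      conv2a = da, bn2a = layer_bn(spec$conv2d_filters[1]),
      relu2a = layer_relu(), pool2a = qa,
      conv2b = db, bn2b = layer_bn(spec$conv2d_filters[2]),
      relu2b = layer_relu(), pool2b = qb,
      flatten = flat,
      dense = layer_dense(concat_dim, spec$dense_units, l2),
      relu_d = layer_relu(),
      dropout = layer_dropout(spec$dropout_rate),
      out = layer_dense(spec$dense_units, 3)
    )
  })
  structure(
    list(type = "deep", spec = spec, layers = layers,
         seq_shape = seq_shape, scaleo_shape = scaleo_shape,
         trained = FALSE, history = NULL),
    class = "hc_nn"
  )
}

#' Build the feed-forward baseline network
#'
#' Three dense layers (two hidden plus the 3-way softmax output) with a batch
#' normalisation layer between consecutive dense layers, trained with sparse
#' categorical crossentropy; consumes the 4 per-bin channel means.
#'
#' @param input_dim Number of input features (default 4).
#' @param spec An [ffnn_spec()].
#' @return An object of class `hc_nn` (untrained).
#' @export
build_ffnn <- function(input_dim = 4, spec = ffnn_spec()) {
  stopifnot(inherits(spec, "hc_ffnn_spec"))
  withr::with_seed(spec$seed, {
    layers <- list(
      dense1 = layer_dense(input_dim, spec$hidden_units[1], spec$l2_lambda),
      bn1 = layer_bn(spec$hidden_units[1]),
      relu1 = layer_relu(),
      dense2 = layer_dense(spec$hidden_units[1], spec$hidden_units[2],
                           spec$l2_lambda),
      bn2 = layer_bn(spec$hidden_units[2]),
      relu2 = layer_relu(),
      out = layer_dense(spec$hidden_units[2], 3)
    )
  })
  structure(
    list(type = "ffnn", spec = spec, layers = layers, input_dim = input_dim,
         trained = FALSE, history = NULL),
    class = "hc_nn"
  )
}

#' Layer sequence of a network
#'
#' Returns the ordered types of the structural (parameterised) layers, for
#' introspection: activations are treated as part of their preceding layer.
#'
#' @param model An `hc_nn`.
#' @return Character vector of layer types.
#' @export
layer_sequence <- function(model) {
  stopifnot(inherits(model, "hc_nn"))
  keep <- vapply(model$layers, function(ly) {
    !ly$type %in% c("relu", "dropout", "flatten")
  }, logical(1))
  out <- vapply(model$layers[keep], function(ly) ly$type, character(1))
  out[length(out)] <- "dense_softmax"
  unname(out)
}

# Internal tensor packing: sample-major (N*S) x C matrices ------------------

pack_sequences <- function(a) {
  d <- dim(a)                                   # N x T x C
  matrix(aperm(a, c(2, 1, 3)), d[1] * d[2], d[3])
}

pack_scaleograms <- function(a) {
  d <- dim(a)                                   # N x H x W x C
  matrix(aperm(a, c(3, 2, 1, 4)), d[1] * d[2] * d[3], d[4])
}

seq_rows <- function(idx, s) rep((idx - 1L) * s, each = s) + seq_len(s)

deep_forward <- function(model, xs, xi, n, training) {
  L <- model$layers
  h1 <- conv1d_fwd(L$conv1a, xs, n)
  h1 <- bn_fwd(L$bn1a, h1, training)
  h1 <- relu_fwd(L$relu1a, h1)
  h1 <- pool1d_fwd(L$pool1a, h1, n)
  h1 <- conv1d_fwd(L$conv1b, h1, n)
  h1 <- bn_fwd(L$bn1b, h1, training)
  h1 <- relu_fwd(L$relu1b, h1)
  h1 <- pool1d_fwd(L$pool1b, h1, n)
  h1 <- lstm_fwd(L$lstm, h1, n)
  h2 <- conv2d_fwd(L$conv2a, xi, n)
  h2 <- bn_fwd(L$bn2a, h2, training)
  h2 <- relu_fwd(L$relu2a, h2)
  h2 <- pool2d_fwd(L$pool2a, h2, n)
  h2 <- conv2d_fwd(L$conv2b, h2, n)
  h2 <- bn_fwd(L$bn2b, h2, training)
  h2 <- relu_fwd(L$relu2b, h2)
  h2 <- pool2d_fwd(L$pool2b, h2, n)
  h2 <- flatten_fwd(L$flatten, h2, n)
  hc <- cbind(h1, h2)
  hd <- dense_fwd(L$dense, hc)
  hd <- relu_fwd(L$relu_d, hd)
  hd <- dropout_fwd(L$dropout, hd, training)
  dense_fwd(L$out, hd)
}

deep_backward <- function(model, dlogits) {
  L <- model$layers
  d <- dense_bwd(L$out, dlogits)
  d <- dropout_bwd(L$dropout, d)
  d <- relu_bwd(L$relu_d, d)
  d <- dense_bwd(L$dense, d)
  u <- L$lstm$units
  d1 <- d[, seq_len(u), drop = FALSE]
  d2 <- d[, -seq_len(u), drop = FALSE]
  d2 <- flatten_bwd(L$flatten, d2)
  d2 <- pool2d_bwd(L$pool2b, d2)
  d2 <- relu_bwd(L$relu2b, d2)
  d2 <- bn_bwd(L$bn2b, d2)
  d2 <- conv2d_bwd(L$conv2b, d2)
  d2 <- pool2d_bwd(L$pool2a, d2)
  d2 <- relu_bwd(L$relu2a, d2)
  d2 <- bn_bwd(L$bn2a, d2)
  conv2d_bwd(L$conv2a, d2)
  d1 <- lstm_bwd(L$lstm, d1)
  d1 <- pool1d_bwd(L$pool1b, d1)
  d1 <- relu_bwd(L$relu1b, d1)
  d1 <- bn_bwd(L$bn1b, d1)
  d1 <- conv1d_bwd(L$conv1b, d1)
  d1 <- pool1d_bwd(L$pool1a, d1)
  d1 <- relu_bwd(L$relu1a, d1)
  d1 <- bn_bwd(L$bn1a, d1)
  conv1d_bwd(L$conv1a, d1)
  invisible(NULL)
}

ffnn_forward <- function(model, x, training) {
  L <- model$layers
  h <- dense_fwd(L$dense1, x)
  h <- bn_fwd(L$bn1, h, training)
  h <- relu_fwd(L$relu1, h)
  h <- dense_fwd(L$dense2, h)
  h <- bn_fwd(L$bn2, h, training)
  h <- relu_fwd(L$relu2, h)
  dense_fwd(L$out, h)
}

ffnn_backward <- function(model, dlogits) {
  L <- model$layers
  d <- dense_bwd(L$out, dlogits)
  d <- relu_bwd(L$relu2, d)
  d <- bn_bwd(L$bn2, d)
  d <- dense_bwd(L$dense2, d)
  d <- relu_bwd(L$relu1, d)
  d <- bn_bwd(L$bn1, d)
  dense_bwd(L$dense1, d)
  invisible(NULL)
}

nn_inputs <- function(model, x) {
  if (model$type == "deep") {
    stopifnot(is.list(x), !is.null(x$seq), !is.null(x$scaleo))
    sd <- dim(x$seq); id <- dim(x$scaleo)
    if (!identical(sd[2:3], as.integer(model$seq_shape)) ||
        !identical(id[2:4], as.integer(model$scaleo_shape))) {
      abort("Input shapes do not match the shapes the model was built for.")
    }
    list(n = sd[1], xs = pack_sequences(x$seq),
         xi = pack_scaleograms(x$scaleo),
         s_seq = sd[2], s_img = id[2] * id[3])
  } else {
    x <- as.matrix(x)
    if (ncol(x) != model$input_dim) {
      abort("Input width does not match the model's input dimension.")
    }
    list(n = nrow(x), xm = x)
  }
}

nn_logits <- function(model, packed, idx, training) {
  if (model$type == "deep") {
    deep_forward(model,
                 packed$xs[seq_rows(idx, packed$s_seq), , drop = FALSE],
                 packed$xi[seq_rows(idx, packed$s_img), , drop = FALSE],
                 length(idx), training)
  } else {
    ffnn_forward(model, packed$xm[idx, , drop = FALSE], training)
  }
}

#' Train a neural classifier
#'
#' Minimises (optionally class-weighted) sparse categorical crossentropy with
#' Adam over shuffled mini-batches. All randomness (shuffling, dropout) is
#' driven by the model spec's seed, so a rebuilt model retrained on the same
#' data reproduces the same trajectory.
#'
#' @param model An untrained `hc_nn` from [build_deep_model()] or
#'   [build_ffnn()].
#' @param x For the deep model a list with `seq` (N x time x 4 array) and
#'   `scaleo` (N x scales x time x 4 array); for the FFNN an N x 4 matrix or
#'   data frame of standardised features.
#' @param labels Integer class vector (0, 1, 2).
#' @param weights Optional per-class loss weights from [class_weights()].
#' @param epochs,batch_size Optional overrides of the spec values.
#' @param verbose Print the per-epoch loss.
#' @return The trained model, with a `history` tibble (epoch, loss, accuracy).
#' @export
train_nn <- function(model, x, labels, weights = NULL, epochs = NULL,
                     batch_size = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "hc_nn"))
  labels <- as.integer(labels)
  if (any(labels < 0 | labels > 2)) abort("Labels must be 0, 1 or 2.")
  spec <- model$spec
  epochs <- epochs %||% spec$epochs
  batch_size <- batch_size %||% spec$batch_size
  packed <- nn_inputs(model, x)
  n <- packed$n
  if (!is.null(weights)) names(weights) <- as.character(names(weights))
  step <- 0L
  hist <- vector("list", epochs)
  withr::with_seed(spec$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hit <- 0L
      for (b in seq_len(ceiling(n / batch_size))) {
        idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
        logits <- nn_logits(model, packed, idx, training = TRUE)
        probs <- softmax_rows(logits)
        ce <- weighted_ce(probs, labels[idx], weights)
        if (!is.finite(ce$loss)) {
          abort(paste0("Non-finite training loss at epoch ", ep, ", batch ",
                       b, "; reduce the learning rate."))
        }
        if (model$type == "deep") {
          deep_backward(model, ce_grad(probs, labels[idx], ce$wv))
        } else {
          ffnn_backward(model, ce_grad(probs, labels[idx], ce$wv))
        }
        step <- step + 1L
        adam_step(model$layers, spec$learning_rate, step)
        ep_loss <- ep_loss + ce$loss * length(idx)
        ep_hit <- ep_hit + sum(max.col(probs, ties.method = "first") - 1L ==
                                 labels[idx])
      }
      hist[[ep]] <- tibble::tibble(
        epoch = ep,
        loss = ep_loss / n + l2_penalty(model$layers),
        accuracy = ep_hit / n
      )
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                        hist[[ep]]$loss, hist[[ep]]$accuracy))
      }
    }
  })
  model$trained <- TRUE
  model$history <- purrr::list_rbind(hist)
  model
}

#' Predicted class probabilities
#'
#' @param model A trained `hc_nn`.
#' @param x Inputs in the same form as for [train_nn()].
#' @return An N x 3 row-stochastic matrix.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "hc_nn"))
  packed <- nn_inputs(model, x)
  softmax_rows(nn_logits(model, packed, seq_len(packed$n), training = FALSE))
}

#' @export
predict.hc_nn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") return(p)
  # argmax with ties broken toward the lowest class index
  max.col(p, ties.method = "first") - 1L
}

#' @export
print.hc_nn <- function(x, ...) {
  cat("<hc_nn> ", x$type, " classifier (",
      if (x$trained) "trained" else "untrained", ")\n", sep = "")
  cat("layers:", paste(layer_sequence(x), collapse = " -> "), "\n")
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model An `hc_nn`.
#' @return Total number of trainable scalars (convolution, LSTM and dense
#'   weights and biases, batch-norm gains and shifts).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "hc_nn"))
  sum(vapply(model$layers, function(ly) {
    if (length(ly$par) == 0) return(0L)
    sum(vapply(ly$par, function(p) length(ly[[p]]), integer(1)))
  }, integer(1)))
}

#' Untrained shallow baseline classifiers
#'
#' `make_baseline("svm")` specifies a one-vs-one support vector classifier
#' (libsvm via e1071) with the default cost `C = 1` and optional per-class
#' weights; the kernel is the library default (RBF) and configurable.
#' `make_baseline("random_forest")` specifies a depth-limited random forest
#' (ranger) with maximum tree depth 4, grown as a probability forest so that
#' class probabilities are available.
#'
#' @param name `"svm"` or `"random_forest"`.
#' @param cost SVM cost parameter (default 1).
#' @param kernel SVM kernel (default `"radial"`).
#' @param max_depth Maximum tree depth (default 4).
#' @param num_trees Number of trees (default 100).
#' @return A list of class `hc_baseline_spec`.
#' @export
make_baseline <- function(name = c("svm", "random_forest"), cost = 1,
                          kernel = "radial", max_depth = 4, num_trees = 100) {
  name <- match.arg(name)
  structure(list(name = name, cost = cost, kernel = kernel,
                 max_depth = max_depth, num_trees = num_trees),
            class = "hc_baseline_spec")
}

#' Fit a shallow baseline
#'
#' @param spec An [make_baseline()] specification.
#' @param x N x 4 matrix or data frame of standardised per-bin features.
#' @param labels Integer class vector (0, 1, 2).
#' @param weights Optional per-class weights from [class_weights()]; the SVM
#'   consumes them as class weights, the forest as per-case sampling weights.
#' @param seed Seed for the forest's bootstrap.
#' @return A fitted object of class `hc_baseline`.
#' @export
fit_baseline <- function(spec, x, labels, weights = NULL, seed = 1L) {
  stopifnot(inherits(spec, "hc_baseline_spec"))
  x <- as.matrix(x)
  y <- factor(labels, levels = 0:2)
  fit <- if (spec$name == "svm") {
    cw <- if (is.null(weights)) NULL else weights[levels(y)[table(y) > 0]]
    e1071::svm(x = x, y = droplevels(y), kernel = spec$kernel,
               cost = spec$cost, class.weights = cw, probability = FALSE,
               scale = FALSE)
  } else {
    cw <- if (is.null(weights)) rep(1, length(labels)) else
      unname(weights[as.character(labels)])
    ranger::ranger(
      x = as.data.frame(x), y = droplevels(y), num.trees = spec$num_trees,
      max.depth = spec$max_depth, probability = TRUE, seed = seed,
      case.weights = cw, num.threads = 1
    )
  }
  structure(list(spec = spec, fit = fit), class = "hc_baseline")
}

#' @export
predict.hc_baseline <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (object$spec$name == "svm") {
    cls <- as.integer(as.character(predict(object$fit, newdata)))
    if (type == "class") return(cls)
    p <- matrix(0, length(cls), 3)
    p[cbind(seq_along(cls), cls + 1L)] <- 1
    return(p)
  }
  pr <- predict(object$fit, data = as.data.frame(newdata),
                num.threads = 1)$predictions
  p <- matrix(0, nrow(pr), 3, dimnames = list(NULL, 0:2))
  p[, colnames(pr)] <- pr
  if (type == "prob") return(unname(p))
  max.col(p, ties.method = "first") - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
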