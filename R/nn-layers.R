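# Minimal batched neural-network layer kernel used by the deep and
# feed-forward classifiers. Everything is expressed as dense matrix algebra
# so the heavy lifting happens in BLAS:
#   - activations with spatial structure are stored as (N * S) x C matrices,
#     rows ordered sample-major (all positions of sample 1, then sample 2...),
#     spatial index row-major for 2-D maps;
#   - convolutions are im2col gathers followed by one GEMM;
#   - the LSTM runs a 12-step BPTT loop of small GEMMs.
# Memory-bound elementwise steps (gather/scatter, batch norm, ReLU, pooling,
# Adam) are compiled kernels in src/kernels.cpp. Layers are environments:
# mutable caches, parameters, gradients and Adam moments live inside each
# layer.

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

new_layer <- function(type, ...) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  ly$par <- character(0)
  ly$decay <- character(0)
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = ly)
  ly
}

add_param <- function(ly, name, value, decay = FALSE) {
  ly[[name]] <- value
  ly$par <- c(ly$par, name)
  if (decay) ly$decay <- c(ly$decay, name)
  ly$g <- NULL
}

# ---- dense ----------------------------------------------------------------

layer_dense <- function(in_dim, units, l2 = 0) {
  ly <- new_layer("dense", in_dim = in_dim, units = units, l2 = l2)
  add_param(ly, "W", glorot(in_dim, units), decay = l2 > 0)
  add_param(ly, "b", numeric(units))
  ly
}

dense_fwd <- function(ly, x) {
  ly$x <- x
  sweep_add(x %*% ly$W, ly$b)
}

dense_bwd <- function(ly, dy) {
  ly$g <- list(W = crossprod(ly$x, dy), b = colSums(dy))
  dy %*% t(ly$W)
}

sweep_add <- function(m, b) m + rep(b, each = nrow(m))

# ---- batch normalisation --------------------------------------------------
# Per-channel (column) statistics; for conv activations the (N*S) rows pool
# batch and spatial positions, matching channel-wise BN. Momentum 0.9 keeps
# the inference-time running statistics usable after short trainings.

layer_bn <- function(channels, momentum = 0.9, eps = 1e-3) {
  ly <- new_layer("bn", channels = channels, momentum = momentum, eps = eps,
                  rmean = numeric(channels), rvar = rep(1, channels),
                  bufs = list())
  add_param(ly, "gamma", rep(1, channels))
  add_param(ly, "beta", numeric(channels))
  ly
}

# Reusable per-shape output buffer owned by a layer.
layer_buf <- function(ly, nr, nc) {
  key <- as.character(nr)
  buf <- ly$bufs[[key]]
  if (is.null(buf)) {
    buf <- matrix(0, nr, nc)
    ly$bufs[[key]] <- buf
  }
  buf
}

bn_fwd <- function(ly, x, training) {
  if (training) {
    y <- layer_buf(ly, nrow(x), ncol(x))
    res <- cpp_bn_train(x, ly$gamma, ly$beta, ly$eps, y)
    ly$rmean <- ly$momentum * ly$rmean + (1 - ly$momentum) * res$mu
    ly$rvar <- ly$momentum * ly$rvar + (1 - ly$momentum) * res$var
    ly$x <- x; ly$mu <- res$mu; ly$inv <- res$inv
    y
  } else {
    cpp_bn_infer(x, ly$gamma, ly$beta, ly$rmean, ly$rvar, ly$eps)
  }
}

bn_bwd <- function(ly, dy) {
  res <- cpp_bn_bwd(dy, ly$x, ly$mu, ly$inv, ly$gamma)
  ly$g <- list(gamma = res$dgamma, beta = res$dbeta)
  res$dx
}

# ---- relu -----------------------------------------------------------------
# Applied in place on the incoming forward temporary; the activation itself
# is cached and y > 0 gates the gradient.

layer_relu <- function() new_layer("relu")
relu_fwd <- function(ly, x) { y <- cpp_relu(x); ly$y <- y; y }
relu_bwd <- function(ly, dy) cpp_relu_bwd(dy, ly$y)

# ---- 1-D convolution ('same' padding, stride 1, odd kernel) ---------------
# im2col column order: (channel, tap) with tap fastest, matching the row
# order of the kernel matrix W ((k * in_ch) x filters). When the convolution
# feeds a batch-norm layer the bias is omitted (`use_bias = FALSE`): BN's
# centring makes a conv bias an exact no-op, so dropping it changes nothing
# and saves a full-tensor add.

layer_conv1d <- function(len, in_ch, filters, kernel = 3, l2 = 0,
                         use_bias = TRUE) {
  stopifnot(kernel %% 2 == 1, len >= kernel)
  ly <- new_layer("conv1d", len = len, in_ch = in_ch, filters = filters,
                  kernel = kernel, l2 = l2, idx = list(), bufs = list())
  add_param(ly, "W", glorot(kernel * in_ch, filters), decay = l2 > 0)
  if (use_bias) add_param(ly, "b", numeric(filters))
  ly$use_bias <- use_bias
  ly
}

# Cached per-batch-size (ns x k) index matrix; 0 marks a padded position.
conv1d_index <- function(ly, n) {
  key <- as.character(n)
  if (!is.null(ly$idx[[key]])) return(ly$idx[[key]])
  len <- ly$len; k <- ly$kernel
  t <- rep(seq_len(len), n)
  base <- rep((seq_len(n) - 1L) * len, each = len)
  half <- (k - 1L) %/% 2L
  idx <- matrix(0L, n * len, k)
  for (j in seq_len(k)) {
    tp <- t + (j - 1L - half)
    idx[, j] <- ifelse(tp >= 1L & tp <= len, base + tp, 0L)
  }
  ly$idx[[key]] <- idx
  idx
}

conv1d_fwd <- function(ly, x, n) {
  buf <- layer_buf(ly, n * ly$len, ly$kernel * ly$in_ch)
  xcol <- cpp_conv_gather(x, conv1d_index(ly, n), buf)
  ly$xcol <- xcol; ly$n <- n
  y <- xcol %*% ly$W
  if (ly$use_bias) y <- sweep_add(y, ly$b)
  y
}

conv1d_bwd <- function(ly, dy) {
  conv_scatter(ly, dy, conv1d_index(ly, ly$n), ly$in_ch)
}

conv_scatter <- function(ly, dy, idx, ch) {
  ly$g <- if (ly$use_bias) {
    list(W = crossprod(ly$xcol, dy), b = colSums(dy))
  } else {
    list(W = crossprod(ly$xcol, dy))
  }
  cpp_conv_scatter(dy %*% t(ly$W), idx, ch)
}

# ---- 2-D convolution ('same' padding, stride 1) ---------------------------
# Spatial rows ordered (h, w) row-major within each sample.

layer_conv2d <- function(h, w, in_ch, filters, kernel = c(3, 3), l2 = 0,
                         use_bias = TRUE) {
  stopifnot(all(kernel %% 2 == 1))
  ly <- new_layer("conv2d", h = h, w = w, in_ch = in_ch, filters = filters,
                  kh = kernel[1], kw = kernel[2], l2 = l2, idx = list(),
                  bufs = list())
  add_param(ly, "W", glorot(kernel[1] * kernel[2] * in_ch, filters),
            decay = l2 > 0)
  if (use_bias) add_param(ly, "b", numeric(filters))
  ly$use_bias <- use_bias
  ly
}

conv2d_index <- function(ly, n) {
  key <- as.character(n)
  if (!is.null(ly$idx[[key]])) return(ly$idx[[key]])
  h <- ly$h; w <- ly$w; kh <- ly$kh; kw <- ly$kw
  s <- h * w; ns <- n * s
  hh <- rep(rep(seq_len(h), each = w), n)
  ww <- rep(seq_len(w), h * n)
  base <- rep((seq_len(n) - 1L) * s, each = s)
  idx <- matrix(0L, ns, kh * kw)
  j <- 0L
  for (dh in seq_len(kh) - 1L - (kh - 1L) %/% 2L) {
    for (dw in seq_len(kw) - 1L - (kw - 1L) %/% 2L) {
      j <- j + 1L
      hp <- hh + dh; wp <- ww + dw
      ok <- hp >= 1L & hp <= h & wp >= 1L & wp <= w
      idx[, j] <- ifelse(ok, base + (hp - 1L) * w + wp, 0L)
    }
  }
  ly$idx[[key]] <- idx
  idx
}

conv2d_fwd <- function(ly, x, n) {
  buf <- layer_buf(ly, n * ly$h * ly$w, ly$kh * ly$kw * ly$in_ch)
  xcol <- cpp_conv_gather(x, conv2d_index(ly, n), buf)
  ly$xcol <- xcol; ly$n <- n
  y <- xcol %*% ly$W
  if (ly$use_bias) y <- sweep_add(y, ly$b)
  y
}

conv2d_bwd <- function(ly, dy) {
  conv_scatter(ly, dy, conv2d_index(ly, ly$n), ly$in_ch)
}

# ---- max pooling ----------------------------------------------------------

layer_pool1d <- function(len) {
  stopifnot(len >= 2)
  new_layer("pool1d", len = len, out_len = len %/% 2L, rows = list())
}

pool1d_rows <- function(ly, n) {
  key <- as.character(n)
  if (!is.null(ly$rows[[key]])) return(ly$rows[[key]])
  lo <- ly$out_len
  t2 <- rep(seq_len(lo), n)
  base <- rep((seq_len(n) - 1L) * ly$len, each = lo)
  out <- list(r1 = base + 2L * t2 - 1L, r2 = base + 2L * t2)
  ly$rows[[key]] <- out
  out
}

pool1d_fwd <- function(ly, x, n) {
  r <- pool1d_rows(ly, n)
  res <- cpp_pool2_fwd(x, r$r1, r$r2)   # ties break toward the earlier step
  ly$sel <- res$sel
  ly$n <- n
  res$y
}

pool1d_bwd <- function(ly, dy) {
  r <- pool1d_rows(ly, ly$n)
  cpp_pool2_bwd(dy, ly$sel, r$r1, r$r2, ly$n * ly$len)
}

layer_pool2d <- function(h, w) {
  stopifnot(h >= 2, w >= 2)
  new_layer("pool2d", h = h, w = w, oh = h %/% 2L, ow = w %/% 2L,
            rows = list())
}

pool2d_rows <- function(ly, n) {
  key <- as.character(n)
  if (!is.null(ly$rows[[key]])) return(ly$rows[[key]])
  oh <- ly$oh; ow <- ly$ow; s <- ly$h * ly$w
  h2 <- rep(rep(seq_len(oh), each = ow), n)
  w2 <- rep(seq_len(ow), oh * n)
  base <- rep((seq_len(n) - 1L) * s, each = oh * ow)
  tl <- base + (2L * h2 - 2L) * ly$w + 2L * w2 - 1L
  out <- list(tl, tl + 1L, tl + ly$w, tl + ly$w + 1L)
  ly$rows[[key]] <- out
  out
}

pool2d_fwd <- function(ly, x, n) {
  rows <- pool2d_rows(ly, n)
  res <- cpp_pool4_fwd(x, rows[[1]], rows[[2]], rows[[3]], rows[[4]])
  ly$arg <- res$arg; ly$n <- n          # ties keep the earliest cell
  res$y
}

pool2d_bwd <- function(ly, dy) {
  rows <- pool2d_rows(ly, ly$n)
  cpp_pool4_bwd(dy, ly$arg, rows[[1]], rows[[2]], rows[[3]], rows[[4]],
                ly$n * ly$h * ly$w)
}

# ---- LSTM (returns last hidden state) -------------------------------------
# Gate order (i, f, g, o); forget-gate bias initialised to 1.

layer_lstm <- function(len, in_dim, units, l2 = 0) {
  ly <- new_layer("lstm", len = len, in_dim = in_dim, units = units, l2 = l2,
                  kbuf = list())
  add_param(ly, "Wx", glorot(in_dim, 4 * units), decay = l2 > 0)
  add_param(ly, "Wh", glorot(units, 4 * units), decay = l2 > 0)
  b <- numeric(4 * units)
  b[units + seq_len(units)] <- 1
  add_param(ly, "b", b)
  ly
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_fwd <- function(ly, x, n) {
  key <- as.character(n)
  if (is.null(ly$kbuf[[key]])) {
    ly$kbuf[[key]] <- numeric(n * ly$units * ly$len * 6)
  }
  h <- cpp_lstm_fwd(x, ly$Wx, ly$Wh, ly$b, n, ly$len, ly$kbuf[[key]])
  ly$x <- x; ly$n <- n
  h
}

lstm_bwd <- function(ly, dh) {
  res <- cpp_lstm_bwd(dh, ly$x, ly$Wx, ly$Wh, ly$kbuf[[as.character(ly$n)]],
                      ly$n, ly$len)
  ly$g <- list(Wx = res$dWx, Wh = res$dWh, b = as.numeric(res$db))
  res$dx
}

# ---- dropout / flatten / concat -------------------------------------------

layer_dropout <- function(rate) new_layer("dropout", rate = rate)

dropout_fwd <- function(ly, x, training) {
  if (!training || ly$rate <= 0) {
    ly$mask <- NULL
    return(x)
  }
  mask <- (runif(length(x)) >= ly$rate) / (1 - ly$rate)
  dim(mask) <- dim(x)
  ly$mask <- mask
  x * mask
}

dropout_bwd <- function(ly, dy) if (is.null(ly$mask)) dy else dy * ly$mask

layer_flatten <- function(s, ch) new_layer("flatten", s = s, ch = ch)

flatten_fwd <- function(ly, x, n) {
  a <- array(x, c(ly$s, n, ly$ch))
  ly$n <- n
  t(matrix(aperm(a, c(1, 3, 2)), ly$s * ly$ch, n))
}

flatten_bwd <- function(ly, dy) {
  a <- array(t(dy), c(ly$s, ly$ch, ly$n))
  matrix(aperm(a, c(1, 3, 2)), ly$s * ly$n, ly$ch)
}

# ---- softmax + weighted sparse categorical crossentropy -------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# labels: integers 0..K-1; weights: named per-class loss multipliers.
weighted_ce <- function(probs, labels, weights = NULL) {
  n <- nrow(probs)
  p <- probs[cbind(seq_len(n), labels + 1L)]
  wv <- if (is.null(weights)) rep(1, n) else
    unname(weights[as.character(labels)])
  list(loss = sum(wv * -log(pmax(p, 1e-12))) / n, wv = wv)
}

ce_grad <- function(probs, labels, wv) {
  n <- nrow(probs)
  y1 <- matrix(0, n, ncol(probs))
  y1[cbind(seq_len(n), labels + 1L)] <- 1
  (probs - y1) * wv / n
}

# ---- Adam -----------------------------------------------------------------

adam_step <- function(layers, lr, step, b1 = 0.9, b2 = 0.999, eps = 1e-7) {
  for (ly in layers) {
    if (length(ly$par) == 0 || is.null(ly$g)) next
    if (is.null(ly$m)) {
      ly$m <- lapply(ly$par, function(p) ly[[p]] * 0)
      ly$v <- lapply(ly$par, function(p) ly[[p]] * 0)
      names(ly$m) <- ly$par; names(ly$v) <- ly$par
    }
    for (p in ly$par) {
      l2 <- if (p %in% ly$decay) ly$l2 else 0
      cpp_adam_update(ly[[p]], ly$m[[p]], ly$v[[p]], ly$g[[p]],
                      lr, b1, b2, eps, step, l2)
    }
  }
}

l2_penalty <- function(layers) {
  tot <- 0
  for (ly in layers) {
    for (p in ly$decay) tot <- tot + ly$l2 * sum(ly[[p]]^2)
  }
  tot
}
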