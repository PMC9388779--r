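#' 3D CNN architecture specification
#'
#' A feature-extraction stack of `length(n_filters)` blocks, each a 3D
#' convolution (cubic kernel, zero padding) followed by ReLU and max
#' pooling, then a flatten, one fully connected hidden layer with dropout,
#' and a 2-logit decision layer. The default desk-scale architecture is 4
#' blocks of 3^3 kernels (padding 1) with 8/16/32/64 filters and 2^3 pools
#' of stride 2 on a 24 x 28 x 24 input; the full-scale 91 x 109 x 91 input
#' is supported by the same code.
#'
#' @param input_dims Integer 3-vector of input volume dimensions.
#' @param n_filters Filters per conv block.
#' @param kernel_size Cubic kernel edge (per block, recycled).
#' @param padding Zero padding per side (per block, recycled).
#' @param pool_size,pool_stride Max-pooling kernel edge and stride.
#' @param fc_units Width of the hidden decision layer.
#' @param dropout_rate Dropout probability on the hidden layer, in `[0, 1)`.
#' @return An object of class `cnn_architecture` with per-block geometry.
#' @export
cnn_architecture <- function(input_dims = c(24, 28, 24),
                             n_filters = c(8, 16, 32, 64),
                             kernel_size = 3, padding = 1,
                             pool_size = 2, pool_stride = 2,
                             fc_units = 64, dropout_rate = 0.5) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("dropout_rate must be in [0, 1)")
  nb <- length(n_filters)
  kernel_size <- rep_len(kernel_size, nb)
  padding <- rep_len(padding, nb)
  pool_size <- rep_len(pool_size, nb)
  pool_stride <- rep_len(pool_stride, nb)
  dims <- as.integer(input_dims)
  blocks <- vector("list", nb)
  in_ch <- 1L
  for (b in seq_len(nb)) {
    conv_out <- dims + 2L * padding[b] - kernel_size[b] + 1L
    if (any(conv_out < 1))
      stopf("conv block %d underflows the volume (dims %s)", b,
            paste(dims, collapse = "x"))
    pool_out <- (conv_out - pool_size[b]) %/% pool_stride[b] + 1L
    if (any(pool_out < 1))
      stopf("pool in block %d underflows the volume (dims %s)", b,
            paste(conv_out, collapse = "x"))
    blocks[[b]] <- list(kernel = kernel_size[b], pad = padding[b],
                        in_ch = in_ch, filters = n_filters[b],
                        pool = pool_size[b], stride = pool_stride[b],
                        in_dims = dims, conv_dims = conv_out,
                        out_dims = pool_out)
    dims <- pool_out
    in_ch <- as.integer(n_filters[b])
  }
  structure(list(input_dims = as.integer(input_dims), blocks = blocks,
                 fc_units = as.integer(fc_units),
                 dropout_rate = dropout_rate,
                 flat_dim = prod(dims) * in_ch),
            class = "cnn_architecture")
}

# linear index helpers for im2col geometry (all 1-based, column-major)
conv_geometry <- function(block) {
  d <- block$in_dims; p <- block$pad; k <- block$kernel
  dp <- d + 2L * p
  o <- block$conv_dims
  og <- expand.grid(x = seq_len(o[1]), y = seq_len(o[2]), z = seq_len(o[3]))
  base <- og$x + dp[1] * (og$y - 1L) + dp[1] * dp[2] * (og$z - 1L)
  off <- expand.grid(a = 0:(k - 1), b = 0:(k - 1), c = 0:(k - 1))
  offsets <- off$a + dp[1] * off$b + dp[1] * dp[2] * off$c
  M <- outer(base, offsets, `+`)
  # positions of the original voxels inside the padded grid
  ig <- expand.grid(x = seq_len(d[1]) + p, y = seq_len(d[2]) + p,
                    z = seq_len(d[3]) + p)
  pad_index <- ig$x + dp[1] * (ig$y - 1L) + dp[1] * dp[2] * (ig$z - 1L)
  # pooling windows (non-overlapping when stride == pool)
  q <- block$pool; s <- block$stride; m <- block$out_dims
  mg <- expand.grid(x = seq_len(m[1]), y = seq_len(m[2]), z = seq_len(m[3]))
  pbase <- (mg$x - 1L) * s + 1L +
    o[1] * ((mg$y - 1L) * s) + o[1] * o[2] * ((mg$z - 1L) * s)
  poff <- expand.grid(a = 0:(q - 1), b = 0:(q - 1), c = 0:(q - 1))
  poffsets <- poff$a + o[1] * poff$b + o[1] * o[2] * poff$c
  PM <- outer(pbase, poffsets, `+`)
  list(M = M, pad_index = pad_index, n_padded = prod(dp), PM = PM,
       n_conv = prod(o), n_out = prod(m))
}

#' Build a 3D CNN model
#'
#' Initializes He-scaled weights under a fixed seed and precomputes the
#' convolution/pooling index geometry.
#'
#' @param arch A [cnn_architecture()].
#' @param seed RNG seed for the initialization.
#' @return An object of class `cnn_model`; `n_parameters` holds the total
#'   parameter count.
#' @export
build_cnn <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "cnn_architecture"))
  with_seed(seed, {
    conv <- lapply(arch$blocks, function(bl) {
      fan_in <- bl$kernel^3 * bl$in_ch
      list(W = matrix(stats::rnorm(fan_in * bl$filters, sd = sqrt(2 / fan_in)),
                      fan_in, bl$filters),
           b = rep(0, bl$filters))
    })
    fc1 <- list(W = matrix(stats::rnorm(arch$flat_dim * arch$fc_units,
                                        sd = sqrt(2 / arch$flat_dim)),
                           arch$flat_dim, arch$fc_units),
                b = rep(0, arch$fc_units))
    fc2 <- list(W = matrix(stats::rnorm(arch$fc_units * 2,
                                        sd = sqrt(2 / arch$fc_units)),
                           arch$fc_units, 2),
                b = rep(0, 2))
    params <- list(conv = conv, fc1 = fc1, fc2 = fc2)
    n_par <- sum(vapply(conv, function(l) length(l$W) + length(l$b), 0)) +
      length(fc1$W) + length(fc1$b) + length(fc2$W) + length(fc2$b)
    structure(list(arch = arch, params = params,
                   geom = lapply(arch$blocks, conv_geometry),
                   n_parameters = n_par),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d conv blocks, input %s, %d parameters\n",
              length(x$arch$blocks),
              paste(x$arch$input_dims, collapse = "x"), x$n_parameters))
  invisible(x)
}

# forward pass for one sample; returns logits and (optionally) the cache
# needed for backprop. x: 3D array; dropout_mask: NULL or fc_units vector.
cnn_forward <- function(model, x, keep_cache = FALSE, dropout_mask = NULL) {
  a <- matrix(as.vector(x), ncol = 1)            # (voxels x channels)
  caches <- if (keep_cache) vector("list", length(model$arch$blocks))
  for (b in seq_along(model$arch$blocks)) {
    g <- model$geom[[b]]
    bl <- model$arch$blocks[[b]]
    P <- matrix(0, g$n_padded, bl$in_ch)
    P[g$pad_index, ] <- a
    A <- array(P[as.vector(g$M), , drop = FALSE],
               c(g$n_conv, bl$kernel^3, bl$in_ch))
    dim(A) <- c(g$n_conv, bl$kernel^3 * bl$in_ch)
    Z <- sweep(A %*% model$params$conv[[b]]$W, 2,
               model$params$conv[[b]]$b, `+`)
    R <- pmax(Z, 0)
    q3 <- ncol(g$PM)
    mx <- R[g$PM[, 1], , drop = FALSE]
    am <- matrix(1L, g$n_out, bl$filters)
    if (q3 > 1) for (t in 2:q3) {
      cand <- R[g$PM[, t], , drop = FALSE]
      better <- cand > mx
      mx[better] <- cand[better]
      am[better] <- t
    }
    if (keep_cache) caches[[b]] <- list(patches = A, Z = Z, argmax = am)
    a <- mx
  }
  flat <- as.vector(a)
  pre1 <- as.vector(crossprod(model$params$fc1$W, flat)) + model$params$fc1$b
  h <- pmax(pre1, 0)
  hd <- if (is.null(dropout_mask)) h else h * dropout_mask
  logits <- as.vector(crossprod(model$params$fc2$W, hd)) + model$params$fc2$b
  if (!keep_cache) return(list(logits = logits))
  list(logits = logits, caches = caches, flat = flat, pre1 = pre1, hd = hd)
}

softmax2 <- function(z) { e <- exp(z - max(z)); e / sum(e) }

# zeroed gradient container matching model params
zero_grads <- function(model) {
  rapply(model$params, function(x) x * 0, how = "replace")
}

# accumulate gradients for one sample into `grads` (modified copy returned)
cnn_backward <- function(model, fwd, y, grads, dropout_mask = NULL) {
  p <- softmax2(fwd$logits)
  dlog <- p
  dlog[y + 1L] <- dlog[y + 1L] - 1
  grads$fc2$W <- grads$fc2$W + outer(fwd$hd, dlog)
  grads$fc2$b <- grads$fc2$b + dlog
  dh <- as.vector(model$params$fc2$W %*% dlog)
  if (!is.null(dropout_mask)) dh <- dh * dropout_mask
  dpre1 <- dh * (fwd$pre1 > 0)
  grads$fc1$W <- grads$fc1$W + outer(fwd$flat, dpre1)
  grads$fc1$b <- grads$fc1$b + dpre1
  da <- as.vector(model$params$fc1$W %*% dpre1)
  nb <- length(model$arch$blocks)
  last_bl <- model$arch$blocks[[nb]]
  da <- matrix(da, model$geom[[nb]]$n_out, last_bl$filters)
  for (b in rev(seq_len(nb))) {
    g <- model$geom[[b]]
    bl <- model$arch$blocks[[b]]
    cache <- fwd$caches[[b]]
    dR <- matrix(0, g$n_conv, bl$filters)
    for (t in seq_len(ncol(g$PM))) {
      sel <- cache$argmax == t
      if (any(sel)) {
        contrib <- da
        contrib[!sel] <- 0
        dR[g$PM[, t], ] <- dR[g$PM[, t], ] + contrib
      }
    }
    dZ <- dR * (cache$Z > 0)
    grads$conv[[b]]$W <- grads$conv[[b]]$W + crossprod(cache$patches, dZ)
    grads$conv[[b]]$b <- grads$conv[[b]]$b + colSums(dZ)
    if (b > 1) {
      dPatch <- dZ %*% t(model$params$conv[[b]]$W)
      dim(dPatch) <- c(g$n_conv, bl$kernel^3, bl$in_ch)
      dPadded <- matrix(0, g$n_padded, bl$in_ch)
      for (t in seq_len(bl$kernel^3))
        dPadded[g$M[, t], ] <- dPadded[g$M[, t], ] +
          dPatch[, t, , drop = TRUE]
      da <- dPadded[g$pad_index, , drop = FALSE]
    }
  }
  grads
}

#' Mean cross-entropy loss and gradients over a batch
#'
#' @param model A [build_cnn()] model.
#' @param xs List of 3D input arrays.
#' @param ys Integer 0/1 labels.
#' @param training If `TRUE`, sample a dropout mask per instance.
#' @return A list with `loss` and `grads` (same shape as the parameters).
#' @export
cnn_loss_grad <- function(model, xs, ys, training = TRUE) {
  grads <- zero_grads(model)
  loss <- 0
  rate <- model$arch$dropout_rate
  for (i in seq_along(xs)) {
    mask <- if (training && rate > 0)
      stats::rbinom(model$arch$fc_units, 1, 1 - rate) / (1 - rate) else NULL
    fwd <- cnn_forward(model, xs[[i]], keep_cache = TRUE,
                       dropout_mask = mask)
    p <- softmax2(fwd$logits)
    loss <- loss - log(max(p[ys[i] + 1L], 1e-12))
    grads <- cnn_backward(model, fwd, ys[i], grads, dropout_mask = mask)
  }
  n <- length(xs)
  list(loss = loss / n,
       grads = rapply(grads, function(x) x / n, how = "replace"))
}

#' Predict with a 3D CNN
#'
#' @param model A [build_cnn()] model.
#' @param xs List of 3D input arrays (or a single array).
#' @param type `"label"`, `"prob"` (P(class 1)) or `"logits"`.
#' @return Vector (or 2-column matrix for logits) of predictions.
#' @export
cnn_predict <- function(model, xs, type = c("label", "prob", "logits")) {
  type <- match.arg(type)
  if (is.array(xs) && length(dim(xs)) == 3) xs <- list(xs)
  out <- t(vapply(xs, function(x) cnn_forward(model, x)$logits, numeric(2)))
  if (type == "logits") return(out)
  p <- apply(out, 1, function(z) softmax2(z)[2])
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Mean cross-entropy of a model on labelled volumes
#'
#' @inheritParams cnn_predict
#' @param ys Integer 0/1 labels.
#' @return Scalar mean cross-entropy (dropout disabled).
#' @export
cnn_eval_loss <- function(model, xs, ys) {
  loss <- 0
  for (i in seq_along(xs)) {
    p <- softmax2(cnn_forward(model, xs[[i]])$logits)
    loss <- loss - log(max(p[ys[i] + 1L], 1e-12))
  }
  loss / length(xs)
}

# checksum of all parameters: (sum, sum of squares)
param_checksum <- function(model) {
  v <- unlist(model$params, use.names = FALSE)
  c(sum(v), sum(v^2))
}
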