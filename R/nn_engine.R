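# Internal minibatch CNN engine.
#
# Tensors travel as R arrays with dim (N, H, W, C); convolutions are "same"
# padded, stride 1, realized as im2col + GEMM (see src/conv_ops.cpp).  All
# parameters live in per-layer environments so updates are in place.  The
# engine is deliberately small: conv/pool/dense/embedding layers, ReLU,
# sigmoid or softmax heads, Adam with L2 weight decay, fixed-seed
# initialization and shuffling.  Single-threaded and deterministic given the
# BLAS in use.

# Identity-preserving (Dirac) initialization: filter j starts as a signed
# center-tap pass-through of input channel j %% cin (sign alternates with
# j %/% cin), plus small symmetry-breaking noise.  Stacked with ReLU, the
# +/- pairs carry the input linearly through the whole branch, so training
# starts from a linear view of the image and only departs from it when the
# gradients ask for nonlinearity.  Pixel positions are gene identities, so
# this is the natural prior for expression images.
nn_conv_layer <- function(kh, kw, cin, f) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"
  l$kh <- kh; l$kw <- kw; l$cin <- cin; l$f <- f
  fan_in <- kh * kw * cin
  w <- matrix(stats::rnorm(fan_in * f, sd = 0.02 / sqrt(fan_in)), fan_in, f)
  center <- (kh %/% 2) + kh * (kw %/% 2)
  for (j in seq_len(f) - 1L) {
    src <- j %% cin
    sgn <- if ((j %/% cin) %% 2L == 0L) 1 else -1
    w[center + kh * kw * src + 1L, j + 1L] <- sgn
  }
  l$W <- w
  l$b <- numeric(f)
  l
}

nn_pool_layer <- function(ph, pw, kind = "max") {
  l <- new.env(parent = emptyenv())
  l$type <- "pool"; l$ph <- ph; l$pw <- pw; l$kind <- kind
  l
}

nn_dense_layer <- function(din, dout, act = "relu") {
  l <- new.env(parent = emptyenv())
  l$type <- "dense"; l$act <- act
  l$W <- matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout)
  l$b <- numeric(dout)
  l
}

nn_embed_layer <- function(vocab, dim) {
  l <- new.env(parent = emptyenv())
  l$type <- "embed"; l$vocab <- vocab; l$dim <- dim
  l$W <- matrix(stats::rnorm(vocab * dim, sd = 0.05), vocab, dim)
  l
}

nn_forward_conv <- function(l, x, training) {
  d <- dim(x)
  P <- im2col_nhwc(x, d[1L], d[2L], d[3L], d[4L], l$kh, l$kw)
  y <- P %*% l$W
  y <- y + rep(l$b, each = nrow(y))
  y[y < 0] <- 0  # ReLU
  dim(y) <- c(d[1L], d[2L], d[3L], l$f)
  if (training) { l$P <- P; l$in_dim <- d; l$out <- y }
  y
}

nn_backward_conv <- function(l, gy) {
  gy <- gy * (l$out > 0)
  d <- l$in_dim
  gym <- gy; dim(gym) <- c(prod(d[1:3]), l$f)
  l$gW <- crossprod(l$P, gym)
  l$gb <- colSums(gym)
  gP <- tcrossprod(gym, l$W)
  gx <- col2im_nhwc(gP, d[1L], d[2L], d[3L], d[4L], l$kh, l$kw)
  dim(gx) <- d
  l$P <- NULL; l$out <- NULL
  gx
}

nn_forward_pool <- function(l, x, training) {
  d <- dim(x)
  if (d[2L] %% l$ph != 0L || d[3L] %% l$pw != 0L)
    stop("pooling window does not divide the spatial dimensions (",
         d[2L], "x", d[3L], " by ", l$ph, "x", l$pw, ")")
  ho <- d[2L] %/% l$ph; wo <- d[3L] %/% l$pw
  if (l$kind == "avg") {
    dim(x) <- c(d[1L], l$ph, ho, l$pw, wo, d[4L])
    xp <- aperm(x, c(2L, 4L, 1L, 3L, 5L, 6L))
    dim(xp) <- c(l$ph * l$pw, d[1L] * ho * wo * d[4L])
    y <- colMeans(xp)
    dim(y) <- c(d[1L], ho, wo, d[4L])
    if (training) l$in_dim <- d
    return(y)
  }
  res <- maxpool_nhwc(x, d[1L], d[2L], d[3L], d[4L], l$ph, l$pw)
  y <- res$y
  dim(y) <- c(d[1L], ho, wo, d[4L])
  if (training) { l$idx <- res$idx; l$in_dim <- d }
  y
}

nn_backward_pool <- function(l, gy) {
  d <- l$in_dim
  if (l$kind == "avg") {
    k <- l$ph * l$pw
    gxp <- matrix(rep(as.vector(gy) / k, each = k), nrow = k)
    ho <- d[2L] %/% l$ph; wo <- d[3L] %/% l$pw
    dim(gxp) <- c(l$ph, l$pw, d[1L], ho, wo, d[4L])
    gx <- aperm(gxp, c(3L, 1L, 4L, 2L, 5L, 6L))
    dim(gx) <- d
    return(gx)
  }
  gx <- numeric(prod(d))
  gx[l$idx] <- gy
  dim(gx) <- d
  l$idx <- NULL
  gx
}

nn_forward_dense <- function(l, x, training) {
  y <- x %*% l$W
  y <- y + rep(l$b, each = nrow(y))
  if (l$act == "relu") y[y < 0] <- 0
  if (training) { l$X <- x; l$out <- y }
  y
}

nn_backward_dense <- function(l, gy) {
  if (l$act == "relu") gy <- gy * (l$out > 0)
  l$gW <- crossprod(l$X, gy)
  l$gb <- colSums(gy)
  gx <- tcrossprod(gy, l$W)
  l$X <- NULL; l$out <- NULL
  gx
}

# counts: N x vocab row-normalized histograms; output N x dim.
nn_forward_embed <- function(l, counts, training) {
  if (training) l$X <- counts
  counts %*% l$W
}

nn_backward_embed <- function(l, gy) {
  l$gW <- crossprod(l$X, gy)
  l$gb <- NULL
  l$X <- NULL
  invisible(NULL)
}

# Full forward pass; returns logits (N x 1 binary, N x K multiclass).
nn_forward <- function(model, x, counts, training = FALSE) {
  a <- x / 255 - 0.5   # center intensities for conditioning
  for (l in model$stack) {
    a <- if (l$type == "conv") nn_forward_conv(l, a, training)
         else nn_forward_pool(l, a, training)
  }
  n <- dim(a)[1L]
  h <- a
  dim(h) <- c(n, length(a) %/% n)
  if (!is.null(model$embed))
    h <- cbind(h, nn_forward_embed(model$embed, counts, training))
  for (l in model$dense) h <- nn_forward_dense(l, h, training)
  h
}

nn_backward <- function(model, glogits) {
  g <- glogits
  for (l in rev(model$dense)) g <- nn_backward_dense(l, g)
  if (!is.null(model$embed)) {
    ed <- model$embed$dim
    nf <- ncol(g) - ed
    nn_backward_embed(model$embed, g[, nf + seq_len(ed), drop = FALSE])
    g <- g[, seq_len(nf), drop = FALSE]
  }
  dim(g) <- c(nrow(g), model$conv_out_dim)
  for (l in rev(model$stack)) {
    g <- if (l$type == "conv") nn_backward_conv(l, g)
         else nn_backward_pool(l, g)
  }
  invisible(NULL)
}

nn_param_layers <- function(model) {
  c(Filter(function(l) l$type == "conv", model$stack),
    if (!is.null(model$embed)) list(model$embed),
    model$dense)
}

nn_adam_init <- function(model) {
  for (l in nn_param_layers(model)) {
    l$mW <- l$W * 0; l$vW <- l$W * 0
    if (!is.null(l$b)) { l$mb <- l$b * 0; l$vb <- l$b * 0 }
  }
  model$t <- 0L
  invisible(model)
}

# Adam with decoupled weight decay: the L2 term shrinks weights directly
# rather than passing through the adaptive normalizer.
nn_adam_step <- function(model, lr, beta1, beta2, eps, l2) {
  model$t <- model$t + 1L
  c1 <- 1 - beta1^model$t
  c2 <- 1 - beta2^model$t
  for (l in nn_param_layers(model)) {
    gW <- l$gW
    l$mW <- beta1 * l$mW + (1 - beta1) * gW
    l$vW <- beta2 * l$vW + (1 - beta2) * gW * gW
    l$W <- l$W - lr * (l$mW / c1) / (sqrt(l$vW / c2) + eps) -
      lr * l2 * l$W
    if (!is.null(l$b)) {
      l$mb <- beta1 * l$mb + (1 - beta1) * l$gb
      l$vb <- beta2 * l$vb + (1 - beta2) * l$gb * l$gb
      l$b <- l$b - lr * (l$mb / c1) / (sqrt(l$vb / c2) + eps)
    }
    l$gW <- NULL; l$gb <- NULL
  }
  invisible(model)
}

# Loss + logits gradient for one minibatch.
nn_loss_grad <- function(logits, y, n_classes) {
  n <- nrow(logits)
  if (n_classes == 2L) {
    p <- stats::plogis(logits[, 1L])
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
    g <- matrix((p - y) / n, ncol = 1L)
  } else {
    z <- logits - apply(logits, 1L, max)
    ez <- exp(z)
    p <- ez / rowSums(ez)
    iy <- cbind(seq_len(n), y + 1L)
    loss <- -mean(log(pmax(p[iy], 1e-12)))
    g <- p
    g[iy] <- g[iy] - 1
    g <- g / n
  }
  list(loss = loss, grad = g)
}

nn_probs <- function(logits, n_classes) {
  if (n_classes == 2L) {
    stats::plogis(logits[, 1L])
  } else {
    z <- logits - apply(logits, 1L, max)
    ez <- exp(z)
    ez / rowSums(ez)
  }
}
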