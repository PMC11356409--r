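# Differentiable operations. Every op_* accepts plain numerics or tracked
# nodes (any mix); with no tracked argument it computes eagerly and returns a
# plain numeric. Network tensors are (w*h) x channels matrices whose row
# index is k + h*j for spatial position (j, k) — i.e. an h x w image plane
# flattened column-major, one column per channel.

op2 <- function(x, y, value, bx, by) {
  if (!is_ad(x) && !is_ad(y)) return(value)
  ad_record(ad_tape_of(x, y), value, list(x, y), function(g) {
    list(if (is_ad(x)) bx(g) else NULL, if (is_ad(y)) by(g) else NULL)
  })
}

op1 <- function(x, value, bx) {
  if (!is_ad(x)) return(value)
  ad_record(x$tape, value, list(x), function(g) list(bx(g)))
}

op_add <- function(x, y) {
  xv <- ad_value(x); yv <- ad_value(y)
  op2(x, y, xv + yv,
      function(g) if (length(xv) == 1L && length(yv) > 1L) sum(g) else g,
      function(g) if (length(yv) == 1L && length(xv) > 1L) sum(g) else g)
}

op_sub <- function(x, y) {
  xv <- ad_value(x); yv <- ad_value(y)
  op2(x, y, xv - yv,
      function(g) if (length(xv) == 1L && length(yv) > 1L) sum(g) else g,
      function(g) if (length(yv) == 1L && length(xv) > 1L) -sum(g) else -g)
}

# elementwise product; either side may be a scalar
op_mul <- function(x, y) {
  xv <- ad_value(x); yv <- ad_value(y)
  op2(x, y, xv * yv,
      function(g) if (length(xv) == 1L && length(yv) > 1L) sum(g * yv) else g * yv,
      function(g) if (length(yv) == 1L && length(xv) > 1L) sum(g * xv) else g * xv)
}

# scalar division (used for loss ratios)
op_div <- function(x, y) {
  xv <- ad_value(x); yv <- ad_value(y)
  op2(x, y, xv / yv,
      function(g) g / yv,
      function(g) -g * xv / (yv * yv))
}

# column-recycled product: each column of x times a length-nrow(x) gate
op_colmul <- function(x, gate) {
  xv <- ad_value(x); gv <- as.vector(ad_value(gate))
  op2(x, gate, xv * gv,
      function(g) g * gv,
      function(g) {
        r <- rowSums(g * xv)
        dim(r) <- dim(ad_value(gate))
        r
      })
}

op_matmul <- function(x, y) {
  xv <- ad_value(x); yv <- ad_value(y)
  op2(x, y, xv %*% yv,
      function(g) tcrossprod(g, yv),
      function(g) crossprod(xv, g))
}

# x %*% t(y)
op_tcrossprod <- function(x, y) {
  xv <- ad_value(x); yv <- ad_value(y)
  op2(x, y, tcrossprod(xv, yv),
      function(g) g %*% yv,
      function(g) crossprod(g, xv))
}

# t(x) %*% y
op_crossprod <- function(x, y) {
  xv <- ad_value(x); yv <- ad_value(y)
  op2(x, y, crossprod(xv, yv),
      function(g) yv %*% t(g),
      function(g) xv %*% g)
}

# add a per-channel bias vector to an n x c matrix
op_bias <- function(x, b) {
  xv <- ad_value(x); bv <- ad_value(b)
  op2(x, b, sweep(xv, 2L, bv, "+"),
      function(g) g,
      function(g) colSums(g))
}

op_relu <- function(x) {
  xv <- ad_value(x)
  v <- xv * (xv > 0)
  op1(x, v, function(g) g * (xv > 0))
}

op_sigmoid <- function(x) {
  v <- stats::plogis(ad_value(x))
  op1(x, v, function(g) g * v * (1 - v))
}

op_softmax_rows <- function(x) {
  xv <- ad_value(x)
  v <- softmax_rows_cpp(xv)
  op1(x, v, function(g) softmax_rows_bwd_cpp(v, g))
}

# Fused scaled-dot-product attention: A = softmax(scale * Q K^T) row-wise,
# O = A V. One node instead of four keeps the n x n intermediates to the
# minimum (matters at the finest decoder level where n = w*h is large).
op_attention <- function(Q, K, V, scale) {
  Qv <- ad_value(Q); Kv <- ad_value(K); Vv <- ad_value(V)
  A <- softmax_rows_cpp(tcrossprod(Qv * scale, Kv))
  O <- A %*% Vv
  if (!is_ad(Q) && !is_ad(K) && !is_ad(V)) {
    attr(O, "A") <- A
    return(O)
  }
  ad_record(ad_tape_of(Q, K, V), O, list(Q, K, V), function(g) {
    dA <- tcrossprod(g, Vv)
    dS <- softmax_rows_bwd_cpp(A, dA)
    list(if (is_ad(Q)) (dS %*% Kv) * scale else NULL,
         if (is_ad(K)) crossprod(dS, Qv) * scale else NULL,
         if (is_ad(V)) crossprod(A, g) else NULL)
  })
}

op_sum <- function(x) {
  xv <- ad_value(x)
  op1(x, sum(xv), function(g) array(g, dim = dim2(xv)))
}

op_mean <- function(x) {
  xv <- ad_value(x); n <- length(xv)
  op1(x, sum(xv) / n, function(g) array(g / n, dim = dim2(xv)))
}

# mean squared difference to a constant target (autoencoder objective)
op_mse <- function(x, target) {
  xv <- ad_value(x); n <- length(xv)
  d <- xv - target
  op1(x, sum(d * d) / n, function(g) (2 * g / n) * d)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- convolution -----------------------------------------------------------

# Cached index maps for im2col on the (k + h*j) position layout. Index 1 of
# the augmented input (a prepended zero row) stands for padding.
.sats_cache <- new.env(parent = emptyenv())

conv_meta <- function(h, w, kh, kw, stride, pad) {
  key <- paste("cv", h, w, kh, kw, stride, pad, sep = "_")
  m <- .sats_cache[[key]]
  if (!is.null(m)) return(m)
  ho <- (h + 2L * pad - kh) %/% stride + 1L
  wo <- (w + 2L * pad - kw) %/% stride + 1L
  oy <- rep(seq_len(ho) - 1L, times = wo) * stride - pad
  ox <- rep(seq_len(wo) - 1L, each = ho) * stride - pad
  K <- kh * kw
  idx <- matrix(1L, ho * wo, K)
  o <- 0L
  for (dx in 0:(kw - 1L)) for (dy in 0:(kh - 1L)) {
    o <- o + 1L
    yy <- oy + dy; xx <- ox + dx
    ok <- yy >= 0L & yy < h & xx >= 0L & xx < w
    idx[ok, o] <- yy[ok] + h * xx[ok] + 2L
  }
  m <- list(idx = idx, K = K, ho = ho, wo = wo, n_in = h * w)
  .sats_cache[[key]] <- m
  m
}

im2col <- function(X, cm) {
  cin <- ncol(X)
  Xa <- rbind(0, X)
  cols <- Xa[as.vector(cm$idx), , drop = FALSE]
  dim(cols) <- c(nrow(cm$idx), cm$K * cin)
  cols
}

col2im <- function(dcols, cm, cin) {
  dX <- matrix(0, cm$n_in + 1L, cin)
  K <- cm$K
  for (o in seq_len(K)) {
    block <- dcols[, o + K * (seq_len(cin) - 1L), drop = FALSE]
    rs <- rowsum(block, cm$idx[, o])
    rows <- as.integer(rownames(rs))
    dX[rows, ] <- dX[rows, ] + rs
  }
  dX[-1L, , drop = FALSE]
}

# 2-D convolution on the flattened layout. W is (kh*kw*cin) x cout with row
# order: kernel offset fastest within each input channel. b is length cout,
# or NULL for a bias-free convolution (used before normalization layers,
# where a bias would receive no gradient).
op_conv <- function(x, W, b, h, w, kh = 3L, kw = 3L, stride = 1L, pad = 1L) {
  cm <- conv_meta(h, w, kh, kw, stride, pad)
  xv <- ad_value(x); Wv <- ad_value(W)
  cin <- ncol(xv)
  cols <- im2col(xv, cm)
  v <- cols %*% Wv
  if (!is.null(b)) v <- sweep(v, 2L, ad_value(b), "+")
  if (!is_ad(x) && !is_ad(W) && !is_ad(b)) return(v)
  ad_record(ad_tape_of(x, W, b), v, list(x, W, b), function(g) {
    list(
      if (is_ad(x)) col2im(tcrossprod(g, Wv), cm, cin) else NULL,
      if (is_ad(W)) crossprod(cols, g) else NULL,
      if (is_ad(b)) colSums(g) else NULL)
  })
}

# ---- normalization ---------------------------------------------------------

# Instance normalization: each channel of one sample standardized over its
# spatial positions, then affinely transformed. Identical in training and
# inference, so forward passes are deterministic regardless of batching.
op_instnorm <- function(x, gain, bias, eps = 1e-5) {
  xv <- ad_value(x)
  n <- nrow(xv)
  mu <- colMeans(xv)
  xc <- sweep(xv, 2L, mu, "-")
  va <- colSums(xc * xc) / n
  isd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, isd, "*")
  gv <- ad_value(gain); bv <- ad_value(bias)
  v <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  if (!is_ad(x) && !is_ad(gain) && !is_ad(bias)) return(v)
  ad_record(ad_tape_of(x, gain, bias), v, list(x, gain, bias), function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(sweep(dxhat, 2L, m1, "-") - sweep(xhat, 2L, m2, "*"),
                2L, isd, "*")
    list(if (is_ad(x)) dx else NULL,
         if (is_ad(gain)) colSums(g * xhat) else NULL,
         if (is_ad(bias)) colSums(g) else NULL)
  })
}

# ---- resampling ------------------------------------------------------------

# Bilinear x2 upsampling (half-pixel centers, coordinates clamped). The map
# is a fixed sparse linear operator: four gathers with convex weights, so
# values stay inside the input range.
upsample2_meta <- function(h, w) {
  key <- paste("up2", h, w, sep = "_")
  m <- .sats_cache[[key]]
  if (!is.null(m)) return(m)
  m <- resize_meta(h, w, 2L * h, 2L * w)
  .sats_cache[[key]] <- m
  m
}

resize_meta <- function(h, w, ho, wo) {
  yi <- pmin(pmax((seq_len(ho) - 0.5) * h / ho - 0.5, 0), h - 1)
  xi <- pmin(pmax((seq_len(wo) - 0.5) * w / wo - 0.5, 0), w - 1)
  y0 <- floor(yi); x0 <- floor(xi)
  fy <- yi - y0; fx <- xi - x0
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  Y0 <- rep(y0, times = wo); Y1 <- rep(y1, times = wo)
  FY <- rep(fy, times = wo)
  X0 <- rep(x0, each = ho); X1 <- rep(x1, each = ho)
  FX <- rep(fx, each = ho)
  list(
    i = cbind(Y0 + h * X0, Y1 + h * X0, Y0 + h * X1, Y1 + h * X1) + 1L,
    wt = cbind((1 - FY) * (1 - FX), FY * (1 - FX), (1 - FY) * FX, FY * FX),
    n_in = h * w, ho = ho, wo = wo)
}

resize_apply <- function(X, rm) {
  X[rm$i[, 1L], , drop = FALSE] * rm$wt[, 1L] +
    X[rm$i[, 2L], , drop = FALSE] * rm$wt[, 2L] +
    X[rm$i[, 3L], , drop = FALSE] * rm$wt[, 3L] +
    X[rm$i[, 4L], , drop = FALSE] * rm$wt[, 4L]
}

op_upsample2 <- function(x, h, w) {
  rm <- upsample2_meta(h, w)
  xv <- ad_value(x)
  v <- resize_apply(xv, rm)
  op1(x, v, function(g) {
    dX <- matrix(0, rm$n_in, ncol(xv))
    for (q in 1:4) {
      rs <- rowsum(g * rm$wt[, q], rm$i[, q])
      rows <- as.integer(rownames(rs))
      dX[rows, ] <- dX[rows, ] + rs
    }
    dX
  })
}

# plain-numeric bilinear resize of an h x w matrix to ho x wo
bilinear_resize <- function(m, ho, wo) {
  h <- nrow(m); w <- ncol(m)
  rm <- resize_meta(h, w, ho, wo)
  out <- resize_apply(matrix(as.vector(m), ncol = 1L), rm)
  matrix(out, ho, wo)
}
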