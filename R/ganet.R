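# Granular Attention Network (GANet): a residual convolutional encoder, an
# identify transformer block (channel + spatial self-attention producing an
# initial coarse mask), and refine transformer blocks (overall, foreground
# and background attention correcting the previous level's features),
# yielding a pyramid of soft masks supervised at every level.
#
# Public functions take channel-first c x w x h feature arrays and H x W x 3
# images; internally tensors are (w*h) x c matrices (see ad-ops.R).

# ---- layout conversions ----------------------------------------------------

fm_to_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(3L, 2L, 1L)), d[2L] * d[3L], d[1L])
}

mat_to_fm <- function(m, w, h) {
  aperm(array(m, dim = c(h, w, ncol(m))), c(3L, 2L, 1L))
}

img_to_mat <- function(img) {
  d <- dim(img)
  matrix(img, d[1L] * d[2L], d[3L])
}

#' Flatten a channel-first feature map to a 2-D matrix
#'
#' Reshapes a `c x w x h` array into a `c x (w*h)` matrix with
#' `out[i, j*h + k] = x[i, j, k]` (zero-based indices), the layout used by
#' the spatial attention module. [spatial_unflatten()] is its exact inverse.
#'
#' @param x a `c x w x h` numeric array.
#' @return a `c x (w*h)` matrix.
#' @export
spatial_flatten <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  t(fm_to_mat(x))
}

#' Restore a flattened feature matrix to channel-first 3-D form
#'
#' @param m a `c x (w*h)` matrix as produced by [spatial_flatten()].
#' @param w,h spatial width and height of the target feature map.
#' @return a `c x w x h` array.
#' @export
spatial_unflatten <- function(m, w, h) {
  stopifnot(length(dim(m)) == 2L)
  if (ncol(m) != w * h) {
    stop("cannot unflatten: ", ncol(m), " columns but w*h = ", w * h)
  }
  mat_to_fm(t(m), w, h)
}

# ---- configuration ---------------------------------------------------------

#' GANet architecture configuration
#'
#' @param D number of encoder levels (ResBlocks); the decoder has one
#'   identify block plus `D - 1` refine blocks, all supervised.
#' @param base_channels channel width of the finest encoder level; width
#'   doubles per level.
#' @param gamma1,gamma2 initial values of the learnable scalars weighting the
#'   foreground / background attention corrections.
#' @param sigmoid_on_predictions apply a sigmoid to every predicted mask (the
#'   masks then gate features and enter the loss as values in `[0, 1]`).
#' @return an object of class `ganet_config`.
#' @export
ganet_config <- function(D = 4L, base_channels = 8L, gamma1 = 1, gamma2 = 1,
                         sigmoid_on_predictions = TRUE) {
  stopifnot(D >= 2L, base_channels >= 4L)
  structure(list(D = as.integer(D), base_channels = as.integer(base_channels),
                 gamma1 = gamma1, gamma2 = gamma2,
                 sigmoid_on_predictions = isTRUE(sigmoid_on_predictions)),
            class = "ganet_config")
}

ganet_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$D) - 1L)

# ---- parameter initialization ---------------------------------------------

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

init_attn <- function(c_in, prefix, P) {
  sd <- sqrt(1 / c_in)
  for (nm in c("Wq", "Wk", "Wv")) P[[paste0(prefix, ".", nm)]] <- rmat(c_in, c_in, sd)
  P
}

#' Initialize GANet parameters
#'
#' He-style random initialization for convolutions, `1/sqrt(c)`-scaled
#' initialization for attention projections, unit instance-norm gains, and
#' the configured initial values for the learnable gamma scalars.
#'
#' @param cfg a [ganet_config()].
#' @param in_channels number of input image channels.
#' @param seed integer seed; initialization is a pure function of
#'   `(cfg, in_channels, seed)`.
#' @return a flat named list of parameter arrays.
#' @export
ganet_init <- function(cfg, in_channels = 3L, seed = 0L) {
  ch <- ganet_channels(cfg)
  P <- list()
  with_seed(seed, {
    cin <- in_channels
    for (d in seq_len(cfg$D)) {
      co <- ch[d]; pre <- paste0("enc", d)
      P[[paste0(pre, ".conv1.W")]] <- rmat(9L * cin, co, sqrt(2 / (9 * cin)))
      P[[paste0(pre, ".n1.g")]] <- rep(1, co)
      P[[paste0(pre, ".n1.b")]] <- numeric(co)
      P[[paste0(pre, ".conv2.W")]] <- rmat(9L * co, co, sqrt(2 / (9 * co)))
      P[[paste0(pre, ".n2.g")]] <- rep(1, co)
      P[[paste0(pre, ".n2.b")]] <- numeric(co)
      P[[paste0(pre, ".skip.W")]] <- rmat(cin, co, sqrt(2 / cin))
      P[[paste0(pre, ".skip.b")]] <- numeric(co)
      cin <- co
    }
    cD <- ch[cfg$D]
    P <- init_attn(cD, "ident.ch", P)
    P <- init_attn(cD, "ident.sp", P)
    P[["ident.out.W"]] <- rmat(cD, 1L, sqrt(1 / cD))
    P[["ident.out.b"]] <- 0
    for (l in seq_len(cfg$D - 1L)) {
      d <- cfg$D - 1L - l            # encoder level this block refines
      c_d <- ch[d + 1L]; c_prev <- ch[d + 2L]
      pre <- paste0("ref", l)
      P[[paste0(pre, ".align.W")]] <- rmat(c_prev, c_d, sqrt(1 / c_prev))
      P[[paste0(pre, ".align.b")]] <- numeric(c_d)
      for (br in c("all", "fg", "bg")) P <- init_attn(c_d, paste0(pre, ".", br), P)
      P[[paste0(pre, ".gamma1")]] <- cfg$gamma1
      P[[paste0(pre, ".gamma2")]] <- cfg$gamma2
      P[[paste0(pre, ".out.W")]] <- rmat(c_d, 1L, sqrt(1 / c_d))
      P[[paste0(pre, ".out.b")]] <- 0
    }
  })
  P
}

# ---- attention cores (matrix layout, numeric or tracked) -------------------

attn_spatial_core <- function(X, Wq, Wk, Wv) {
  cw <- ncol(ad_value(X))
  Q <- op_matmul(X, Wq); K <- op_matmul(X, Wk); V <- op_matmul(X, Wv)
  O <- op_attention(Q, K, V, 1 / sqrt(cw))
  list(O = O, A = attr(ad_value(O), "A"))
}

attn_channel_core <- function(X, Wq, Wk, Wv) {
  cw <- ncol(ad_value(X))
  Q <- op_matmul(X, Wq); K <- op_matmul(X, Wk); V <- op_matmul(X, Wv)
  A <- op_softmax_rows(op_mul(op_crossprod(Q, K), 1 / sqrt(cw)))
  list(O = op_tcrossprod(V, A), A = A)
}

check_attn_params <- function(params) {
  stopifnot(is.list(params), all(c("Wq", "Wk", "Wv") %in% names(params)))
}

#' Channel self-attention over a feature map
#'
#' Computes `softmax(Q K^T / sqrt(c))` over the `c x c` channel-similarity
#' matrix (row-stochastic) and reweights the value projection with it, as in
#' the identify transformer block.
#'
#' @param z a `c x w x h` feature array.
#' @param params list with `c x c` projection matrices `Wq`, `Wk`, `Wv`.
#' @return a `c x w x h` array; the attention matrix is attached as
#'   attribute `"A"`.
#' @export
channel_attention <- function(z, params) {
  check_attn_params(params)
  d <- dim(z)
  r <- attn_channel_core(fm_to_mat(z), params$Wq, params$Wk, params$Wv)
  structure(mat_to_fm(r$O, d[2L], d[3L]), A = r$A)
}

#' Spatial self-attention over a feature map
#'
#' Flattens the map, computes a `(w*h) x (w*h)` row-stochastic attention
#' matrix between spatial positions, reweights the values and restores the
#' 3-D shape.
#'
#' @inheritParams channel_attention
#' @return a `c x w x h` array with attention matrix attribute `"A"`.
#' @export
spatial_attention <- function(z, params) {
  check_attn_params(params)
  d <- dim(z)
  r <- attn_spatial_core(fm_to_mat(z), params$Wq, params$Wk, params$Wv)
  structure(mat_to_fm(r$O, d[2L], d[3L]), A = r$A)
}

#' Gated (foreground/background) spatial attention
#'
#' Multiplies the features by a soft gate in `[0, 1]` before spatial
#' self-attention. With `gate = P` this is the foreground branch of a refine
#' block; with `gate = 1 - P` the background branch.
#'
#' @inheritParams channel_attention
#' @param gate an `h x w` matrix in `[0, 1]` matching `z`'s spatial size.
#' @return a `c x w x h` array with attention matrix attribute `"A"`.
#' @export
masked_attention <- function(z, gate, params) {
  check_attn_params(params)
  d <- dim(z)
  if (!all(dim(gate) == d[c(3L, 2L)])) {
    stop("gate size ", paste(dim(gate), collapse = "x"),
         " does not match feature map h x w = ", d[3L], "x", d[2L])
  }
  gv <- as.vector(gate)   # h x w, column-major = position index j*h + k
  r <- attn_spatial_core(fm_to_mat(z) * gv, params$Wq, params$Wk, params$Wv)
  structure(mat_to_fm(r$O, d[2L], d[3L]), A = r$A)
}

# ---- encoder ---------------------------------------------------------------

res_block_core <- function(x, h, w, P, pre) {
  g <- function(s) P[[paste0(pre, ".", s)]]
  h1 <- op_conv(x, g("conv1.W"), NULL, h, w, 3L, 3L, 2L, 1L)
  h1 <- op_relu(op_instnorm(h1, g("n1.g"), g("n1.b")))
  h2 <- op_conv(h1, g("conv2.W"), NULL, h %/% 2L, w %/% 2L, 3L, 3L, 1L, 1L)
  h2 <- op_instnorm(h2, g("n2.g"), g("n2.b"))
  sk <- op_conv(x, g("skip.W"), g("skip.b"), h, w, 1L, 1L, 2L, 0L)
  op_relu(op_add(h2, sk))
}

encode_core <- function(xmat, h, w, P, cfg) {
  zs <- vector("list", cfg$D)
  cur <- xmat; ch <- h; cw <- w
  for (d in seq_len(cfg$D)) {
    cur <- res_block_core(cur, ch, cw, P, paste0("enc", d))
    ch <- ch %/% 2L; cw <- cw %/% 2L
    zs[[d]] <- list(m = cur, h = ch, w = cw)
  }
  zs
}

#' Encode an image into the GANet feature pyramid
#'
#' Applies `D` residual blocks with stride-2 downsampling; channel width
#' doubles and spatial size halves per level.
#'
#' @param image an `H x W x 3` array with values in `[0, 1]`; `H` and `W`
#'   must be divisible by `2^D`.
#' @param params parameters from [ganet_init()].
#' @param cfg the [ganet_config()] used at initialization.
#' @return a list of `D` feature arrays `c_d x w_d x h_d`, deepest last.
#' @export
encode <- function(image, params, cfg) {
  d <- dim(image)
  stopifnot(length(d) == 3L)
  div <- 2L^cfg$D
  if (d[1L] %% div != 0L || d[2L] %% div != 0L) {
    stop("image size ", d[1L], "x", d[2L], " not divisible by 2^D = ", div,
         "; pad to ", ceiling(d[1L] / div) * div, "x",
         ceiling(d[2L] / div) * div)
  }
  zs <- encode_core(img_to_mat(image), d[1L], d[2L], params, cfg)
  lapply(zs, function(z) mat_to_fm(z$m, z$w, z$h))
}

# ---- decoder blocks --------------------------------------------------------

identify_core <- function(z, P) {
  x1 <- attn_channel_core(z, P[["ident.ch.Wq"]], P[["ident.ch.Wk"]],
                          P[["ident.ch.Wv"]])$O
  x2 <- attn_spatial_core(x1, P[["ident.sp.Wq"]], P[["ident.sp.Wk"]],
                          P[["ident.sp.Wv"]])$O
  p <- op_sigmoid(op_bias(op_matmul(x2, P[["ident.out.W"]]), P[["ident.out.b"]]))
  list(O = x2, P = p)
}

#' Identify transformer block
#'
#' Channel attention followed by spatial attention on the deepest encoder
#' features, then a 1x1 convolution + sigmoid producing the initial coarse
#' polyp mask.
#'
#' @param z_deep the deepest feature array `c x w x h` from [encode()].
#' @param params full parameter list from [ganet_init()].
#' @return list with `O_sp` (attended features, `c x w x h`) and `P_ini`
#'   (an `h x w` soft mask in `[0, 1]`).
#' @export
identify_block <- function(z_deep, params) {
  d <- dim(z_deep)
  r <- identify_core(fm_to_mat(z_deep), params)
  list(O_sp = mat_to_fm(r$O, d[2L], d[3L]),
       P_ini = matrix(r$P, d[3L], d[2L]))
}

refine_core <- function(z, O_prev, P_prev, P, pre, cfg) {
  g <- function(s) P[[paste0(pre, ".", s)]]
  z_all <- attn_spatial_core(z, g("all.Wq"), g("all.Wk"), g("all.Wv"))$O
  z_fg <- attn_spatial_core(op_colmul(z_all, P_prev),
                            g("fg.Wq"), g("fg.Wk"), g("fg.Wv"))$O
  z_bg <- attn_spatial_core(op_colmul(z_all, op_sub(1, P_prev)),
                            g("bg.Wq"), g("bg.Wk"), g("bg.Wv"))$O
  z_new <- op_add(op_sub(O_prev, op_mul(g("gamma1"), z_fg)),
                  op_mul(g("gamma2"), z_bg))
  p <- op_bias(op_matmul(z_new, g("out.W")), g("out.b"))
  if (cfg$sigmoid_on_predictions) p <- op_sigmoid(p)
  list(O = z_new, P = p)
}

#' Refine transformer block
#'
#' Applies overall spatial attention to the encoder features of this level,
#' then foreground attention to the features gated by the previous coarse
#' mask and background attention to the complement-gated features, and
#' corrects the previous level's features:
#' `z' = O_prev - gamma1 * z_fg + gamma2 * z_bg`, followed by a 1x1
#' convolution + sigmoid giving this level's finer mask.
#'
#' @param z_d encoder features at this level, `c x w x h`.
#' @param O_prev previous block's features, already upsampled x2 and
#'   channel-aligned to `z_d` (`c x w x h`).
#' @param P_prev previous mask upsampled x2, an `h x w` matrix.
#' @param params full parameter list; `level` selects the refine block
#'   (1 = first block after the identify block).
#' @param cfg the [ganet_config()].
#' @param level refine block index.
#' @return list with `z` (corrected features) and `P` (an `h x w` soft mask).
#' @export
refine_block <- function(z_d, O_prev, P_prev, params, cfg, level = 1L) {
  d <- dim(z_d)
  if (!all(dim(O_prev) == d)) {
    stop("O_prev shape ", paste(dim(O_prev), collapse = "x"),
         " does not match z_d ", paste(d, collapse = "x"))
  }
  if (!all(dim(P_prev) == d[c(3L, 2L)])) {
    stop("P_prev size ", paste(dim(P_prev), collapse = "x"),
         " does not match spatial size h x w = ", d[3L], "x", d[2L])
  }
  r <- refine_core(fm_to_mat(z_d), fm_to_mat(O_prev),
                   matrix(as.vector(P_prev), ncol = 1L),
                   params, paste0("ref", level), cfg)
  list(z = mat_to_fm(r$O, d[2L], d[3L]),
       P = matrix(r$P, d[3L], d[2L]))
}

# ---- full forward ----------------------------------------------------------

forward_core <- function(xmat, h, w, P, cfg) {
  zs <- encode_core(xmat, h, w, P, cfg)
  D <- cfg$D
  deep <- zs[[D]]
  idb <- identify_core(deep$m, P)
  O <- idb$O; Pm <- idb$P
  ph <- deep$h; pw <- deep$w
  preds <- list(list(m = Pm, h = ph, w = pw))
  for (l in seq_len(D - 1L)) {
    d <- D - 1L - l
    pre <- paste0("ref", l)
    O_up <- op_bias(op_matmul(op_upsample2(O, ph, pw), P[[paste0(pre, ".align.W")]]),
                    P[[paste0(pre, ".align.b")]])
    P_up <- op_upsample2(Pm, ph, pw)
    ph <- ph * 2L; pw <- pw * 2L
    r <- refine_core(zs[[d + 1L]]$m, O_up, P_up, P, pre, cfg)
    O <- r$O; Pm <- r$P
    preds <- c(list(list(m = Pm, h = ph, w = pw)), preds)
  }
  preds
}

#' Full GANet forward pass
#'
#' @inheritParams encode
#' @return an object of class `prediction_pyramid`: a list of `D` soft masks
#'   (`h_d x w_d` matrices in `[0, 1]`), finest first, with the initial mask
#'   of the identify block at the coarsest position; attribute `"final"`
#'   holds the finest mask bilinearly upsampled to the input resolution.
#' @export
ganet_forward <- function(image, params, cfg) {
  d <- dim(image)
  preds <- forward_core(img_to_mat(image), d[1L], d[2L], params, cfg)
  masks <- lapply(preds, function(p) matrix(p$m, p$h, p$w))
  structure(masks, class = "prediction_pyramid",
            final = bilinear_resize(masks[[1L]], d[1L], d[2L]))
}

#' Predict a full-resolution soft mask with a trained GANet
#'
#' @param model a model list with elements `params` and `cfg` (as returned
#'   by the training functions).
#' @param image an `H x W x 3` array in `[0, 1]`.
#' @return an `H x W` matrix of foreground probabilities.
#' @export
ganet_predict <- function(model, image) {
  attr(ganet_forward(image, model$params, model$cfg), "final")
}
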