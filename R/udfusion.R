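# Uncertainty and Distance Fusion (UDFusion): per-domain reconstruction
# autoencoders measure how close a target image is to each source dataset
# (distribution weight u, a softmax over negated reconstruction errors);
# per-pixel prediction entropies measure each teacher's confidence
# (uncertainty weight v, a per-pixel softmax over negated entropies); the
# fused pseudo-label averages the teachers' predictions with weights
# w = (u + v)/2.

# ---- reconstruction autoencoder -------------------------------------------

ae_channels <- c(8L, 16L, 16L)

ae_init <- function(seed = 0L, in_channels = 3L) {
  P <- list()
  with_seed(mix_seed(seed, 4242L), {
    cin <- in_channels
    for (l in 1:3) {
      co <- ae_channels[l]
      P[[paste0("e", l, ".W")]] <- rmat(9L * cin, co, sqrt(2 / (9 * cin)))
      P[[paste0("e", l, ".b")]] <- numeric(co)
      cin <- co
    }
    dch <- c(16L, 8L, in_channels)
    for (l in 1:3) {
      co <- dch[l]
      P[[paste0("d", l, ".W")]] <- rmat(9L * cin, co, sqrt(2 / (9 * cin)))
      P[[paste0("d", l, ".b")]] <- numeric(co)
      cin <- co
    }
  })
  P
}

ae_forward <- function(P, xmat, h, w) {
  cur <- xmat; ch <- h; cw <- w
  for (l in 1:3) {
    cur <- op_relu(op_conv(cur, P[[paste0("e", l, ".W")]],
                           P[[paste0("e", l, ".b")]], ch, cw, 3L, 3L, 2L, 1L))
    ch <- ch %/% 2L; cw <- cw %/% 2L
  }
  for (l in 1:3) {
    cur <- op_upsample2(cur, ch, cw)
    ch <- ch * 2L; cw <- cw * 2L
    cur <- op_conv(cur, P[[paste0("d", l, ".W")]], P[[paste0("d", l, ".b")]],
                   ch, cw, 3L, 3L, 1L, 1L)
    cur <- if (l < 3) op_relu(cur) else op_sigmoid(cur)
  }
  cur
}

#' Train a reconstruction autoencoder on one domain's images
#'
#' Minimizes mean squared reconstruction error (labels are never used) with
#' Adam; the trained network reconstructs images drawn from its own domain
#' better than images from differently-styled domains, which is what the
#' distribution weights exploit.
#'
#' @param dataset a `domain_dataset` (only `$images` is read).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size gradient accumulation batch.
#' @param seed integer seed; training is deterministic given
#'   `(dataset, epochs, lr, batch_size, seed)`.
#' @return an object of class `sats_autoencoder` with `params`, image size,
#'   and the per-epoch loss `history`.
#' @export
train_autoencoder <- function(dataset, epochs = 8L, lr = 1e-3,
                              batch_size = 4L, seed = 0L) {
  if (length(dataset$images) == 0L) stop("cannot train on an empty dataset")
  d <- dim(dataset$images[[1L]])
  h <- d[1L]; w <- d[2L]
  P <- ae_init(seed, d[3L])
  st <- adam_init(P)
  xs <- lapply(dataset$images, img_to_mat)
  n <- length(xs)
  history <- numeric(epochs)
  with_seed(mix_seed(seed, 777L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1L, n, by = batch_size)) {
        ids <- ord[b0:min(b0 + batch_size - 1L, n)]
        gacc <- NULL; bl <- 0
        for (i in ids) {
          r <- grad_pass(P, function(L) op_mse(ae_forward(L, xs[[i]], h, w), xs[[i]]))
          gacc <- acc_grads(gacc, r$grads)
          bl <- bl + r$loss
        }
        upd <- adam_step(st, P, scale_grads(gacc, 1 / length(ids)), lr)
        st <- upd$state; P <- upd$params
        ep_loss <- ep_loss + bl
      }
      history[ep] <- ep_loss / n
    }
  })
  structure(list(params = P, h = h, w = w, in_channels = d[3L],
                 domain_id = dataset$domain_id, history = history),
            class = "sats_autoencoder")
}

#' Reconstruction distance of an image under a trained autoencoder
#'
#' Mean squared residual over all pixels and channels between the image and
#' its reconstruction — the distribution distance between the image and the
#' autoencoder's training domain.
#'
#' @param ae a `sats_autoencoder`, or a function mapping an image to an
#'   image (useful for analytic checks, e.g. the identity).
#' @param image `H x W x 3` array in `[0, 1]`.
#' @return nonnegative scalar.
#' @export
reconstruction_distance <- function(ae, image) {
  recon <- if (is.function(ae)) {
    ae(image)
  } else {
    d <- dim(image)
    array(ae_forward(ae$params, img_to_mat(image), d[1L], d[2L]), dim = d)
  }
  mean((recon - image)^2)
}

# ---- fusion weights --------------------------------------------------------

#' Distribution weights from reconstruction distances
#'
#' Softmax of the negated distances: `u_i = exp(-D_i) / sum_j exp(-D_j)`.
#' Smaller distance (the image looks like that source domain) gives a larger
#' weight; the result lies on the probability simplex.
#'
#' @param distances nonnegative numeric vector of length `k`.
#' @return simplex vector of length `k`.
#' @export
distribution_weights <- function(distances) {
  if (length(distances) < 1L || anyNA(distances) || any(!is.finite(distances))) {
    stop("distances must be a finite numeric vector of length >= 1")
  }
  e <- exp(-(distances - min(distances)))
  e / sum(e)
}

#' Per-pixel prediction uncertainty of a soft mask
#'
#' The entropy term `U = -y * log(y + eps)`: zero for confident foreground
#' (`y = 1`) and, in the `eps` limit, for confident background (`y = 0`);
#' maximal (`1/e`) at `y = exp(-1)`. Setting `binary = TRUE` uses the
#' two-term binary entropy `-y log y - (1-y) log(1-y)` (maximal at 0.5)
#' instead.
#'
#' @param y_hat soft mask in `[0, 1]`.
#' @param eps stabilizer inside the logarithm.
#' @param binary use two-term binary entropy.
#' @return nonnegative field of the same shape.
#' @export
pixel_uncertainty <- function(y_hat, eps = 1e-8, binary = FALSE) {
  u <- -y_hat * log(y_hat + eps)
  if (binary) u <- u - (1 - y_hat) * log(1 - y_hat + eps)
  pmax(u, 0)
}

#' Per-pixel uncertainty weights across teachers
#'
#' At every pixel, softmax over the `k` teachers of the negated uncertainty:
#' the least uncertain teacher gets the largest weight; weights at each
#' pixel lie on the simplex.
#'
#' @param U_maps list of `k` nonnegative uncertainty fields of equal shape.
#' @return list of `k` fields summing to 1 at every pixel.
#' @export
uncertainty_weights <- function(U_maps) {
  k <- length(U_maps)
  stopifnot(k >= 1L)
  dims <- dim2(U_maps[[1L]])
  for (m in U_maps) {
    if (!identical(dim2(m), dims)) stop("uncertainty maps differ in shape")
  }
  M <- matrix(-unlist(lapply(U_maps, as.vector)), nrow = prod(dims), ncol = k)
  V <- softmax_rows_cpp(M)
  lapply(seq_len(k), function(i) array(V[, i], dim = dims))
}

#' Fuse teacher predictions into one reliable pseudo-label
#'
#' Under the default `udfusion` mode the fused weight of teacher `i` at
#' pixel `(p, q)` is `w_i = (u_i + v_i(p, q)) / 2` — the mean of its
#' image-level distribution weight and its pixel-level uncertainty weight —
#' and the pseudo-label is the convex combination
#' `Yhat = sum_i w_i * yhat_i`. The ablation modes replace `w`: `mean` uses
#' `1/k`, `uncertainty_only` uses `v`, `distance_only` uses `u`.
#'
#' @param predictions list of `k` soft masks of equal shape.
#' @param u simplex vector of length `k` from [distribution_weights()].
#' @param v_maps list of `k` per-pixel simplex fields from
#'   [uncertainty_weights()].
#' @param mode one of `"udfusion"`, `"mean"`, `"uncertainty_only"`,
#'   `"distance_only"`.
#' @return list with `fused` (the pseudo-label `Yhat`) and `weights` (class
#'   `fusion_weights`: `u`, `v_maps`, `w_maps`, `mode`).
#' @export
fuse_pseudo_label <- function(predictions, u, v_maps,
                              mode = c("udfusion", "mean", "uncertainty_only",
                                       "distance_only")) {
  mode <- match.arg(mode)
  k <- length(predictions)
  stopifnot(k >= 1L)
  if (length(u) != k || length(v_maps) != k) {
    stop("predictions (", k, "), u (", length(u), ") and v_maps (",
         length(v_maps), ") must agree in length")
  }
  dims <- dim2(predictions[[1L]])
  w_maps <- switch(mode,
    udfusion = lapply(seq_len(k), function(i) (u[i] + v_maps[[i]]) / 2),
    mean = lapply(seq_len(k), function(i) array(1 / k, dim = dims)),
    uncertainty_only = v_maps,
    distance_only = lapply(seq_len(k), function(i) array(u[i], dim = dims)))
  fused <- 0
  for (i in seq_len(k)) fused <- fused + w_maps[[i]] * predictions[[i]]
  list(fused = fused,
       weights = structure(list(u = u, v_maps = v_maps, w_maps = w_maps,
                                mode = mode), class = "fusion_weights"))
}
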