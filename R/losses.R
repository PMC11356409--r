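# Tversky loss, bilinear label downsampling and the multi-scale
# deep-supervision objective. All loss functions run on plain numerics or on
# tracked autodiff values, so the same code scores masks in tests and drives
# training gradients.

#' Loss configuration
#'
#' The Tversky index generalizes Dice overlap with separate penalties for
#' false positives (`alpha`) and false negatives (`beta`); `alpha + beta = 1`
#' is enforced (so `alpha = beta = 0.5` recovers soft Dice). The default
#' `alpha = 0.3, beta = 0.7` penalizes missed polyp pixels harder, matching
#' the sensitivity rationale for small lesions.
#'
#' @param alpha false-positive weight in `(0, 1)`.
#' @param beta false-negative weight in `(0, 1)`; must equal `1 - alpha`.
#' @param smooth nonnegative smoothing constant guarding empty masks.
#' @param level_weight_scheme per-level coefficient scheme for the
#'   multi-scale loss: one of `"constant"`, `"linear"`, `"pow2"`, `"pow3"`
#'   (weights `1`, `i`, `2^i`, `3^i` for decoder-order index `i`, coarsest
#'   `i = 0`). Default `"pow2"`, so the finest level carries the largest
#'   weight.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.3, beta = 0.7, smooth = 1e-6,
                        level_weight_scheme = c("pow2", "constant", "linear", "pow3")) {
  level_weight_scheme <- match.arg(level_weight_scheme)
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1, smooth >= 0)
  if (abs(alpha + beta - 1) > 1e-12) {
    stop("alpha + beta must equal 1 (got ", alpha + beta, ")")
  }
  structure(list(alpha = alpha, beta = beta, smooth = smooth,
                 level_weight_scheme = level_weight_scheme),
            class = "loss_config")
}

#' Tversky loss between a soft prediction and a (possibly soft) target
#'
#' `1 - (TP + s) / (TP + alpha*FP + beta*FN + s)` with soft counts
#' `TP = sum(P*y)`, `FP = sum(P*(1-y))`, `FN = sum((1-P)*y)`. Targets may be
#' binary masks or soft pseudo-labels in `[0, 1]`.
#'
#' @param P soft prediction in `[0, 1]` (matrix or vector).
#' @param y target of the same shape.
#' @param cfg a [loss_config()].
#' @return scalar loss in `[0, 1]`.
#' @export
tversky_loss <- function(P, y, cfg = loss_config()) {
  pv <- ad_value(P)
  if (!identical(dim2(pv), dim2(ad_value(y)))) {
    stop("prediction and target shapes differ")
  }
  tp <- op_sum(op_mul(P, y))
  fp <- op_sum(op_mul(P, op_sub(1, y)))
  fn <- op_sum(op_mul(op_sub(1, P), y))
  den <- op_add(op_add(tp, op_add(op_mul(fp, cfg$alpha), op_mul(fn, cfg$beta))),
                cfg$smooth)
  op_sub(1, op_div(op_add(tp, cfg$smooth), den))
}

#' Downsample a label mask by bilinear interpolation
#'
#' @param y an `h x w` mask (binary or soft).
#' @param target_size integer vector `c(h, w)` (or a single integer for a
#'   square target); must not exceed the source size.
#' @return a soft mask in `[0, 1]` at the target size.
#' @export
downsample_label <- function(y, target_size) {
  if (length(target_size) == 1L) target_size <- c(target_size, target_size)
  if (target_size[1L] > nrow(y) || target_size[2L] > ncol(y)) {
    stop("downsample_label: target ", paste(target_size, collapse = "x"),
         " exceeds source ", nrow(y), "x", ncol(y))
  }
  if (target_size[1L] == nrow(y) && target_size[2L] == ncol(y)) return(y)
  bilinear_resize(y, target_size[1L], target_size[2L])
}

#' Per-level coefficient of the multi-scale loss
#'
#' @param d decoder-order index, `0` = coarsest (the identify block),
#'   `D - 1` = finest refine block.
#' @param D number of supervised decoder levels.
#' @param scheme one of `"constant"`, `"linear"`, `"pow2"`, `"pow3"`.
#' @return the scalar coefficient `lambda_d`.
#' @export
level_weight <- function(d, D, scheme = "pow2") {
  stopifnot(d >= 0, d < D)
  switch(scheme,
         constant = 1,
         linear = d,
         pow2 = 2^d,
         pow3 = 3^d,
         stop("unknown level weight scheme: ", scheme))
}

multiscale_loss_core <- function(preds, ymat, cfg) {
  D <- length(preds)
  total <- 0
  for (m in seq_len(D)) {           # m = 1 is the finest level
    p <- preds[[m]]
    lam <- level_weight(D - m, D, cfg$level_weight_scheme)
    yd <- downsample_label(ymat, c(p$h, p$w))
    total <- op_add(total, op_mul(tversky_loss(p$m, matrix(as.vector(yd), ncol = 1L), cfg), lam))
  }
  total
}

#' Multi-scale deep-supervision loss over a prediction pyramid
#'
#' Sums `lambda_d * Tversky(P_d, I(y, P_d))` over all decoder levels, where
#' `I` bilinearly downsamples the full-resolution target to each level's
#' size and `lambda_d` follows the configured scheme (finest level largest
#' under the default `pow2`).
#'
#' @param pyramid a `prediction_pyramid` from [ganet_forward()] (masks
#'   finest first).
#' @param y full-resolution `h x w` target mask (binary or soft).
#' @param cfg a [loss_config()].
#' @return scalar loss, `>= 0`.
#' @export
multiscale_loss <- function(pyramid, y, cfg = loss_config()) {
  preds <- lapply(pyramid, function(p) {
    list(m = matrix(as.vector(p), ncol = 1L), h = nrow(p), w = ncol(p))
  })
  multiscale_loss_core(preds, y, cfg)
}
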