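# Adam optimizer over a flat named list of parameter arrays.

adam_init <- function(params) {
  z <- lapply(params, function(p) p * 0)
  list(m = z, v = z, t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(state = state, params = params)
}

# One tracked forward/backward pass: build leaves for every parameter, call
# `lossfn(leaves)` (returning a scalar node), and return the loss value plus
# gradients as a named list aligned with `params`.
grad_pass <- function(params, lossfn) {
  tape <- ad_tape()
  leaves <- lapply(params, function(p) ad_leaf(tape, p))
  loss <- lossfn(leaves)
  grads_by_id <- ad_backward(loss)
  grads <- lapply(leaves, function(l) grads_by_id[[l$id]])
  list(loss = ad_value(loss), grads = grads)
}

acc_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) {
    if (!is.null(g[[nm]])) {
      total[[nm]] <- if (is.null(total[[nm]])) g[[nm]] else total[[nm]] + g[[nm]]
    }
  }
  total
}

scale_grads <- function(g, s) {
  lapply(g, function(x) if (is.null(x)) NULL else x * s)
}
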