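# Independent reference implementations used as oracles. These are written
# as direct loops over the defining equations and share no code with the
# package internals they check.

row_softmax_ref <- function(S) {
  t(apply(S, 1L, function(r) {
    e <- exp(r - max(r))
    e / sum(e)
  }))
}

# channel attention by triple loops on a c x w x h array
naive_channel_attention <- function(z, Wq, Wk, Wv) {
  d <- dim(z); cc <- d[1L]; w <- d[2L]; h <- d[3L]
  proj <- function(W) {
    out <- array(0, dim = c(cc, w, h))
    for (co in 1:cc) for (j in 1:w) for (k in 1:h) {
      s <- 0
      for (ci in 1:cc) s <- s + W[ci, co] * z[ci, j, k]
      out[co, j, k] <- s
    }
    out
  }
  Q <- proj(Wq); K <- proj(Wk); V <- proj(Wv)
  S <- matrix(0, cc, cc)
  for (i1 in 1:cc) for (i2 in 1:cc) {
    s <- 0
    for (j in 1:w) for (k in 1:h) s <- s + Q[i1, j, k] * K[i2, j, k]
    S[i1, i2] <- s / sqrt(cc)
  }
  A <- row_softmax_ref(S)
  O <- array(0, dim = d)
  for (i1 in 1:cc) for (j in 1:w) for (k in 1:h) {
    s <- 0
    for (i2 in 1:cc) s <- s + A[i1, i2] * V[i2, j, k]
    O[i1, j, k] <- s
  }
  list(O = O, A = A)
}

# spatial attention by loops; gate (h x w, optional) multiplies the input
naive_spatial_attention <- function(z, Wq, Wk, Wv, gate = NULL) {
  d <- dim(z); cc <- d[1L]; w <- d[2L]; h <- d[3L]
  if (!is.null(gate)) {
    for (i in 1:cc) z[i, , ] <- z[i, , ] * t(gate)
  }
  proj <- function(W) {
    out <- array(0, dim = d)
    for (co in 1:cc) for (j in 1:w) for (k in 1:h) {
      s <- 0
      for (ci in 1:cc) s <- s + W[ci, co] * z[ci, j, k]
      out[co, j, k] <- s
    }
    out
  }
  Q <- proj(Wq); K <- proj(Wk); V <- proj(Wv)
  n <- w * h
  pos <- cbind(j = rep(1:w, each = h), k = rep(1:h, times = w)) # index j*h+k
  S <- matrix(0, n, n)
  for (p in 1:n) for (q in 1:n) {
    s <- 0
    for (i in 1:cc) {
      s <- s + Q[i, pos[p, 1L], pos[p, 2L]] * K[i, pos[q, 1L], pos[q, 2L]]
    }
    S[p, q] <- s / sqrt(cc)
  }
  A <- row_softmax_ref(S)
  O <- array(0, dim = d)
  for (i in 1:cc) for (p in 1:n) {
    s <- 0
    for (q in 1:n) s <- s + A[p, q] * V[i, pos[q, 1L], pos[q, 2L]]
    O[i, pos[p, 1L], pos[p, 2L]] <- s
  }
  list(O = O, A = A)
}

# brute-force directed/symmetric surface distances over all point pairs
brute_hd_msd <- function(predB, truthB) {
  dmin <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      best <- Inf
      for (j in seq_len(nrow(b))) {
        d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
        if (d < best) best <- d
      }
      best
    }, 0)
  }
  d1 <- dmin(predB, truthB); d2 <- dmin(truthB, predB)
  list(hd = max(max(d1), max(d2)), msd = (mean(d1) + mean(d2)) / 2)
}

rand_attn_params <- function(cc, seed) {
  set.seed(seed)
  list(Wq = matrix(rnorm(cc * cc), cc, cc),
       Wk = matrix(rnorm(cc * cc), cc, cc),
       Wv = matrix(rnorm(cc * cc), cc, cc))
}

rand_mask <- function(h, w, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(as.numeric(rbinom(h * w, 1, p)), h, w)
}
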