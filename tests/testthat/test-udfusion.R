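# Fusion mathematics: distribution weights, entropies, uncertainty weights
# and the convex pseudo-label fusion, including the ablation modes.

test_that("distribution weights are a softmax over negated distances", {
  expect_equal(distribution_weights(c(2, 2, 2)), rep(1 / 3, 3))
  u <- distribution_weights(c(0, 50, 50))
  expect_lt(max(abs(u - c(1, 0, 0))), 1e-9)
  # high-precision scalar evaluation
  u2 <- distribution_weights(c(0.1, 0.2, 0.3))
  e <- exp(-c(0.1, 0.2, 0.3))
  expect_equal(u2, e / sum(e), tolerance = 1e-12)
  expect_equal(round(u2, 4), c(0.3672, 0.3322, 0.3006))
  expect_equal(sum(u2), 1, tolerance = 1e-12)
  expect_error(distribution_weights(c(1, NaN)), "finite")
  expect_error(distribution_weights(numeric(0)))
})

test_that("decreasing one distance never decreases its weight", {
  set.seed(1)
  for (i in 1:20) {
    d <- runif(4, 0, 2)
    u0 <- distribution_weights(d)
    d2 <- d; d2[2] <- d2[2] - runif(1, 0, d[2])
    u1 <- distribution_weights(d2)
    expect_gte(u1[2], u0[2] - 1e-12)
  }
})

test_that("pixel uncertainty follows the entropy closed forms", {
  expect_equal(pixel_uncertainty(1), 0, tolerance = 1e-7)
  expect_equal(pixel_uncertainty(0), 0, tolerance = 1e-7)
  expect_equal(pixel_uncertainty(0.5), 0.5 * log(2), tolerance = 1e-7)
  # maximum at y = exp(-1) with value exp(-1)
  ys <- seq(0, 1, by = 1e-4)
  us <- pixel_uncertainty(ys)
  expect_equal(ys[which.max(us)], exp(-1), tolerance = 1e-3)
  expect_equal(max(us), exp(-1), tolerance = 1e-4)
  expect_true(all(us >= 0))
  # binary-entropy variant peaks at 0.5 instead
  ub <- pixel_uncertainty(ys, binary = TRUE)
  expect_equal(ys[which.max(ub)], 0.5, tolerance = 1e-3)
})

test_that("uncertainty weights form a per-pixel simplex favoring confident teachers", {
  U <- list(matrix(0.3, 2, 2), matrix(0.3, 2, 2))
  v <- uncertainty_weights(U)
  expect_equal(v[[1]], matrix(0.5, 2, 2))
  # teacher 1 certain at one pixel, others very uncertain
  U2 <- list(matrix(c(0, 1, 1, 1), 2, 2), matrix(10, 2, 2))
  v2 <- uncertainty_weights(U2)
  expect_gt(v2[[1]][1, 1], 1 - 1e-4)
  # scalar evaluation: k=2, U=(0.1, 0.4)
  v3 <- uncertainty_weights(list(0.1, 0.4))
  e <- exp(-c(0.1, 0.4))
  expect_equal(c(v3[[1]], v3[[2]]), e / sum(e), tolerance = 1e-12)
  expect_equal(round(c(v3[[1]], v3[[2]]), 4), c(0.5744, 0.4256))
  expect_error(uncertainty_weights(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "shape")
})

test_that("fusion is convex with simplex weights in every mode", {
  set.seed(2)
  k <- 3L
  preds <- lapply(1:k, function(i) matrix(runif(16), 4, 4))
  dists <- runif(k)
  u <- distribution_weights(dists)
  v <- uncertainty_weights(lapply(preds, pixel_uncertainty))
  for (mode in c("udfusion", "mean", "uncertainty_only", "distance_only")) {
    r <- fuse_pseudo_label(preds, u, v, mode)
    wsum <- Reduce(`+`, r$weights$w_maps)
    expect_lt(max(abs(wsum - 1)), 1e-9)
    expect_true(all(vapply(r$weights$w_maps, function(w) all(w >= 0), TRUE)))
    lo <- Reduce(pmin, preds); hi <- Reduce(pmax, preds)
    expect_true(all(r$fused >= lo - 1e-12 & r$fused <= hi + 1e-12))
  }
  # simplex invariants of the ingredient weights
  expect_equal(sum(u), 1, tolerance = 1e-9)
  expect_lt(max(abs(Reduce(`+`, v) - 1)), 1e-9)
})

test_that("fusion endpoint identities hold exactly", {
  set.seed(3)
  p1 <- matrix(runif(9), 3, 3)
  # k = 1: fused equals the single prediction in every mode
  for (mode in c("udfusion", "mean", "uncertainty_only", "distance_only")) {
    r <- fuse_pseudo_label(list(p1), 1, list(matrix(1, 3, 3)), mode)
    expect_equal(r$fused, p1, tolerance = 1e-12)
  }
  # one-hot u AND one-hot v on teacher 2: fused equals teacher 2 exactly
  preds <- list(matrix(runif(9), 3, 3), p1, matrix(runif(9), 3, 3))
  u <- c(0, 1, 0)
  v <- list(matrix(0, 3, 3), matrix(1, 3, 3), matrix(0, 3, 3))
  r <- fuse_pseudo_label(preds, u, v, "udfusion")
  expect_equal(r$fused, p1, tolerance = 1e-12)
  expect_error(fuse_pseudo_label(preds, c(0.5, 0.5), v, "mean"), "agree")
})

test_that("hand example: w = (0.65, 0.35) gives a fused value of 0.59", {
  preds <- list(matrix(0.8, 1, 1), matrix(0.2, 1, 1))
  u <- c(0.7, 0.3)
  v <- list(matrix(0.6, 1, 1), matrix(0.4, 1, 1))
  r <- fuse_pseudo_label(preds, u, v, "udfusion")
  expect_equal(as.numeric(r$weights$w_maps[[1]]), 0.65, tolerance = 1e-12)
  expect_equal(as.numeric(r$weights$w_maps[[2]]), 0.35, tolerance = 1e-12)
  expect_equal(as.numeric(r$fused), 0.59, tolerance = 1e-12)
})

test_that("udfusion weights are the mean of the two ablation weightings", {
  set.seed(4)
  k <- 3L
  preds <- lapply(1:k, function(i) matrix(runif(25), 5, 5))
  u <- distribution_weights(runif(k))
  v <- uncertainty_weights(lapply(preds, pixel_uncertainty))
  w_ud <- fuse_pseudo_label(preds, u, v, "udfusion")$weights$w_maps
  w_d <- fuse_pseudo_label(preds, u, v, "distance_only")$weights$w_maps
  w_u <- fuse_pseudo_label(preds, u, v, "uncertainty_only")$weights$w_maps
  for (i in 1:k) {
    expect_equal(w_ud[[i]], (w_d[[i]] + w_u[[i]]) / 2, tolerance = 1e-12)
  }
  # identical teacher predictions: fused outputs coincide across the modes
  same <- lapply(1:k, function(i) preds[[1]])
  vs <- uncertainty_weights(lapply(same, pixel_uncertainty))
  f_ud <- fuse_pseudo_label(same, u, vs, "udfusion")$fused
  f_d <- fuse_pseudo_label(same, u, vs, "distance_only")$fused
  f_u <- fuse_pseudo_label(same, u, vs, "uncertainty_only")$fused
  expect_equal(f_ud, (f_d + f_u) / 2, tolerance = 1e-12)
  expect_equal(f_ud, preds[[1]], tolerance = 1e-12)
})

test_that("reconstruction distance is the mean squared residual", {
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  expect_equal(reconstruction_distance(identity, img), 0)
  # hand 2x2 example via a constant-shift reconstructor
  img2 <- array(0.5, dim = c(2, 2, 3))
  shift <- function(x) x + 0.1
  expect_equal(reconstruction_distance(shift, img2), 0.01, tolerance = 1e-12)
  # invariance to storage order: pure function of pixel values
  expect_equal(reconstruction_distance(shift, aperm(img, c(2, 1, 3))),
               reconstruction_distance(shift, img))
})
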