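# Architecture contracts of the granular attention network.

test_that("spatial_flatten follows the index identity and inverts exactly", {
  set.seed(7)
  h <- 4L; w <- 3L; cc <- 3L
  x <- array(rnorm(cc * w * h), dim = c(cc, w, h))
  m <- spatial_flatten(x)
  expect_equal(dim(m), c(cc, w * h))
  # element (i=0, j=1, k=2) with h=4 appears at flat column j*h + k = 6
  expect_identical(m[1L, 1L * h + 2L + 1L], x[1L, 2L, 3L])
  for (i in 1:cc) for (j in 1:w) for (k in 1:h) {
    expect_identical(m[i, (j - 1L) * h + (k - 1L) + 1L], x[i, j, k])
  }
  expect_identical(spatial_unflatten(m, w, h), x)
  expect_error(spatial_unflatten(m, w, h + 1L), "unflatten")
})

test_that("encoder produces the documented shape ladder and finite values", {
  cfg <- ganet_config(D = 3L, base_channels = 8L)
  P <- ganet_init(cfg, 3L, seed = 1)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  zs <- encode(img, P, cfg)
  expect_equal(lapply(zs, dim),
               list(c(8L, 32L, 32L), c(16L, 16L, 16L), c(32L, 8L, 8L)))
  z0 <- encode(array(0, dim = c(64, 64, 3)), P, cfg)
  expect_true(all(vapply(z0, function(z) all(is.finite(z)), TRUE)))
  expect_error(encode(array(0, dim = c(60, 60, 3)), P, cfg), "divisible")
  expect_identical(encode(img, P, cfg), zs)   # deterministic
})

test_that("channel attention matches a naive-loop oracle and is row-stochastic", {
  for (seed in 1:3) {
    set.seed(seed)
    cc <- 2L + seed %% 2L; w <- 2L; h <- 3L
    z <- array(rnorm(cc * w * h), dim = c(cc, w, h))
    pars <- rand_attn_params(cc, seed + 50)
    got <- channel_attention(z, pars)
    ref <- naive_channel_attention(z, pars$Wq, pars$Wk, pars$Wv)
    expect_lt(max(abs(got - ref$O)), 1e-6)
    expect_lt(max(abs(attr(got, "A") - ref$A)), 1e-6)
    expect_lt(max(abs(rowSums(attr(got, "A")) - 1)), 1e-6)
  }
  # zero input: all scores zero, softmax uniform
  z0 <- array(0, dim = c(3, 2, 2))
  A0 <- attr(channel_attention(z0, rand_attn_params(3, 1)), "A")
  expect_equal(A0, matrix(1 / 3, 3, 3), tolerance = 1e-12)
})

test_that("spatial attention matches the naive oracle and is permutation-equivariant", {
  for (seed in 1:3) {
    set.seed(seed)
    cc <- 2L; w <- 2L; h <- 2L + seed %% 2L
    z <- array(rnorm(cc * w * h), dim = c(cc, w, h))
    pars <- rand_attn_params(cc, seed + 80)
    got <- spatial_attention(z, pars)
    ref <- naive_spatial_attention(z, pars$Wq, pars$Wk, pars$Wv)
    expect_lt(max(abs(got - ref$O)), 1e-6)
    expect_lt(max(abs(rowSums(attr(got, "A")) - 1)), 1e-6)
  }
  # permuting spatial positions permutes the output identically
  set.seed(42)
  cc <- 3L; w <- 2L; h <- 2L
  z <- array(rnorm(cc * w * h), dim = c(cc, w, h))
  pars <- rand_attn_params(cc, 9)
  perm <- sample(w * h)
  zf <- spatial_flatten(z)
  zp <- spatial_unflatten(zf[, perm, drop = FALSE], w, h)
  out <- spatial_flatten(spatial_attention(z, pars))
  outp <- spatial_flatten(spatial_attention(zp, pars))
  expect_lt(max(abs(outp - out[, perm, drop = FALSE])), 1e-8)
})

test_that("masked attention honors degenerate and identity gates", {
  set.seed(5)
  cc <- 2L; w <- 2L; h <- 2L
  z <- array(rnorm(cc * w * h), dim = c(cc, w, h))
  pars <- rand_attn_params(cc, 11)
  ones <- matrix(1, h, w); zeros <- matrix(0, h, w)
  expect_equal(masked_attention(z, ones, pars),
               spatial_attention(z, pars), ignore_attr = TRUE)
  # zero gate: attention over all-zero features = value projection of zero
  out0 <- masked_attention(z, zeros, pars)
  expect_lt(max(abs(out0)), 1e-12)
  # against the gated naive oracle
  gate <- matrix(runif(h * w), h, w)
  ref <- naive_spatial_attention(z, pars$Wq, pars$Wk, pars$Wv, gate = gate)
  expect_lt(max(abs(masked_attention(z, gate, pars) - ref$O)), 1e-6)
  expect_error(masked_attention(z, matrix(1, h + 1L, w), pars), "gate size")
})

test_that("identify block composes channel then spatial attention with a sigmoid head", {
  cfg <- ganet_config(D = 2L, base_channels = 4L)
  P <- ganet_init(cfg, 3L, seed = 3)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  z_deep <- encode(img, P, cfg)[[2L]]
  r <- identify_block(z_deep, P)
  expect_true(all(r$P_ini >= 0 & r$P_ini <= 1))
  expect_equal(dim(r$P_ini), dim(z_deep)[c(3L, 2L)])
  # definitional decomposition
  ch <- channel_attention(z_deep, list(Wq = P[["ident.ch.Wq"]],
                                       Wk = P[["ident.ch.Wk"]],
                                       Wv = P[["ident.ch.Wv"]]))
  sp <- spatial_attention(ch, list(Wq = P[["ident.sp.Wq"]],
                                   Wk = P[["ident.sp.Wk"]],
                                   Wv = P[["ident.sp.Wv"]]))
  expect_equal(r$O_sp, sp, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("refine block passes O_prev through exactly when both gammas are zero", {
  cfg <- ganet_config(D = 2L, base_channels = 4L, gamma1 = 0, gamma2 = 0)
  P <- ganet_init(cfg, 3L, seed = 4)
  set.seed(4)
  cc <- 4L; w <- 8L; h <- 8L
  z_d <- array(rnorm(cc * w * h), dim = c(cc, w, h))
  O_prev <- array(rnorm(cc * w * h), dim = c(cc, w, h))
  P_prev <- matrix(runif(h * w), h, w)
  r <- refine_block(z_d, O_prev, P_prev, P, cfg, level = 1L)
  expect_equal(r$z, O_prev, tolerance = 1e-12)
  expect_true(all(r$P >= 0 & r$P <= 1))
  expect_error(refine_block(z_d, O_prev[, 1:4, , drop = FALSE], P_prev, P, cfg),
               "O_prev")
  expect_error(refine_block(z_d, O_prev, P_prev[1:4, ], P, cfg), "P_prev")
})

test_that("refine block agrees with a scripted evaluation of the update rule", {
  cfg <- ganet_config(D = 2L, base_channels = 4L, gamma1 = 0.8, gamma2 = 1.3)
  P <- ganet_init(cfg, 3L, seed = 6)
  set.seed(6)
  cc <- 4L; w <- 2L; h <- 2L
  z_d <- array(rnorm(cc * w * h), dim = c(cc, w, h))
  O_prev <- array(rnorm(cc * w * h), dim = c(cc, w, h))
  P_prev <- matrix(runif(h * w), h, w)
  pars <- function(br) list(Wq = P[[paste0("ref1.", br, ".Wq")]],
                            Wk = P[[paste0("ref1.", br, ".Wk")]],
                            Wv = P[[paste0("ref1.", br, ".Wv")]])
  z_all <- naive_spatial_attention(z_d, pars("all")$Wq, pars("all")$Wk,
                                   pars("all")$Wv)$O
  z_fg <- naive_spatial_attention(z_all, pars("fg")$Wq, pars("fg")$Wk,
                                  pars("fg")$Wv, gate = P_prev)$O
  z_bg <- naive_spatial_attention(z_all, pars("bg")$Wq, pars("bg")$Wk,
                                  pars("bg")$Wv, gate = 1 - P_prev)$O
  z_ref <- O_prev - 0.8 * z_fg + 1.3 * z_bg
  r <- refine_block(z_d, O_prev, P_prev, P, cfg, level = 1L)
  expect_lt(max(abs(r$z - z_ref)), 1e-6)
})

test_that("full forward yields a shape ladder of masks in [0,1], deterministically", {
  cfg <- ganet_config(D = 3L, base_channels = 8L)
  P <- ganet_init(cfg, 3L, seed = 8)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  pyr <- ganet_forward(img, P, cfg)
  expect_length(pyr, 3L)
  expect_equal(lapply(pyr, dim),
               list(c(32L, 32L), c(16L, 16L), c(8L, 8L)))
  expect_true(all(vapply(pyr, function(p) all(p >= 0 & p <= 1), TRUE)))
  expect_equal(dim(attr(pyr, "final")), c(64L, 64L))
  pyr2 <- ganet_forward(img, P, cfg)
  expect_identical(pyr[[1L]], pyr2[[1L]])
})

test_that("every parameter receives gradient from the multi-scale loss", {
  cfg <- ganet_config(D = 2L, base_channels = 4L)
  P <- ganet_init(cfg, 3L, seed = 12)
  set.seed(12)
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  y <- matrix(0, 16, 16); y[4:10, 5:12] <- 1
  r <- sats:::grad_pass(P, function(L) {
    preds <- sats:::forward_core(sats:::img_to_mat(img), 16L, 16L, L, cfg)
    sats:::multiscale_loss_core(preds, y, loss_config())
  })
  for (nm in names(P)) {
    expect_false(is.null(r$grads[[nm]]), info = nm)
    expect_gt(max(abs(r$grads[[nm]])), 0, label = paste("grad", nm))
  }
})

test_that("analytic gradients match finite differences through the whole network", {
  cfg <- ganet_config(D = 2L, base_channels = 4L)
  P <- ganet_init(cfg, 3L, seed = 2)
  set.seed(2)
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  y <- matrix(0, 16, 16); y[5:10, 6:12] <- 1
  lossfn <- function(L) {
    preds <- sats:::forward_core(sats:::img_to_mat(img), 16L, 16L, L, cfg)
    sats:::multiscale_loss_core(preds, y, loss_config())
  }
  r <- sats:::grad_pass(P, lossfn)
  numeric_loss <- function(Pl) sats:::ad_value(lossfn(Pl))
  for (nm in sample(names(P), 8L)) {
    idx <- sample(length(P[[nm]]), 1L)
    eps <- 1e-6
    Pp <- P; Pp[[nm]][idx] <- Pp[[nm]][idx] + eps
    Pm <- P; Pm[[nm]][idx] <- Pm[[nm]][idx] - eps
    fd <- (numeric_loss(Pp) - numeric_loss(Pm)) / (2 * eps)
    an <- r$grads[[nm]][idx]
    expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4,
              label = paste("fd vs analytic for", nm))
  }
})
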