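# Synthetic domain generator: determinism, style separation, mask geometry.

test_that("domain styles are deterministic and separated across ids", {
  s1a <- make_domain_style(1, 0)
  s1b <- make_domain_style(1, 0)
  expect_identical(s1a, s1b)
  s2 <- make_domain_style(2, 0)
  hue_gap <- min(abs(s1a$base_hue - s2$base_hue),
                 360 - abs(s1a$base_hue - s2$base_hue))
  gain_gap <- abs(s1a$illumination_gain - s2$illumination_gain)
  expect_true(hue_gap >= 10 || gain_gap >= 0.2)
  expect_error(make_domain_style(0), "domain_id")
})

test_that("sampled styles stay within their documented ranges", {
  set.seed(1)
  for (i in 1:100) {
    id <- sample(1:12, 1); sd <- sample(0:500, 1)
    st <- make_domain_style(id, sd)
    expect_gte(st$base_hue, 0); expect_lt(st$base_hue, 360)
    expect_gt(st$illumination_gain, 0)
    expect_gte(st$texture_frequency, 3); expect_lte(st$texture_frequency, 9)
    expect_true(all(st$specular_spot_color >= 0 & st$specular_spot_color <= 1))
    expect_gte(st$specular_spot_rate, 0)
    expect_gte(st$noise_sd, 0)
  }
})

test_that("rendering is deterministic and masks are one connected blob of valid area", {
  st <- make_domain_style(3, 7)
  s1 <- render_polyp_image(st, 64, 64, seed = 5)
  s2 <- render_polyp_image(st, 64, 64, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  for (seed in 1:12) {
    sm <- render_polyp_image(st, 48, 48, seed = seed)
    frac <- mean(sm$mask)
    expect_gte(frac, 0.02); expect_lte(frac, 0.40)
    # exactly one 4-connected foreground component (flood fill from any pixel)
    mask <- sm$mask
    start <- which(mask == 1)[1]
    comp <- matrix(FALSE, nrow(mask), ncol(mask))
    comp[start] <- TRUE
    repeat {
      grown <- comp
      grown[-1, ] <- grown[-1, ] | comp[-nrow(comp), ]
      grown[-nrow(comp), ] <- grown[-nrow(comp), ] | comp[-1, ]
      grown[, -1] <- grown[, -1] | comp[, -ncol(comp)]
      grown[, -ncol(comp)] <- grown[, -ncol(comp)] | comp[, -1]
      grown <- grown & (mask == 1)
      if (identical(grown, comp)) break
      comp <- grown
    }
    expect_equal(sum(comp), sum(mask))
  }
  expect_error(render_polyp_image(st, 16, 64, seed = 1), "at least 32")
})

test_that("styles with a large hue gap separate in mean channel intensity", {
  stA <- make_domain_style(1, 0)
  stB <- make_domain_style(2, 0)  # 49 degrees apart by construction
  meanch <- function(st, seed) {
    img <- render_polyp_image(st, 32, 32, seed = seed)$image
    apply(img, 3, mean)
  }
  mA <- t(vapply(1:40, meanch, numeric(3), st = stA))
  mB <- t(vapply(1:40, meanch, numeric(3), st = stB))
  # at least one channel separates strongly (Welch t)
  pvals <- vapply(1:3, function(ch) stats::t.test(mA[, ch], mB[, ch])$p.value, 0)
  expect_lt(min(pvals), 1e-6)
})

test_that("benchmark structure, determinism and per-domain color centroids", {
  b <- generate_benchmark(3, 10, 32, 32, master_seed = 0)
  expect_length(b$sources, 3L)
  expect_equal(vapply(b$sources, `[[`, 0L, "n"), rep(10L, 3))
  expect_equal(b$target$n, 10L)
  expect_true(b$target$held_out)
  expect_null(b$target$masks)
  expect_length(b$target$heldout_masks, 10L)
  expect_true(b$nearest_source %in% 1:3)
  b2 <- generate_benchmark(3, 10, 32, 32, master_seed = 0)
  expect_identical(b$sources[[2]]$images, b2$sources[[2]]$images)
  expect_identical(b$target$images, b2$target$images)
  # mean-color centroids pairwise distinct
  centroid <- function(ds) {
    rowMeans(vapply(ds$images, function(im) apply(im, 3, mean), numeric(3)))
  }
  cents <- vapply(b$sources, centroid, numeric(3))
  d12 <- sqrt(sum((cents[, 1] - cents[, 2])^2))
  d13 <- sqrt(sum((cents[, 1] - cents[, 3])^2))
  d23 <- sqrt(sum((cents[, 2] - cents[, 3])^2))
  expect_gt(min(d12, d13, d23), 0.02)
})

test_that("nearest-centroid classification on mean RGB separates the domains", {
  b <- generate_benchmark(3, 20, 32, 32, master_seed = 2)
  feats <- lapply(b$sources, function(ds) {
    t(vapply(ds$images, function(im) apply(im, 3, mean), numeric(3)))
  })
  cents <- t(vapply(feats, colMeans, numeric(3)))
  correct <- 0; total <- 0
  for (dom in 1:3) for (i in 1:20) {
    dd <- rowSums((cents - matrix(feats[[dom]][i, ], 3, 3, byrow = TRUE))^2)
    correct <- correct + (which.min(dd) == dom)
    total <- total + 1
  }
  expect_gt(correct / total, 0.8)
})

test_that("held-out mask access is logged and training fields stay clean", {
  b <- generate_benchmark(1, 4, 32, 32, master_seed = 3)
  expect_length(mask_access_log(b$target), 0L)
  m <- held_out_masks(b$target, purpose = "evaluation")
  expect_length(m, 4L)
  expect_equal(mask_access_log(b$target), "evaluation")
  # labeled source datasets pass masks through unlogged
  expect_length(held_out_masks(b$sources[[1]]), 4L)
  expect_length(mask_access_log(b$sources[[1]]), 0L)
})

test_that("benchmark round-trips through the on-disk layout", {
  b <- generate_benchmark(2, 4, 32, 32, master_seed = 4)
  dir <- tempfile("bench")
  write_benchmark(b, dir)
  expect_true(file.exists(file.path(dir, "metadata.yaml")))
  b2 <- load_benchmark(dir)
  expect_equal(b2$k, 2L)
  expect_equal(b2$nearest_source, b$nearest_source)
  expect_identical(b2$sources[[1]]$masks, b$sources[[1]]$masks)
  # images survive 8-bit quantization
  err <- max(abs(b2$sources[[1]]$images[[1]] - b$sources[[1]]$images[[1]]))
  expect_lt(err, 1 / 255)
  expect_true(b2$target$held_out)
  unlink(dir, recursive = TRUE)
})
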