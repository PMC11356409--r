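# Synthetic multi-domain polyp image generator. Each "domain" mimics one
# endoscopy dataset with its own color/illumination/texture statistics: a
# mucosa-like background tinted by a base hue with a smooth illumination
# vignette and sinusoidal texture, one blob-shaped polyp (a rotated ellipse
# with low-frequency sinusoidal boundary perturbation) with shifted hue and
# brightness, Poisson-distributed specular spots, and Gaussian pixel noise.
# The target domain is a convex mixture of the source styles with one
# dominant source, plus its own perturbation and green/blue bright spots.

hsv_to_rgb <- function(h, s, v) {
  # h in degrees, s/v in [0,1]; vectorized, returns list(r, g, b)
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Create the style of one synthetic imaging domain
#'
#' Styles of distinct domains are separated by construction: base hues step
#' by 49 degrees per domain id and illumination gains cycle in steps of 0.22
#' (with at most +/-0.01 jitter), so any two distinct ids differ by at least
#' 10 degrees of hue or 0.2 of gain — the margin the per-domain
#' reconstruction autoencoders rely on.
#'
#' @param domain_id integer `>= 1`.
#' @param rng_seed integer seed; the style is a pure function of
#'   `(domain_id, rng_seed)`.
#' @return an object of class `domain_style`.
#' @export
make_domain_style <- function(domain_id, rng_seed = 0L) {
  if (!is.numeric(domain_id) || length(domain_id) != 1L || domain_id < 1 ||
      domain_id != round(domain_id)) {
    stop("domain_id must be a single integer >= 1")
  }
  domain_id <- as.integer(domain_id)
  hue0 <- mix_seed(rng_seed, 17L) %% 360L
  st <- with_seed(mix_seed(rng_seed, domain_id), {
    list(
      domain_id = domain_id,
      base_hue = (hue0 + (domain_id - 1L) * 49) %% 360,
      illumination_gain = 0.7 + 0.22 * ((domain_id - 1L) %% 5L) +
        stats::runif(1, -0.01, 0.01),
      texture_frequency = stats::runif(1, 3, 9),
      specular_spot_color = clamp01(c(stats::runif(1, 0.85, 1),
                                      stats::runif(1, 0.85, 1),
                                      stats::runif(1, 0.7, 0.95))),
      specular_spot_rate = stats::runif(1, 0.5, 2.5),
      noise_sd = stats::runif(1, 0.005, 0.02))
  })
  structure(st, class = "domain_style")
}

# draw polyp geometry until the mask area fraction is within bounds
draw_polyp_mask <- function(h, w) {
  X <- matrix(rep((seq_len(w) - 0.5) / w, each = h), h, w)
  Y <- matrix(rep((seq_len(h) - 0.5) / h, times = w), h, w)
  for (try in 1:25) {
    cx <- stats::runif(1, 0.32, 0.68); cy <- stats::runif(1, 0.32, 0.68)
    a <- stats::runif(1, 0.13, 0.26); b <- stats::runif(1, 0.13, 0.26)
    th <- stats::runif(1, 0, pi)
    a1 <- stats::runif(1, 0.05, 0.16); a2 <- stats::runif(1, 0.03, 0.10)
    p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
    dx <- X - cx; dy <- Y - cy
    xr <- dx * cos(th) + dy * sin(th)
    yr <- -dx * sin(th) + dy * cos(th)
    rr <- sqrt((xr / a)^2 + (yr / b)^2)
    phi <- atan2(yr, xr)
    bound <- 1 + a1 * sin(3 * phi + p1) + a2 * sin(5 * phi + p2)
    mask <- (rr <= bound) * 1
    frac <- mean(mask)
    if (frac >= 0.025 && frac <= 0.38) return(mask)
  }
  mask  # last attempt; bounds are loose enough that this is unreachable
}

#' Render one synthetic polyp image with its mask
#'
#' @param style a [make_domain_style()] object.
#' @param height,width image size in pixels, each `>= 32`.
#' @param seed integer; rendering is a pure function of `(style, seed)`.
#' @return a list with `image` (`H x W x 3` in `[0, 1]`), `mask` (binary
#'   `H x W`), `domain_id` and `seed`.
#' @export
render_polyp_image <- function(style, height, width, seed = 0L) {
  stopifnot(inherits(style, "domain_style"))
  if (height < 32L || width < 32L) {
    stop("image size must be at least 32x32 (got ", height, "x", width, ")")
  }
  h <- as.integer(height); w <- as.integer(width)
  with_seed(mix_seed(seed, style$domain_id, round(style$base_hue * 8)), {
    X <- matrix(rep((seq_len(w) - 0.5) / w, each = h), h, w)
    Y <- matrix(rep((seq_len(h) - 0.5) / h, times = w), h, w)
    # background: vignette illumination + oriented sinusoidal texture
    icx <- stats::runif(1, 0.35, 0.65); icy <- stats::runif(1, 0.35, 0.65)
    illum <- style$illumination_gain * (1.05 - 0.55 * ((X - icx)^2 + (Y - icy)^2))
    th1 <- stats::runif(1, 0, pi); ph1 <- stats::runif(1, 0, 2 * pi)
    tex <- 0.05 * sin(2 * pi * style$texture_frequency *
                        (X * cos(th1) + Y * sin(th1)) + ph1)
    mask <- draw_polyp_mask(h, w)
    # polyp: shifted hue, higher saturation/value, finer texture
    th2 <- stats::runif(1, 0, pi); ph2 <- stats::runif(1, 0, 2 * pi)
    texp <- 0.06 * sin(2 * pi * style$texture_frequency * 1.7 *
                         (X * cos(th2) + Y * sin(th2)) + ph2)
    hue <- matrix(style$base_hue, h, w)
    sat <- matrix(0.45, h, w)
    val <- clamp01(0.52 * illum + tex)
    hue[mask == 1] <- (style$base_hue + 45) %% 360
    sat[mask == 1] <- 0.62
    val[mask == 1] <- clamp01(0.52 * illum + 0.2 + texp)[mask == 1]
    rgb <- hsv_to_rgb(hue, sat, val)
    img <- array(c(rgb$r, rgb$g, rgb$b), dim = c(h, w, 3L))
    # specular spots
    nspot <- if (style$specular_spot_rate > 0) {
      stats::rpois(1, style$specular_spot_rate)
    } else 0L
    if (nspot > 0) {
      for (s in seq_len(nspot)) {
        sy <- stats::runif(1, 0.05, 0.95) * h
        sx <- stats::runif(1, 0.05, 0.95) * w
        r <- stats::runif(1, 1.5, 3.5)
        gpx <- exp(-(((row(mask) - sy)^2 + (col(mask) - sx)^2) / (2 * r^2)))
        wgt <- 0.85 * gpx
        for (ch in 1:3) {
          img[, , ch] <- img[, , ch] * (1 - wgt) +
            style$specular_spot_color[ch] * wgt
        }
      }
    }
    if (style$noise_sd > 0) {
      img <- img + array(stats::rnorm(h * w * 3L, 0, style$noise_sd),
                         dim = dim(img))
    }
    list(image = clamp01(img), mask = mask,
         domain_id = style$domain_id, seed = as.integer(seed))
  })
}

# ---- datasets --------------------------------------------------------------

#' Construct a domain dataset
#'
#' When `held_out = TRUE` the masks are sequestered: `ds$masks` is `NULL`
#' and the labels are only reachable through [held_out_masks()], which
#' records every access — the guard ensuring no target-domain label leaks
#' into training.
#'
#' @param images list of `H x W x 3` arrays.
#' @param masks list of binary `H x W` matrices, or `NULL` for unlabeled.
#' @param domain_id integer domain index.
#' @param name dataset name.
#' @param style optional `domain_style`.
#' @param held_out flag masks as evaluation-only.
#' @return an object of class `domain_dataset`.
#' @export
domain_dataset <- function(images, masks = NULL, domain_id = 1L,
                           name = paste0("domain", domain_id), style = NULL,
                           held_out = FALSE) {
  ds <- list(images = images, domain_id = as.integer(domain_id), name = name,
             style = style, n = length(images), held_out = isTRUE(held_out))
  if (ds$held_out) {
    ds$masks <- NULL
    ds$heldout_masks <- masks
    ds$access_log <- new.env(parent = emptyenv())
    ds$access_log$log <- character()
  } else {
    ds$masks <- masks
  }
  structure(ds, class = "domain_dataset")
}

#' Access the held-out evaluation masks of a dataset (logged)
#'
#' @param ds a `domain_dataset`.
#' @param purpose short string recorded in the access log.
#' @return the list of masks.
#' @export
held_out_masks <- function(ds, purpose = "evaluation") {
  if (!isTRUE(ds$held_out)) return(ds$masks)
  ds$access_log$log <- c(ds$access_log$log, purpose)
  ds$heldout_masks
}

#' Return the label access log of a held-out dataset
#'
#' @param ds a `domain_dataset`.
#' @return character vector of recorded access purposes (empty if labels
#'   were never touched).
#' @export
mask_access_log <- function(ds) {
  if (is.null(ds$access_log)) character() else ds$access_log$log
}

# ---- benchmark -------------------------------------------------------------

mix_styles <- function(styles, wts, master_seed, k) {
  hx <- sum(wts * cos(vapply(styles, `[[`, 0, "base_hue") * pi / 180))
  hy <- sum(wts * sin(vapply(styles, `[[`, 0, "base_hue") * pi / 180))
  wmean <- function(f) sum(wts * vapply(styles, `[[`, 0, f))
  with_seed(mix_seed(master_seed, 9090L), {
    structure(list(
      domain_id = k + 1L,
      base_hue = ((atan2(hy, hx) * 180 / pi) + stats::runif(1, -5, 5)) %% 360,
      illumination_gain = max(0.1, wmean("illumination_gain") +
                                stats::runif(1, -0.05, 0.05)),
      texture_frequency = wmean("texture_frequency") + stats::runif(1, -0.5, 0.5),
      specular_spot_color = clamp01(c(stats::runif(1, 0.05, 0.25),
                                      stats::runif(1, 0.8, 1),
                                      stats::runif(1, 0.75, 0.95))),
      specular_spot_rate = wmean("specular_spot_rate") + 1.5,
      noise_sd = wmean("noise_sd")), class = "domain_style")
  })
}

#' Generate a synthetic multi-domain benchmark
#'
#' Renders `k` labeled source domains plus one unlabeled target domain whose
#' style is a convex combination of the source styles with one dominant
#' source (weight 0.75) plus a small perturbation; the dominant source index
#' is recorded as `nearest_source` (the ground truth for fusion-selectivity
#' checks). Target masks are generated but flagged held-out: they are only
#' reachable through [held_out_masks()]. The target's bright spots are
#' green/blue, a feature absent from the sources.
#'
#' @param k number of source domains, `>= 1`.
#' @param n_per_domain images per domain, `>= 4`.
#' @param height,width image size in pixels.
#' @param master_seed integer; the benchmark is a pure function of all
#'   arguments.
#' @return an object of class `sats_benchmark` with elements `sources`
#'   (list of `k` labeled `domain_dataset`s), `target` (held-out
#'   `domain_dataset`), `nearest_source`, `styles`, `k`, `master_seed`.
#' @export
generate_benchmark <- function(k, n_per_domain, height = 64L, width = 64L,
                               master_seed = 0L) {
  stopifnot(k >= 1L, n_per_domain >= 4L)
  styles <- lapply(seq_len(k), make_domain_style, rng_seed = master_seed)
  jstar <- (master_seed %% k) + 1L
  wts <- if (k == 1L) 1 else {
    v <- rep(0.25 / (k - 1), k); v[jstar] <- 0.75; v
  }
  tstyle <- mix_styles(styles, wts, master_seed, k)
  render_domain <- function(style, i, labeled) {
    samples <- lapply(seq_len(n_per_domain), function(j) {
      render_polyp_image(style, height, width,
                         seed = mix_seed(master_seed, i, j))
    })
    domain_dataset(images = lapply(samples, `[[`, "image"),
                   masks = lapply(samples, `[[`, "mask"),
                   domain_id = style$domain_id,
                   name = if (labeled) paste0("source", i) else "target",
                   style = style, held_out = !labeled)
  }
  sources <- lapply(seq_len(k), function(i) render_domain(styles[[i]], i, TRUE))
  target <- render_domain(tstyle, k + 1L, FALSE)
  structure(list(sources = sources, target = target, nearest_source = jstar,
                 styles = c(styles, list(tstyle)), k = as.integer(k),
                 n_per_domain = as.integer(n_per_domain),
                 height = as.integer(height), width = as.integer(width),
                 master_seed = as.integer(master_seed)),
            class = "sats_benchmark")
}

# ---- on-disk layout --------------------------------------------------------

#' Write a benchmark to the standard on-disk layout
#'
#' `<dir>/<domain>/images/*.png`, `<dir>/<domain>/masks/*.png`, plus
#' `metadata.yaml` recording styles, seeds and the nearest-source index.
#' Target masks are written too (for later evaluation) and marked held-out
#' in the metadata.
#'
#' @param bench a `sats_benchmark`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  write_ds <- function(ds, masks) {
    root <- file.path(dir, ds$name)
    dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(root, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(ds$n)) {
      fn <- sprintf("img%04d.png", j)
      write_image(ds$images[[j]], file.path(root, "images", fn))
      write_mask(masks[[j]], file.path(root, "masks", fn))
    }
  }
  for (ds in bench$sources) write_ds(ds, ds$masks)
  write_ds(bench$target, bench$target$heldout_masks)
  meta <- list(
    k = bench$k, n_per_domain = bench$n_per_domain,
    height = bench$height, width = bench$width,
    master_seed = bench$master_seed, nearest_source = bench$nearest_source,
    domains = lapply(c(bench$sources, list(bench$target)), function(ds) {
      list(name = ds$name, domain_id = ds$domain_id, held_out = ds$held_out,
           style = unclass(ds$style))
    }))
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Load a benchmark written by [write_benchmark()]
#'
#' @param dir benchmark directory containing `metadata.yaml`.
#' @return a `sats_benchmark` (target masks restored as held-out).
#' @export
load_benchmark <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  read_ds <- function(dm) {
    root <- file.path(dir, dm$name)
    files <- sort(list.files(file.path(root, "images"), full.names = TRUE))
    images <- lapply(files, read_image)
    mfiles <- file.path(root, "masks", basename(files))
    masks <- lapply(mfiles, read_mask)
    style <- structure(dm$style, class = "domain_style")
    domain_dataset(images, masks, dm$domain_id, dm$name, style,
                   held_out = isTRUE(dm$held_out))
  }
  dss <- lapply(meta$domains, read_ds)
  held <- vapply(meta$domains, function(d) isTRUE(d$held_out), TRUE)
  structure(list(sources = dss[!held], target = dss[held][[1L]],
                 nearest_source = meta$nearest_source,
                 styles = lapply(dss, `[[`, "style"),
                 k = meta$k, n_per_domain = meta$n_per_domain,
                 height = meta$height, width = meta$width,
                 master_seed = meta$master_seed),
            class = "sats_benchmark")
}
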