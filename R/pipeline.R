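# Two-phase teacher-student protocol: (1) train one GANet teacher and one
# reconstruction autoencoder per labeled source domain; (2) fuse the
# teachers' predictions on the unlabeled target domain into pseudo-labels
# and train a student GANet on them. Target-domain ground truth is only
# touched at evaluation, through the logged held-out accessor.

#' Experiment configuration
#'
#' Defaults follow the reference training recipe: Adam with initial
#' learning rate 2e-4 and decay rates 0.9/0.999, batch size 4, 200 epochs,
#' and a 90/10 train/validation split of each labeled dataset. Scaled-down
#' runs override `epochs` and the architecture.
#'
#' @param ganet a [ganet_config()].
#' @param loss a [loss_config()].
#' @param fusion_mode pseudo-label fusion mode (see [fuse_pseudo_label()]).
#' @param epochs training epochs per network.
#' @param learning_rate initial Adam learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param batch_size gradient accumulation batch.
#' @param seed master seed; every stage derives its own stream from it.
#' @param val_fraction fraction of each labeled dataset held out for
#'   validation/model selection.
#' @param ae_epochs autoencoder pre-training epochs (default half of
#'   `epochs`).
#' @param ae_learning_rate autoencoder Adam learning rate.
#' @param threshold binarization threshold applied to soft predictions
#'   before evaluation metrics.
#' @return an object of class `sats_config`.
#' @export
sats_config <- function(ganet = ganet_config(), loss = loss_config(),
                        fusion_mode = "udfusion", epochs = 200L,
                        learning_rate = 2e-4, adam_beta1 = 0.9,
                        adam_beta2 = 0.999, batch_size = 4L, seed = 0L,
                        val_fraction = 0.1, ae_epochs = NULL,
                        ae_learning_rate = 1e-3, threshold = 0.5) {
  stopifnot(inherits(ganet, "ganet_config"), inherits(loss, "loss_config"),
            epochs >= 1L, learning_rate > 0, batch_size >= 1L,
            val_fraction > 0, val_fraction < 1)
  if (is.null(ae_epochs)) ae_epochs <- max(1L, as.integer(ceiling(epochs / 2)))
  structure(list(ganet = ganet, loss = loss, fusion_mode = fusion_mode,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 val_fraction = val_fraction, ae_epochs = as.integer(ae_epochs),
                 ae_learning_rate = ae_learning_rate, threshold = threshold),
            class = "sats_config")
}

dice_of <- function(pred_soft, truth, threshold) {
  overlap_metrics(confusion_counts((pred_soft > threshold) * 1, truth))[["dice"]]
}

# Core GANet training loop on (image, target-mask) pairs; targets may be
# binary or soft. Optional validation pairs drive best-checkpoint selection
# by Dice.
train_ganet <- function(images, targets, cfg, stage_seed,
                        val_images = NULL, val_masks = NULL) {
  d <- dim(images[[1L]])
  h <- d[1L]; w <- d[2L]
  P <- ganet_init(cfg$ganet, d[3L], stage_seed)
  st <- adam_init(P)
  xs <- lapply(images, img_to_mat)
  n <- length(xs)
  history <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                        val_dice = NA_real_)
  best <- list(params = P, dice = -Inf)
  with_seed(mix_seed(stage_seed, 31L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        ids <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        gacc <- NULL
        for (i in ids) {
          r <- grad_pass(P, function(L) {
            preds <- forward_core(xs[[i]], h, w, L, cfg$ganet)
            multiscale_loss_core(preds, targets[[i]], cfg$loss)
          })
          gacc <- acc_grads(gacc, r$grads)
          ep_loss <- ep_loss + r$loss
        }
        upd <- adam_step(st, P, scale_grads(gacc, 1 / length(ids)),
                         cfg$learning_rate, cfg$adam_beta1, cfg$adam_beta2)
        st <- upd$state; P <- upd$params
      }
      history$train_loss[ep] <- ep_loss / n
      if (!is.null(val_images)) {
        model_ep <- list(params = P, cfg = cfg$ganet)
        vd <- mean(vapply(seq_along(val_images), function(i) {
          dice_of(ganet_predict(model_ep, val_images[[i]]), val_masks[[i]],
                  cfg$threshold)
        }, 0))
        history$val_dice[ep] <- vd
        if (vd > best$dice) best <- list(params = P, dice = vd)
      }
    }
  })
  if (is.null(val_images)) best <- list(params = P, dice = NA_real_)
  structure(list(params = best$params, cfg = cfg$ganet,
                 best_val_dice = best$dice, history = history,
                 seed = stage_seed),
            class = "ganet_model")
}

split_train_val <- function(n, val_fraction, seed) {
  n_val <- max(1L, round(val_fraction * n))
  ord <- with_seed(mix_seed(seed, 91L), sample.int(n))
  list(train = ord[seq_len(n - n_val)], val = ord[(n - n_val + 1L):n])
}

#' Train a teacher segmenter on one labeled source domain
#'
#' Splits the dataset 90/10 into training and validation, trains a GANet
#' with the multi-scale Tversky loss, and keeps the checkpoint with the best
#' validation Dice.
#'
#' @param dataset a labeled `domain_dataset`.
#' @param cfg a [sats_config()].
#' @return a `ganet_model` with `best_val_dice` and training `history`.
#' @export
train_teacher <- function(dataset, cfg) {
  if (is.null(dataset$masks)) {
    stop("train_teacher requires a labeled dataset (no masks found)")
  }
  sp <- split_train_val(dataset$n, cfg$val_fraction,
                        mix_seed(cfg$seed, dataset$domain_id))
  train_ganet(dataset$images[sp$train], dataset$masks[sp$train], cfg,
              stage_seed = mix_seed(cfg$seed, 100L, dataset$domain_id),
              val_images = dataset$images[sp$val],
              val_masks = dataset$masks[sp$val])
}

#' Train the pooled-source baseline segmenter
#'
#' Merges all source datasets into one and trains a single GANet on the
#' pool — the "Merge" pseudo-label baseline.
#'
#' @param sources list of labeled `domain_dataset`s.
#' @param cfg a [sats_config()].
#' @return a `ganet_model`.
#' @export
train_merged_baseline <- function(sources, cfg) {
  pooled <- domain_dataset(
    images = do.call(c, lapply(sources, `[[`, "images")),
    masks = do.call(c, lapply(sources, `[[`, "masks")),
    domain_id = 0L, name = "merged")
  train_teacher(pooled, cfg)
}

#' Generate fused pseudo-labels for an unlabeled target domain
#'
#' For every target image, each teacher predicts a full-resolution soft
#' mask; each domain autoencoder supplies a reconstruction distance (so the
#' distribution weight `u` is image-specific); per-pixel entropies give the
#' uncertainty weights; and the configured fusion mode combines the
#' predictions into one pseudo-label.
#'
#' @param teachers list of `k` `ganet_model`s.
#' @param aes list of `k` `sats_autoencoder`s (same order).
#' @param target unlabeled (held-out) `domain_dataset`.
#' @param mode fusion mode (see [fuse_pseudo_label()]).
#' @param out_dir optional directory: pseudo-labels are written as 16-bit
#'   TIFF plus a YAML sidecar of per-image `u` vectors.
#' @param binary_entropy use two-term entropy in [pixel_uncertainty()].
#' @return the target dataset with `pseudo_labels` (list of soft masks),
#'   `pseudo_u` (per-image distribution weights) and `fusion_mode` added.
#' @export
generate_pseudo_labels <- function(teachers, aes, target, mode = "udfusion",
                                   out_dir = NULL, binary_entropy = FALSE) {
  k <- length(teachers)
  stopifnot(k >= 1L)
  if (length(aes) != k) {
    stop("teacher count (", k, ") and autoencoder count (", length(aes),
         ") differ")
  }
  labels <- vector("list", target$n)
  u_all <- matrix(NA_real_, target$n, k)
  for (j in seq_len(target$n)) {
    img <- target$images[[j]]
    preds <- lapply(teachers, ganet_predict, image = img)
    dist <- vapply(aes, reconstruction_distance, 0, image = img)
    u <- distribution_weights(dist)
    U <- lapply(preds, pixel_uncertainty, binary = binary_entropy)
    v <- uncertainty_weights(U)
    labels[[j]] <- fuse_pseudo_label(preds, u, v, mode)$fused
    u_all[j, ] <- u
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(target$n)) {
      write_soft_label(labels[[j]], file.path(out_dir, sprintf("pl%04d.tif", j)))
    }
    yaml::write_yaml(list(mode = mode,
                          u = lapply(seq_len(target$n),
                                     function(j) as.numeric(u_all[j, ]))),
                     file.path(out_dir, "weights.yaml"))
  }
  target$pseudo_labels <- labels
  target$pseudo_u <- u_all
  target$fusion_mode <- mode
  target
}

#' Train the student segmenter on fused pseudo-labels
#'
#' The student is a fresh GANet trained with the multi-scale Tversky loss
#' against the soft fused pseudo-labels (no binarization, so the fusion
#' weights are preserved in the targets). Target ground truth is never read.
#'
#' @param target_with_pseudo output of [generate_pseudo_labels()].
#' @param cfg a [sats_config()].
#' @return a `ganet_model`.
#' @export
train_student <- function(target_with_pseudo, cfg) {
  if (is.null(target_with_pseudo$pseudo_labels)) {
    stop("target dataset has no pseudo-labels; run generate_pseudo_labels first")
  }
  train_ganet(target_with_pseudo$images, target_with_pseudo$pseudo_labels,
              cfg, stage_seed = mix_seed(cfg$seed, 300L))
}

#' Evaluate a segmenter on a labeled dataset
#'
#' Predictions are binarized at the threshold and scored with the seven
#' metrics (IoU, Dice, Precision, Recall, Accuracy in `[0, 1]`; HD and MSD
#' in pixels), reported as mean and standard deviation over images. For a
#' held-out dataset the labels are read through [held_out_masks()], which
#' records the access. An empty predicted or true mask makes HD/MSD fall
#' back to the image diagonal; the number of such images is reported.
#'
#' @param model a `ganet_model`.
#' @param dataset a labeled `domain_dataset` (masks may be held out).
#' @param threshold binarization threshold in `(0, 1)`.
#' @return an object of class `metrics_report`: list with `mean`, `sd`
#'   (named over the seven metrics), `per_image` data frame, `n_images`,
#'   `n_empty_fallback`.
#' @export
evaluate_model <- function(model, dataset, threshold = 0.5) {
  if (dataset$n == 0L) stop("cannot evaluate on an empty dataset")
  masks <- held_out_masks(dataset, purpose = "evaluation")
  if (is.null(masks)) stop("dataset has no masks to evaluate against")
  rows <- t(vapply(seq_len(dataset$n), function(j) {
    pred <- (ganet_predict(model, dataset$images[[j]]) > threshold) * 1
    mask_metrics(pred, masks[[j]])
  }, numeric(8L)))
  per_image <- as.data.frame(rows)
  metric_cols <- c("iou", "dice", "precision", "recall", "accuracy", "hd", "msd")
  structure(list(
    mean = vapply(per_image[metric_cols], mean, 0),
    sd = vapply(per_image[metric_cols], stats::sd, 0),
    per_image = per_image,
    n_images = dataset$n,
    n_empty_fallback = sum(per_image$empty_fallback)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics over", x$n_images, "images\n")
  for (nm in names(x$mean)) {
    cat(sprintf("  %-9s %6.3f +/- %.3f\n", nm, x$mean[[nm]], x$sd[[nm]]))
  }
  if (x$n_empty_fallback > 0) {
    cat("  (", x$n_empty_fallback, "image(s) used the empty-mask diagonal",
        "fallback for HD/MSD)\n")
  }
  invisible(x)
}

#' Run the full teacher-student experiment
#'
#' Executes the pipeline end to end on a benchmark: per-source teachers and
#' autoencoders, pseudo-label fusion on the target, student training, and
#' evaluation of the student against the held-out target labels. Artifacts
#' (model checkpoints, pseudo-labels, JSON report) are written under
#' `out_dir` when given.
#'
#' @param config a [sats_config()], or the path to a YAML file with fields
#'   mirroring it.
#' @param benchmark a `sats_benchmark` (or a directory written by
#'   [write_benchmark()]).
#' @param out_dir optional output directory.
#' @param dry_run validate the configuration and data layout, then return
#'   without training.
#' @return an object of class `sats_report`: teacher summaries, student
#'   metrics, fusion-weight summaries, config snapshot and per-stage
#'   timings.
#' @export
run_sats <- function(config, benchmark, out_dir = NULL, dry_run = FALSE) {
  if (is.character(config)) config <- sats_config_from_yaml(config)
  stopifnot(inherits(config, "sats_config"))
  if (is.character(benchmark)) benchmark <- load_benchmark(benchmark)
  stopifnot(inherits(benchmark, "sats_benchmark"))
  if (dry_run) {
    return(structure(list(config = config, k = benchmark$k,
                          n_target = benchmark$target$n, dry_run = TRUE),
                     class = "sats_report"))
  }
  t_stage <- function(f) {
    t0 <- Sys.time()
    v <- f()
    list(value = v, secs = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  timings <- list()
  s <- t_stage(function() lapply(benchmark$sources, train_teacher, cfg = config))
  teachers <- s$value; timings$teachers <- s$secs
  s <- t_stage(function() lapply(benchmark$sources, function(ds) {
    train_autoencoder(ds, epochs = config$ae_epochs,
                      lr = config$ae_learning_rate,
                      batch_size = config$batch_size,
                      seed = mix_seed(config$seed, 200L, ds$domain_id))
  }))
  aes <- s$value; timings$autoencoders <- s$secs
  s <- t_stage(function() generate_pseudo_labels(
    teachers, aes, benchmark$target, mode = config$fusion_mode,
    out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "pseudo_labels")))
  target_pl <- s$value; timings$pseudo_labels <- s$secs
  s <- t_stage(function() train_student(target_pl, config))
  student <- s$value; timings$student <- s$secs
  s <- t_stage(function() evaluate_model(student, benchmark$target,
                                         config$threshold))
  student_eval <- s$value; timings$evaluation <- s$secs

  u_mean <- colMeans(target_pl$pseudo_u)
  sel_rate <- mean(apply(target_pl$pseudo_u, 1L, which.max) ==
                     benchmark$nearest_source)
  report <- structure(list(
    teachers = lapply(teachers, function(m) {
      list(best_val_dice = m$best_val_dice,
           final_train_loss = utils::tail(m$history$train_loss, 1L))
    }),
    student_metrics = student_eval,
    fusion = list(mode = config$fusion_mode, u_mean = u_mean,
                  nearest_source = benchmark$nearest_source,
                  selectivity = sel_rate),
    target_label_accesses = mask_access_log(benchmark$target),
    config = config, timings = timings), class = "sats_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(teachers, file.path(out_dir, "teachers.rds"))
    saveRDS(aes, file.path(out_dir, "autoencoders.rds"))
    saveRDS(student, file.path(out_dir, "student.rds"))
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_to_list <- function(r) {
  list(teachers = r$teachers,
       student = list(mean = as.list(r$student_metrics$mean),
                      sd = as.list(r$student_metrics$sd),
                      n_images = r$student_metrics$n_images),
       fusion = list(mode = r$fusion$mode, u_mean = as.numeric(r$fusion$u_mean),
                     nearest_source = r$fusion$nearest_source,
                     selectivity = r$fusion$selectivity),
       timings = r$timings)
}

sats_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ganet <- do.call(ganet_config, y$ganet %||% list())
  loss <- do.call(loss_config, y$loss %||% list())
  y$ganet <- NULL; y$loss <- NULL
  do.call(sats_config, c(list(ganet = ganet, loss = loss), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
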