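# Overlap and surface-distance metrics for binary segmentation masks:
# IoU, Dice, Precision, Recall, Accuracy, Hausdorff distance (HD) and mean
# surface distance (MSD), all at evaluation resolution in pixel units.

check_binary <- function(m, what) {
  v <- as.vector(m)
  if (!all(v %in% c(0, 1))) stop(what, " must be binary (0/1)")
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth binary `h x w` matrices (values 0/1).
#' @return named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  check_binary(pred, "pred"); check_binary(truth, "truth")
  p <- as.logical(pred); t <- as.logical(truth)
  c(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

#' Overlap metrics from confusion counts
#'
#' IoU = TP/(TP+FP+FN), Dice = 2TP/(2TP+FP+FN), Precision = TP/(TP+FP),
#' Recall = TP/(TP+FN), Accuracy = (TP+TN)/total. When both masks are empty
#' (TP+FP+FN = 0) IoU and Dice are 1 by convention; an undefined Precision
#' or Recall (empty denominator) is likewise scored 1 against an equally
#' empty counterpart and 0 otherwise.
#'
#' @param counts output of [confusion_counts()].
#' @return named numeric vector `c(iou, dice, precision, recall, accuracy)`.
#' @export
overlap_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  tot <- tp + fp + fn + tn
  iou <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  dice <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  prec <- if (tp + fp == 0) (if (fn == 0) 1 else 0) else tp / (tp + fp)
  rec <- if (tp + fn == 0) (if (fp == 0) 1 else 0) else tp / (tp + fn)
  c(iou = iou, dice = dice, precision = prec, recall = rec,
    accuracy = (tp + tn) / tot)
}

#' Boundary pixels of a binary mask
#'
#' Foreground pixels with at least one background 4-neighbor; the image
#' border counts as background.
#'
#' @param mask binary `h x w` matrix.
#' @return an `n x 2` matrix of (row, col) coordinates (possibly 0 rows).
#' @export
boundary_pixels <- function(mask) {
  check_binary(mask, "mask")
  h <- nrow(mask); w <- ncol(mask)
  fg <- mask == 1
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- fg
  interior <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  which(fg & !interior, arr.ind = TRUE)
}

cross_dist2 <- function(a, b) {
  outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
}

#' Hausdorff distance between two boundary point sets
#'
#' Maximum over both directed maximum nearest-neighbor Euclidean distances;
#' symmetric in its arguments.
#'
#' @param predB,truthB `n x 2` coordinate matrices from [boundary_pixels()];
#'   both must be nonempty.
#' @return distance in pixels.
#' @export
hausdorff_distance <- function(predB, truthB) {
  if (nrow(predB) == 0L || nrow(truthB) == 0L) {
    stop("hausdorff_distance: empty boundary set; callers substitute the ",
         "image diagonal for empty masks (see evaluate_model)")
  }
  d2 <- cross_dist2(predB, truthB)
  sqrt(max(max(apply(d2, 1L, min)), max(apply(d2, 2L, min))))
}

#' Mean surface distance between two boundary point sets
#'
#' Average of the two mean directed nearest-neighbor distances; symmetric
#' and never larger than the Hausdorff distance.
#'
#' @inheritParams hausdorff_distance
#' @return distance in pixels.
#' @export
mean_surface_distance <- function(predB, truthB) {
  if (nrow(predB) == 0L || nrow(truthB) == 0L) {
    stop("mean_surface_distance: empty boundary set; callers substitute ",
         "the image diagonal for empty masks (see evaluate_model)")
  }
  d2 <- cross_dist2(predB, truthB)
  (mean(sqrt(apply(d2, 1L, min))) + mean(sqrt(apply(d2, 2L, min)))) / 2
}

# All seven metrics for one mask pair. Empty boundary sets fall back to the
# image diagonal for HD/MSD, and the event is reported in the result.
mask_metrics <- function(pred, truth) {
  ov <- overlap_metrics(confusion_counts(pred, truth))
  pb <- boundary_pixels(pred); tb <- boundary_pixels(truth)
  fallback <- nrow(pb) == 0L || nrow(tb) == 0L
  if (fallback && sum(pred) == 0 && sum(truth) == 0) {
    hd <- 0; msd <- 0
  } else if (fallback) {
    diag_px <- sqrt(nrow(pred)^2 + ncol(pred)^2)
    hd <- diag_px; msd <- diag_px
  } else {
    hd <- hausdorff_distance(pb, tb)
    msd <- mean_surface_distance(pb, tb)
  }
  c(ov, hd = hd, msd = msd, empty_fallback = as.numeric(fallback))
}
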