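# Segmentation evaluation: detection F1 at an IoU threshold, Dice,
# (symmetric) best dice, and surface dice on skeletonised masks.

#' Detection F1 at an IoU threshold
#'
#' Object pairs with intersection-over-union strictly above the threshold
#' are matched (at thresholds >= 0.5 the matching is unique, so there is no
#' assignment ambiguity); unmatched segmentation objects are false
#' positives, unmatched ground-truth objects false negatives, and
#' `F1 = 2 TP / (2 TP + FP + FN)`.
#'
#' @param seg,gt Instance segmentations (`syn_labels` or integer arrays);
#'   background 0 is excluded.
#' @param iou_threshold Matching threshold (default 0.5).
#' @return A list: `f1`, `tp`, `fp`, `fn`, and `matches` (tibble of gt id,
#'   seg id, IoU). Class `syn_match_result`.
#' @export
matched_f1 <- function(seg, gt, iou_threshold = 0.5) {
  s <- as_label_array(seg)
  g <- as_label_array(gt)
  if (!identical(dim(s), dim(g))) abort("segmentation shapes differ")
  tab <- overlap_table_cpp(as.integer(g), as.integer(s))
  sizes_g <- stats::aggregate(tab[, 3], by = list(id = tab[, 1]), FUN = sum)
  sizes_s <- stats::aggregate(tab[, 3], by = list(id = tab[, 2]), FUN = sum)
  size_g <- setNames(sizes_g$x, sizes_g$id)
  size_s <- setNames(sizes_s$x, sizes_s$id)
  pos <- tab[tab[, 1] > 0 & tab[, 2] > 0, , drop = FALSE]
  n_gt <- sum(names(size_g) != "0")
  n_seg <- sum(names(size_s) != "0")
  matches <- tibble::tibble(gt_id = integer(0), seg_id = integer(0),
                            iou = numeric(0))
  if (nrow(pos)) {
    inter <- pos[, 3]
    uni <- size_g[as.character(pos[, 1])] + size_s[as.character(pos[, 2])] -
      inter
    iou <- inter / uni
    keep <- iou > iou_threshold
    if (any(keep)) {
      cand <- data.frame(gt_id = pos[keep, 1], seg_id = pos[keep, 2],
                         iou = iou[keep])
      cand <- cand[order(-cand$iou, cand$gt_id, cand$seg_id), ]
      used_g <- used_s <- integer(0)
      rows <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {  # greedy; unique anyway at >= 0.5
        if (cand$gt_id[r] %in% used_g || cand$seg_id[r] %in% used_s) next
        rows[r] <- TRUE
        used_g <- c(used_g, cand$gt_id[r])
        used_s <- c(used_s, cand$seg_id[r])
      }
      matches <- tibble::as_tibble(cand[rows, ])
    }
  }
  tp <- nrow(matches)
  fp <- n_seg - tp
  fn <- n_gt - tp
  f1 <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(list(f1 = f1, tp = tp, fp = fp, fn = fn, matches = matches,
                 iou_threshold = iou_threshold),
            class = "syn_match_result")
}

#' @export
print.syn_match_result <- function(x, ...) {
  cat("<syn_match_result> F1 = ", signif(x$f1, 4), " (TP ", x$tp, ", FP ",
      x$fp, ", FN ", x$fn, ") at IoU > ", x$iou_threshold, "\n", sep = "")
  invisible(x)
}

#' Dice coefficient of two binary masks
#'
#' `2 |s & a| / (|s| + |a|)`; two empty masks score 1.
#'
#' @param seg,gt Binary masks (arrays or `syn_labels`).
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(seg, gt) {
  s <- as_label_array(seg) > 0L
  g <- as_label_array(gt) > 0L
  if (!identical(dim(s), dim(g))) abort("mask shapes differ")
  denom <- sum(s) + sum(g)
  if (denom == 0) return(1)
  2 * sum(s & g) / denom
}

#' Best-dice instance agreement
#'
#' For every ground-truth object the best Dice over all segmented objects,
#' averaged over ground-truth objects. The score as published is
#' directional (ground truth versus segmentation); `symmetric = TRUE`
#' additionally evaluates the reverse direction and returns the minimum of
#' the two, which equals the directional value on identical inputs.
#'
#' @param seg,gt Instance segmentations.
#' @param symmetric Return the min of both directions?
#' @return Score in `[0, 1]`; empty gt with non-empty seg scores 0.
#' @export
best_dice <- function(seg, gt, symmetric = FALSE) {
  s <- as_label_array(seg)
  g <- as_label_array(gt)
  if (!identical(dim(s), dim(g))) abort("segmentation shapes differ")
  fwd <- best_dice_directional(s, g)
  if (!symmetric) return(fwd)
  min(fwd, best_dice_directional(g, s))
}

best_dice_directional <- function(s, g) {
  ids_g <- sort(unique(as.integer(g)))
  ids_g <- ids_g[ids_g > 0]
  if (!length(ids_g)) {
    return(if (any(s > 0)) 0 else 1)
  }
  tab <- overlap_table_cpp(as.integer(g), as.integer(s))
  size_g <- tapply(tab[, 3], tab[, 1], sum)
  size_s <- tapply(tab[, 3], tab[, 2], sum)
  pos <- tab[tab[, 1] > 0 & tab[, 2] > 0, , drop = FALSE]
  best <- setNames(rep(0, length(ids_g)), ids_g)
  if (nrow(pos)) {
    dice <- 2 * pos[, 3] /
      (size_g[as.character(pos[, 1])] + size_s[as.character(pos[, 2])])
    per <- tapply(dice, pos[, 1], max)
    best[names(per)] <- per
  }
  mean(best)
}

#' Surface Dice of two boundary-like masks
#'
#' Both masks are skeletonised; precision is the fraction of segmentation
#' skeleton voxels within `tolerance` voxels of the ground-truth skeleton,
#' recall the symmetric quantity, and the score their harmonic mean. Thin
#' sheet-like masks (everywhere within 2 voxels of their surface) are
#' their own skeleton; thicker masks are reduced to their EDT medial
#' voxels (local distance maxima). Two empty masks score 1.
#'
#' @param seg,gt Binary masks.
#' @param tolerance Match tolerance in voxels.
#' @return Score in `[0, 1]`.
#' @export
surface_dice <- function(seg, gt, tolerance = 1) {
  s <- as_label_array(seg) > 0L
  g <- as_label_array(gt) > 0L
  if (!identical(dim(s), dim(g))) abort("mask shapes differ")
  if (!any(s) && !any(g)) return(1)
  if (!any(s) || !any(g)) return(0)
  d <- dim(s)
  sk_s <- skeletonize_mask(array(s, d))
  sk_g <- skeletonize_mask(array(g, d))
  ones <- rep(1, length(d))
  dist_g <- sqrt(edt_sq_cpp(sk_g, d, ones))
  dist_s <- sqrt(edt_sq_cpp(sk_s, d, ones))
  precision <- mean(dist_g[sk_s] <= tolerance)
  recall <- mean(dist_s[sk_g] <= tolerance)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

# Skeleton used by the surface dice: thin masks pass through unchanged;
# thicker masks keep the medial voxels where the interior EDT is locally
# maximal (a ridge / medial-surface approximation).
skeletonize_mask <- function(mask) {
  d <- dim(mask)
  interior <- sqrt(edt_sq_cpp(array(!mask, d), d, rep(1, length(d))))
  if (max(interior) <= 2) return(mask)
  # local maxima of the interior distance within the mask
  shifted_max <- interior
  nd <- length(d)
  for (a in seq_len(nd)) {
    for (s in c(-1L, 1L)) {
      sh <- shift_array(interior, a, s)
      shifted_max <- pmax(shifted_max, sh)
    }
  }
  ridge <- mask & (interior >= shifted_max - 1e-9)
  array(ridge, d)
}

shift_array <- function(x, axis, by) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(a) {
    if (a != axis) return(seq_len(d[a]))
    i <- seq_len(d[a]) + by
    pmin(pmax(i, 1L), d[a])
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Aggregate a metric over several volumes
#'
#' Reports the mean, and the SD when five or more items contribute.
#'
#' @param scores Numeric vector of per-volume scores.
#' @return A tibble: `n`, `mean`, `sd` (NA below five items).
#' @export
aggregate_scores <- function(scores) {
  tibble::tibble(
    n = length(scores),
    mean = mean(scores),
    sd = if (length(scores) >= 5) stats::sd(scores) else NA_real_
  )
}
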