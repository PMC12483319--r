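# Independent brute-force oracles used to validate the fast implementations.

# all-pairs IoU matching: returns F1 by exhaustive pair enumeration
brute_force_f1 <- function(seg, gt, thr = 0.5) {
  s <- if (inherits(seg, "syn_labels")) seg$labels else seg
  g <- if (inherits(gt, "syn_labels")) gt$labels else gt
  ids_s <- setdiff(unique(as.integer(s)), 0L)
  ids_g <- setdiff(unique(as.integer(g)), 0L)
  pairs <- list()
  for (ig in ids_g) {
    mg <- g == ig
    for (is in ids_s) {
      ms <- s == is
      inter <- sum(mg & ms)
      if (inter == 0) next
      iou <- inter / sum(mg | ms)
      if (iou > thr) pairs[[length(pairs) + 1]] <- c(ig, is, iou)
    }
  }
  # greedy unique assignment by decreasing IoU
  tp <- 0L
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(-pm[, 3]), , drop = FALSE]
    used_g <- used_s <- integer(0)
    for (r in seq_len(nrow(pm))) {
      if (pm[r, 1] %in% used_g || pm[r, 2] %in% used_s) next
      tp <- tp + 1L
      used_g <- c(used_g, pm[r, 1])
      used_s <- c(used_s, pm[r, 2])
    }
  }
  fp <- length(ids_s) - tp
  fn <- length(ids_g) - tp
  if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
}

brute_force_best_dice <- function(seg, gt) {
  s <- if (inherits(seg, "syn_labels")) seg$labels else seg
  g <- if (inherits(gt, "syn_labels")) gt$labels else gt
  ids_g <- setdiff(unique(as.integer(g)), 0L)
  ids_s <- setdiff(unique(as.integer(s)), 0L)
  if (!length(ids_g)) return(if (length(ids_s)) 0 else 1)
  mean(vapply(ids_g, function(ig) {
    mg <- g == ig
    if (!length(ids_s)) return(0)
    max(vapply(ids_s, function(is) {
      ms <- s == is
      2 * sum(mg & ms) / (sum(mg) + sum(ms))
    }, 1.0))
  }, 1.0))
}

# minimum pairwise voxel distance between an object and a structure, in nm
brute_force_min_distance <- function(obj_mask, struct_mask, voxel_size) {
  pv <- which(obj_mask, arr.ind = TRUE)
  ps <- which(struct_mask, arr.ind = TRUE)
  best <- Inf
  for (i in seq_len(nrow(pv))) {
    d <- sqrt(colSums((t(ps) - pv[i, ])^2 * voxel_size^2))
    best <- min(best, min(d))
  }
  best
}

# random labelled fixture: a few blobs on a small grid
random_label_fixture <- function(shape, n_obj, seed) {
  set.seed(seed)
  lab <- array(0L, shape)
  for (i in seq_len(n_obj)) {
    ctr <- runif(length(shape), 4, shape - 3)
    r <- runif(1, 2, 5)
    coords <- as.matrix(expand.grid(lapply(shape, seq_len)))
    d <- sqrt(rowSums((t(t(coords) - ctr))^2))
    lab[coords[d <= r, , drop = FALSE]] <- i
  }
  lab
}

# digital sphere helper
digital_sphere <- function(n, ctr, r) {
  g <- array(0L, c(n, n, n))
  for (k in seq_len(n)) {
    g[, , k] <- as.integer(outer(((1:n) - ctr[1])^2, ((1:n) - ctr[2])^2,
                                 "+") + (k - ctr[3])^2 <= r^2)
  }
  g
}

# EDT in voxel units (squared distances) for tests
edt_voxels <- function(mask) {
  d <- dim(mask)
  array(synrec:::edt_sq_cpp(mask, d, rep(1, length(d))), d)
}
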