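# Structure-specific postprocessing: probability maps -> segmentations.

#' Distance-seeded watershed parameters
#'
#' Presets: vesicles use boundary threshold 0.5 and seed distance 8 voxels;
#' mitochondria, being larger with weaker boundary evidence, use 0.25 and 6.
#' The pixel-unit thresholds apply at the model's working resolution, and
#' are calibrated to the physical object size in voxels: the vesicle preset
#' assumes vesicle radii of about 10-16 voxels (30-50 nm at ~1.5 nm voxels).
#'
#' @param boundary_threshold Boundary probability threshold in (0, 1).
#' @param seed_distance Distance threshold (voxels) for seed extraction.
#' @param foreground_threshold Foreground probability threshold.
#' @return A `syn_ws_params`.
#' @export
watershed_params <- function(boundary_threshold = 0.5, seed_distance = 8,
                             foreground_threshold = 0.5) {
  stopifnot(boundary_threshold > 0, boundary_threshold < 1,
            foreground_threshold > 0, foreground_threshold < 1,
            seed_distance >= 1)
  structure(list(boundary_threshold = boundary_threshold,
                 seed_distance = seed_distance,
                 foreground_threshold = foreground_threshold),
            class = "syn_ws_params")
}

#' @rdname watershed_params
#' @param preset `"vesicles"` or `"mitochondria"`.
#' @export
watershed_preset <- function(preset = c("vesicles", "mitochondria")) {
  preset <- match.arg(preset)
  switch(preset,
    vesicles = watershed_params(0.5, 8, 0.5),
    mitochondria = watershed_params(0.25, 6, 0.5))
}

#' Instance segmentation by distance-seeded watershed
#'
#' The five-step procedure used for vesicle and mitochondrion instances:
#' \enumerate{
#'   \item Euclidean distance transform of the complement of the
#'     thresholded boundary predictions.
#'   \item Threshold these distances at `seed_distance`; connected
#'     components of the result are the \emph{seeds}.
#'   \item The distance to the nearest seed component (EDT again) is the
#'     \emph{heightmap}.
#'   \item Thresholded foreground predictions form the \emph{mask}.
#'   \item A seeded watershed of the heightmap within the mask yields the
#'     instance segmentation.
#' }
#' The distance-based seed computation recovers one seed per roughly
#' spherical object even when its boundary prediction has holes.
#'
#' @param maps A [new_maps()] with foreground and boundary channels.
#' @param params A [watershed_params()].
#' @return A `syn_labels` instance segmentation (empty when the foreground
#'   is empty -- not an error).
#' @export
distance_watershed_instances <- function(maps, params = watershed_preset()) {
  stopifnot(inherits(maps, "syn_maps"), inherits(params, "syn_ws_params"))
  fg <- maps$foreground
  bd <- maps$boundary
  d <- dim(fg)
  ones <- rep(1, length(d))
  # (1) distance to thresholded boundaries
  bmask <- bd > params$boundary_threshold
  dist_b <- sqrt(edt_sq_cpp(bmask, d, ones))
  dist_b[is.infinite(dist_b)] <- max(d)  # no boundary anywhere
  # (2) seeds
  seed_mask <- array(dist_b > params$seed_distance, d)
  seeds <- label_components_cpp(seed_mask, d, 2L)
  # (4) mask
  mask <- array(fg > params$foreground_threshold, d)
  if (!any(mask)) {
    return(new_labels(array(0L, d), maps$voxel_size))
  }
  # (3) heightmap: distance to the nearest seed
  if (!any(seed_mask)) {
    return(new_labels(array(0L, d), maps$voxel_size))
  }
  height <- sqrt(edt_sq_cpp(seed_mask, d, ones))
  # (5) seeded watershed within the mask
  lab <- watershed_cpp(height, seeds, mask, d)
  new_labels(array(lab, d), maps$voxel_size)
}

#' Active-zone segmentation by thresholding and size filtering
#'
#' Active zones are spatially well separated, so a binary segmentation
#' suffices: the probability map is thresholded and connected components
#' smaller than `min_size` voxels are removed (strictly smaller: a
#' 500-voxel component survives the default).
#'
#' @param maps A [new_maps()]; the foreground channel is used.
#' @param threshold Probability threshold.
#' @param min_size Minimum component size in voxels.
#' @return A binary `syn_labels` mask.
#' @export
segment_active_zone <- function(maps, threshold = 0.5, min_size = 500) {
  stopifnot(inherits(maps, "syn_maps"))
  p <- maps$foreground
  d <- dim(p)
  mask <- array(p > threshold, d)
  cc <- label_components_cpp(mask, d, 2L)
  if (max(cc) > 0) {
    sizes <- tabulate(cc[cc > 0L])
    drop <- which(sizes < min_size)
    if (length(drop)) mask[cc %in% drop] <- FALSE
  }
  out <- array(0L, d)
  out[mask] <- 1L
  new_labels(out, maps$voxel_size)
}

#' Compartment merging parameters
#'
#' @param slice_params [watershed_params()] applied per slice.
#' @param merge_cost_offset Offset subtracted from the overlap fraction to
#'   obtain the signed multicut edge cost (positive = attractive).
#' @param min_compartment_size Minimum 3D component size in voxels.
#' @return A `syn_compartment_params`.
#' @export
compartment_params <- function(slice_params = watershed_params(0.5, 6, 0.5),
                               merge_cost_offset = 0.5,
                               min_compartment_size = 0) {
  structure(list(slice_params = slice_params,
                 merge_cost_offset = merge_cost_offset,
                 min_compartment_size = min_compartment_size),
            class = "syn_compartment_params")
}

#' Compartment segmentation: per-slice watershed + multicut-style merging
#'
#' Large compartments are segmented slice by slice with a seeded watershed
#' on the distance to the boundary predictions, then 2D fragments are
#' merged across the depth axis: fragments overlapping in adjacent slices
#' are connected by edges weighted `overlap_fraction - merge_cost_offset`
#' (overlap fraction relative to the smaller fragment), and the resulting
#' signed graph is partitioned by greedy additive edge contraction --
#' repeatedly contracting the most attractive remaining edge, summing
#' parallel edge weights -- which is order-independent in all cases where
#' the optimal multicut is unambiguous.
#'
#' @param maps A [new_maps()] with boundary (and optionally
#'   boundary-distance) channels; 3D.
#' @param params A [compartment_params()].
#' @return A `syn_labels` with one id per merged 3D compartment.
#' @export
segment_compartments <- function(maps, params = compartment_params()) {
  stopifnot(inherits(maps, "syn_maps"))
  bd <- maps$boundary
  d <- dim(bd)
  if (length(d) != 3) abort("compartment segmentation requires 3D maps")
  sp <- params$slice_params
  nz <- d[1]
  frag <- array(0L, d)
  offset <- 0L
  frag_slices <- integer(0)
  for (z in seq_len(nz)) {
    sl <- bd[z, , ]
    d2 <- dim(sl)
    bmask <- sl > sp$boundary_threshold
    if (!is.null(maps$boundary_distance)) {
      dist_b <- maps$boundary_distance[z, , ]
      # normalised channel: convert to voxels via its cap if attached
      cap <- attr(maps$boundary_distance, "cap") %||% 10
      dist_b <- dist_b * cap
    } else {
      dist_b <- sqrt(edt_sq_cpp(bmask, d2, c(1, 1)))
      dist_b[is.infinite(dist_b)] <- max(d2)
    }
    seed_mask <- array(dist_b > sp$seed_distance, d2)
    if (!any(seed_mask)) next
    seeds <- label_components_cpp(seed_mask, d2, 2L)
    mask <- array(!bmask, d2)
    height <- -dist_b  # flood from deep interiors towards boundaries
    lab <- array(watershed_cpp(as.numeric(height), seeds, mask, d2), d2)
    n_here <- max(lab)
    lab[lab > 0L] <- lab[lab > 0L] + offset
    frag[z, , ] <- lab
    frag_slices <- c(frag_slices, rep(z, n_here))
    offset <- offset + n_here
  }
  if (offset == 0L) {
    return(new_labels(array(0L, d), maps$voxel_size))
  }
  # fragment adjacency across z
  edges <- list()
  sizes <- tabulate(frag[frag > 0L], nbins = offset)
  for (z in seq_len(nz - 1)) {
    a <- frag[z, , ]
    b <- frag[z + 1, , ]
    keep <- a > 0L & b > 0L
    if (!any(keep)) next
    tab <- overlap_table_cpp(as.integer(a[keep]), as.integer(b[keep]))
    for (r in seq_len(nrow(tab))) {
      ia <- tab[r, 1]; ib <- tab[r, 2]; ov <- tab[r, 3]
      fracv <- ov / min(sizes[ia], sizes[ib])
      edges[[length(edges) + 1]] <- c(ia, ib, fracv - params$merge_cost_offset)
    }
  }
  merged <- greedy_agglomerate(offset, edges)
  out <- frag
  out[out > 0L] <- merged[out[out > 0L]]
  out <- relabel_consecutive(out)
  if (params$min_compartment_size > 0 && max(out) > 0) {
    sz <- tabulate(out[out > 0L])
    drop <- which(sz < params$min_compartment_size)
    if (length(drop)) out[out %in% drop] <- 0L
    out <- relabel_consecutive(out)
  }
  new_labels(array(out, d), maps$voxel_size)
}

# Greedy additive edge contraction on a signed graph: contract the highest
# positive edge, merging nodes and summing parallel edges, until no
# attractive edge remains. Ties broken by (weight, smaller node ids).
greedy_agglomerate <- function(n_nodes, edges) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # accumulate weights between node pairs
  w <- new.env(hash = TRUE)
  key <- function(i, j) paste0(min(i, j), "_", max(i, j))
  for (e in edges) {
    k <- key(e[1], e[2])
    w[[k]] <- (w[[k]] %||% 0) + e[3]
  }
  repeat {
    keys <- ls(w)
    if (!length(keys)) break
    wts <- vapply(keys, function(k) w[[k]], 1.0)
    best <- max(wts)
    if (best <= 0) break
    cand <- sort(keys[wts == best])[1]  # deterministic tie-break
    ij <- as.integer(strsplit(cand, "_")[[1]])
    ri <- find(ij[1]); rj <- find(ij[2])
    if (ri != rj) {
      keep <- min(ri, rj); drop <- max(ri, rj)
      parent[drop] <- keep
      # reroute edges incident to drop
      for (k in ls(w)) {
        ab <- as.integer(strsplit(k, "_")[[1]])
        if (drop %in% ab) {
          other <- setdiff(ab, drop)
          val <- w[[k]]
          rm(list = k, envir = w)
          if (length(other) == 0 || other == keep) next
          nk <- key(keep, other)
          w[[nk]] <- (w[[nk]] %||% 0) + val
        }
      }
    } else {
      rm(list = cand, envir = w)
    }
  }
  vapply(seq_len(n_nodes), find, 1L)
}

relabel_consecutive <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  lab[lab > 0L] <- lut[lab[lab > 0L]]
  lab
}

#' Filter ribbon-synapse structure candidates
#'
#' The ribbon is the candidate component with the most surrounding
#' vesicles (surface distance at most `proximity_radius`); the presynaptic
#' density is the candidate closest to the chosen ribbon. Empty candidate
#' masks yield empty outputs with a warning.
#'
#' @param ribbon_mask,pd_mask Binary candidate masks (`syn_labels` or
#'   arrays).
#' @param vesicles A `syn_labels` vesicle segmentation.
#' @param proximity_radius Vesicle-counting radius in nm (default 80 nm,
#'   the ribbon-association distance).
#' @param voxel_size Voxel size in nm (taken from `vesicles` if absent).
#' @return List with binary `syn_labels` `ribbon` and
#'   `presynaptic_density`.
#' @export
filter_ribbon_structures <- function(ribbon_mask, pd_mask, vesicles,
                                     proximity_radius = 80,
                                     voxel_size = NULL) {
  ves <- if (inherits(vesicles, "syn_labels")) vesicles else
    new_labels(vesicles, voxel_size %||% 1)
  vs <- voxel_size %||% ves$voxel_size
  rmask <- as_label_array(ribbon_mask) > 0L
  pmask <- as_label_array(pd_mask) > 0L
  d <- dim(ves$labels)
  empty <- new_labels(array(0L, d), vs)
  if (!any(rmask)) {
    warn("no ribbon candidates; returning empty structures")
    return(list(ribbon = empty, presynaptic_density = empty))
  }
  rcc <- array(label_components_cpp(array(rmask, d), d, 2L), d)
  # vesicle surface distance to each candidate; count vesicles within radius
  counts <- vapply(seq_len(max(rcc)), function(id) {
    dist <- sqrt(edt_sq_cpp(rcc == id, d, vs))
    mins <- label_min_cpp(ves$labels, dist)
    sum(mins[, 2] <= proximity_radius)
  }, 1.0)
  best_r <- which.max(counts)  # which.max takes the lowest id on ties
  ribbon <- array(0L, d)
  ribbon[rcc == best_r] <- 1L
  rib_lab <- new_labels(ribbon, vs)
  if (!any(pmask)) {
    warn("no presynaptic density candidates; returning empty mask")
    return(list(ribbon = rib_lab, presynaptic_density = empty))
  }
  pcc <- array(label_components_cpp(array(pmask, d), d, 2L), d)
  dist_r <- sqrt(edt_sq_cpp(ribbon > 0L, d, vs))
  dmins <- label_min_cpp(pcc, dist_r)
  best_p <- dmins[which.min(dmins[, 2]), 1]
  pd <- array(0L, d)
  pd[pcc == best_p] <- 1L
  list(ribbon = rib_lab, presynaptic_density = new_labels(pd, vs))
}
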