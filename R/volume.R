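#' Volumetric image with voxel-size metadata
#'
#' A `syn_volume` wraps a 2D or 3D numeric array together with its per-axis
#' voxel size in nanometres. 3D arrays use the tomography axis convention
#' (z, y, x), so the anisotropic (depth) axis is always the first one; 2D
#' arrays are (y, x). All downstream measurements are reported in nm, which
#' is why a voxel size is mandatory: it is never silently defaulted.
#'
#' @param data Numeric array, 2D or 3D.
#' @param voxel_size Numeric vector of per-axis voxel edge lengths in nm.
#'   A single value is recycled to all axes.
#' @param provenance Free-text source tag.
#' @return A `syn_volume` object.
#' @export
new_volume <- function(data, voxel_size, provenance = "") {
  if (!is.array(data) && !is.matrix(data)) {
    data <- as.array(data)
  }
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) abort("volume data must be a 2D or 3D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, nd)
  if (length(voxel_size) != nd) {
    abort("voxel_size must have one entry per axis")
  }
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("voxel_size components must be strictly positive and finite")
  }
  if (any(!is.finite(data))) abort("volume data must be finite")
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         provenance = provenance),
    class = "syn_volume"
  )
}

#' Instance segmentation label volume
#'
#' Non-negative integer labels congruent with a [new_volume()] array:
#' 0 is background, each positive id one object. Ids need not be consecutive.
#'
#' @param labels Integer array (2D or 3D) of non-negative ids.
#' @param voxel_size Per-axis voxel size in nm (single values are recycled).
#' @return A `syn_labels` object.
#' @export
new_labels <- function(labels, voxel_size) {
  nd <- length(dim(labels))
  if (!nd %in% c(2L, 3L)) abort("label data must be a 2D or 3D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, nd)
  if (length(voxel_size) != nd) abort("voxel_size must have one entry per axis")
  if (any(voxel_size <= 0)) abort("voxel_size components must be positive")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) abort("labels must be non-negative")
  structure(
    list(labels = labels, voxel_size = as.numeric(voxel_size)),
    class = "syn_labels"
  )
}

#' @export
print.syn_volume <- function(x, ...) {
  cat("<syn_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size, 4), collapse = "/"), " nm",
      if (nzchar(x$provenance)) paste0("  [", x$provenance, "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
print.syn_labels <- function(x, ...) {
  ids <- label_ids(x)
  cat("<syn_labels> ", paste(dim(x$labels), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size, 4), collapse = "/"), " nm, ",
      length(ids), " objects\n", sep = "")
  invisible(x)
}

#' Positive label ids present in a segmentation
#' @param seg A `syn_labels` object or integer array.
#' @return Sorted integer vector of positive ids.
#' @export
label_ids <- function(seg) {
  arr <- if (inherits(seg, "syn_labels")) seg$labels else seg
  ids <- sort(unique(as.integer(arr)))
  ids[ids > 0L]
}

as_label_array <- function(x) {
  if (inherits(x, "syn_labels")) return(x$labels)
  if (inherits(x, "syn_volume")) {
    a <- x$data
    storage.mode(a) <- "integer"
    return(a)
  }
  if (is.array(x) || is.matrix(x)) {
    a <- x
    storage.mode(a) <- "integer"
    return(a)
  }
  abort("expected a syn_labels, syn_volume, or array")
}

as_numeric_array <- function(x) {
  if (inherits(x, "syn_volume")) return(x$data)
  if (inherits(x, "syn_labels")) return(x$labels + 0)
  if (is.array(x) || is.matrix(x)) return(x)
  abort("expected a syn_volume, syn_labels, or array")
}

#' Resample a volume or label image to a new voxel size
#'
#' Intensity data are linearly interpolated; label data use nearest-neighbour
#' lookup so no new ids are invented. The output shape is
#' `round(shape * voxel_size / target)` per axis. Binning by an integer
#' factor k is the special case `target = k * voxel_size`.
#'
#' @param vol A `syn_volume` or `syn_labels`.
#' @param target_voxel_size Target per-axis voxel size in nm (single values
#'   are recycled).
#' @param mode `"intensity"` (linear) or `"labels"` (nearest). Defaults to
#'   the type of `vol`.
#' @return An object of the same class as `vol` at the new resolution.
#' @export
resample_volume <- function(vol, target_voxel_size,
                            mode = c("auto", "intensity", "labels")) {
  mode <- match.arg(mode)
  is_lab <- inherits(vol, "syn_labels")
  if (mode == "auto") mode <- if (is_lab) "labels" else "intensity"
  arr <- if (is_lab) vol$labels else vol$data
  d <- dim(arr)
  nd <- length(d)
  if (length(target_voxel_size) == 1L) {
    target_voxel_size <- rep(target_voxel_size, nd)
  }
  if (any(target_voxel_size <= 0)) abort("target voxel size must be positive")
  out_dim <- pmax(1L, as.integer(round(d * vol$voxel_size / target_voxel_size)))
  res <- resample_cpp(as.numeric(arr), d, out_dim, mode == "labels")
  out <- array(res, out_dim)
  if (is_lab) {
    new_labels(out, target_voxel_size)
  } else {
    new_volume(out, target_voxel_size,
               provenance = vol$provenance)
  }
}

#' Bin a volume by an integer factor
#'
#' @param vol A `syn_volume` or `syn_labels`.
#' @param factor Integer binning factor (applied to every axis).
#' @return The resampled object at `factor * voxel_size`.
#' @export
bin_volume <- function(vol, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  resample_volume(vol, vol$voxel_size * factor)
}
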