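# Phantom tomogram generation. Phantoms emulate the content of presynaptic
# electron tomograms -- spherical vesicles rendered as a dark membrane ring
# with a lighter lumen on a bright background, a slab-like active zone,
# an ellipsoidal mitochondrion, a dense ribbon with its presynaptic density,
# and stacked synaptic compartments -- with exact instance labels, so every
# downstream stage can be validated without real data.

#' Probability maps aligned to a volume
#'
#' Per-voxel semantic predictions in `[0, 1]`: a foreground channel, a
#' boundary channel, and optionally a normalised boundary-distance channel
#' (used by the compartment model variant).
#'
#' @param foreground,boundary Numeric arrays in `[0, 1]`, same shape.
#' @param boundary_distance Optional numeric array (normalised distance).
#' @param voxel_size Per-axis voxel size in nm.
#' @return A `syn_maps` object.
#' @export
new_maps <- function(foreground, boundary, boundary_distance = NULL,
                     voxel_size = 1) {
  stopifnot(identical(dim(foreground), dim(boundary)))
  nd <- length(dim(foreground))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, nd)
  rng <- range(foreground, boundary)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    abort("probability channels must lie in [0, 1]")
  }
  structure(
    list(foreground = foreground, boundary = boundary,
         boundary_distance = boundary_distance,
         voxel_size = as.numeric(voxel_size)),
    class = "syn_maps"
  )
}

#' @export
print.syn_maps <- function(x, ...) {
  cat("<syn_maps> ", paste(dim(x$foreground), collapse = " x "),
      " voxels; channels: foreground, boundary",
      if (!is.null(x$boundary_distance)) ", boundary_distance" else "",
      "\n", sep = "")
  invisible(x)
}

#' Phantom tomogram specification
#'
#' Defaults follow the scale of room-temperature electron tomograms of
#' presynaptic terminals: 1.554 nm voxels and vesicle radii of 8-15 nm.
#' The seed fixes all randomness, so equal specs produce bit-identical
#' phantoms.
#'
#' @param shape Voxels per axis, length 3 (z, y, x) or 2 (y, x).
#' @param voxel_size Voxel edge length in nm (scalar or per axis).
#' @param n_vesicles Number of vesicles to place.
#' @param vesicle_radius_range Radius interval in nm.
#' @param structures Character subset of `"active_zone"`, `"mitochondrion"`,
#'   `"ribbon"`, `"presynaptic_density"`, `"compartments"`.
#' @param membrane_contrast Intensity drop of membranes below background
#'   (data range is `[0, 1]`, background 0.75).
#' @param noise_sd Additive Gaussian noise SD as a fraction of the data range.
#' @param seed RNG seed fixing placement and noise.
#' @param retry_cap Rejection-sampling retries per vesicle before failing.
#' @param missing_wedge Apply anisotropic blur along z emulating the
#'   missing-wedge elongation (off by default).
#' @return A `syn_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_size = 1.554,
                         n_vesicles = 20, vesicle_radius_range = c(8, 15),
                         structures = character(0),
                         membrane_contrast = 0.4, noise_sd = 0.1, seed = 1,
                         retry_cap = 1000, missing_wedge = FALSE) {
  known <- c("active_zone", "mitochondrion", "ribbon",
             "presynaptic_density", "compartments")
  bad <- setdiff(structures, known)
  if (length(bad)) abort(paste0("unknown structures: ",
                                paste(bad, collapse = ", ")))
  stopifnot(n_vesicles >= 0, length(vesicle_radius_range) == 2,
            diff(vesicle_radius_range) >= 0, noise_sd >= 0)
  nd <- length(shape)
  if (!nd %in% 2:3) abort("shape must have 2 or 3 axes")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, nd)
  r_max_vx <- vesicle_radius_range[2] / min(voxel_size)
  if (2 * r_max_vx + 6 > min(shape)) {
    abort("vesicle radii do not fit inside the phantom shape")
  }
  structure(
    list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
         n_vesicles = as.integer(n_vesicles),
         vesicle_radius_range = vesicle_radius_range,
         structures = structures, membrane_contrast = membrane_contrast,
         noise_sd = noise_sd, seed = as.integer(seed),
         retry_cap = as.integer(retry_cap), missing_wedge = missing_wedge),
    class = "syn_phantom_spec"
  )
}

# paint a filled ball / disc into arr over its bounding box; returns indices
ball_mask_bbox <- function(shape, center, radius_vx) {
  nd <- length(shape)
  lo <- pmax(1L, floor(center - radius_vx - 1))
  hi <- pmin(shape, ceiling(center + radius_vx + 1))
  coords <- lapply(seq_len(nd), function(a) seq(lo[a], hi[a]))
  sub <- as.matrix(expand.grid(coords))
  d2 <- rowSums((t(t(sub) - center))^2 * rep(1, nd))
  list(sub = sub, dist = sqrt(d2))
}

lin_index <- function(sub, shape) {
  idx <- sub[, 1]
  mult <- 1
  for (a in seq_len(ncol(sub))[-1]) {
    mult <- mult * shape[a - 1]
    idx <- idx + (sub[, a] - 1L) * mult
  }
  idx
}

#' Generate a phantom tomogram with ground-truth labels
#'
#' Vesicles are non-overlapping spheres placed by rejection sampling and
#' rendered as a dark membrane ring around a lighter lumen. Requested
#' structures are rendered with distinct label volumes per class. The result
#' is deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a `syn_volume`), `labels` (named
#'   list of `syn_labels`: always `vesicles`, plus one entry per requested
#'   structure) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "syn_phantom_spec"))
  with_seed(spec$seed, function() generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  shape <- spec$shape
  nd <- length(shape)
  vs <- spec$voxel_size
  vx <- min(vs)
  bg <- 0.75
  dark <- bg - spec$membrane_contrast
  vol <- array(bg, shape)
  occupied <- array(FALSE, shape)
  labels <- list()

  # --- compartments: two stacked compartments split by a dark membrane ---
  has <- function(s) s %in% spec$structures
  y_ax <- nd - 1L  # y axis index (2D: 1, 3D: 2)
  az_y <- round(0.72 * shape[y_ax])
  if (has("compartments") || has("active_zone") || has("ribbon") ||
      has("presynaptic_density")) {
    # membrane plane at az_y (two voxels thick)
    mem_idx <- slab_indices(shape, y_ax, az_y, az_y + 1L)
    vol[mem_idx] <- dark
    occupied[mem_idx] <- TRUE
  }
  if (has("compartments")) {
    comp <- array(0L, shape)
    comp[slab_indices(shape, y_ax, 1L, az_y - 1L)] <- 1L
    comp[slab_indices(shape, y_ax, az_y + 2L, shape[y_ax])] <- 2L
    labels$compartments <- new_labels(comp, vs)
  }
  if (has("active_zone")) {
    az <- array(0L, shape)
    az_idx <- box_indices(shape, y_ax, az_y - 1L, az_y,
                          lateral_fraction = 0.35)
    az[az_idx] <- 1L
    vol[az_idx] <- dark - 0.05
    occupied[az_idx] <- TRUE
    labels$active_zone <- new_labels(az, vs)
  }
  if (has("ribbon")) {
    rib <- array(0L, shape)
    ctr <- shape * 0.5
    ctr[y_ax] <- az_y - round(14 / vx)
    semi <- pmax(2, round(c(10, 12, 8)[seq_len(nd)] / vs))
    idx <- ellipsoid_indices(shape, ctr, semi)
    rib[idx] <- 1L
    vol[idx] <- dark - 0.1
    occupied[idx] <- TRUE
    labels$ribbon <- new_labels(rib, vs)
  }
  if (has("presynaptic_density")) {
    pd <- array(0L, shape)
    idx <- box_indices(shape, y_ax, az_y - max(2L, round(4 / vx)) - 1L,
                       az_y - 2L, lateral_fraction = 0.12)
    pd[idx] <- 1L
    vol[idx] <- dark - 0.1
    occupied[idx] <- TRUE
    labels$presynaptic_density <- new_labels(pd, vs)
  }
  if (has("mitochondrion")) {
    mito <- array(0L, shape)
    ctr <- shape * c(0.3, 0.3, 0.72)[seq_len(nd)]
    semi <- pmax(3, round(0.14 * shape))
    idx <- ellipsoid_indices(shape, ctr, semi)
    rim <- ellipsoid_indices(shape, ctr, pmax(1, semi - max(1, round(3 / vx))))
    mito[idx] <- 1L
    vol[idx] <- dark
    vol[rim] <- bg - 0.2
    occupied[idx] <- TRUE
    labels$mitochondrion <- new_labels(mito, vs)
  }

  # --- vesicles by rejection sampling ---
  ves <- array(0L, shape)
  centers <- matrix(numeric(0), 0, nd)
  radii_vx <- numeric(0)
  mem_vx <- max(1, round(3 / vx))  # ~3 nm membrane
  for (i in seq_len(spec$n_vesicles)) {
    r_nm <- runif(1, spec$vesicle_radius_range[1], spec$vesicle_radius_range[2])
    r_vx <- r_nm / vx
    placed <- FALSE
    for (t in seq_len(spec$retry_cap)) {
      ctr <- runif(nd, r_vx + 2, shape - r_vx - 1)
      if (nrow(centers) &&
          any(sqrt(colSums((t(centers) - ctr)^2)) <= radii_vx + r_vx + 1.5)) {
        next
      }
      bb <- ball_mask_bbox(shape, ctr, r_vx)
      inside <- bb$dist <= r_vx
      idx <- lin_index(bb$sub[inside, , drop = FALSE], shape)
      if (any(occupied[idx])) next
      ves[idx] <- i
      lum <- bb$dist <= r_vx - mem_vx
      vol[idx] <- dark
      lum_idx <- lin_index(bb$sub[lum, , drop = FALSE], shape)
      vol[lum_idx] <- bg - 0.1
      centers <- rbind(centers, ctr)
      radii_vx <- c(radii_vx, r_vx)
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(paste0("could not place vesicle ", i, " after ",
                   spec$retry_cap, " retries"))
    }
  }
  labels <- c(list(vesicles = new_labels(ves, vs)), labels)

  if (spec$missing_wedge && nd == 3L) {
    vol <- array(gaussian_blur_cpp(vol, shape, c(1.5, 0, 0)), shape)
  }
  if (spec$noise_sd > 0) {
    vol <- vol + rnorm(length(vol), sd = spec$noise_sd)
    vol <- pmin(pmax(vol, 0), 1)
    vol <- array(vol, shape)
  }
  list(volume = new_volume(vol, vs, provenance = "phantom"),
       labels = labels, spec = spec,
       vesicle_centers = centers, vesicle_radii_vx = radii_vx)
}

slab_indices <- function(shape, axis, from, to) {
  idx <- lapply(seq_along(shape), function(a) {
    if (a == axis) seq(max(1L, from), min(shape[a], to)) else seq_len(shape[a])
  })
  lin_index(as.matrix(expand.grid(idx)), shape)
}

box_indices <- function(shape, axis, from, to, lateral_fraction) {
  idx <- lapply(seq_along(shape), function(a) {
    if (a == axis) {
      seq(max(1L, from), min(shape[a], to))
    } else {
      half <- round(lateral_fraction * shape[a])
      ctr <- round(shape[a] / 2)
      seq(max(1L, ctr - half), min(shape[a], ctr + half))
    }
  })
  lin_index(as.matrix(expand.grid(idx)), shape)
}

ellipsoid_indices <- function(shape, center, semi) {
  lo <- pmax(1L, floor(center - semi))
  hi <- pmin(shape, ceiling(center + semi))
  coords <- lapply(seq_along(shape), function(a) seq(lo[a], hi[a]))
  sub <- as.matrix(expand.grid(coords))
  u <- t((t(sub) - center) / semi)
  lin_index(sub[rowSums(u^2) <= 1, , drop = FALSE], shape)
}

#' Two touching spheres placed explicitly
#'
#' Fixture for watershed splitting tests: two equal spheres with centre
#' separation `separation_factor * radius`; overlap voxels are assigned to
#' the nearer centre (lower id on ties).
#'
#' @param radius_nm Sphere radius in nm.
#' @param separation_factor Centre separation in units of the radius
#'   (values below 2 give touching/overlapping spheres).
#' @param voxel_size Voxel size in nm.
#' @param shape Volume shape in voxels.
#' @param direction Unit direction of the centre axis (defaults to x).
#' @return A `syn_labels` with ids 1 and 2.
#' @export
phantom_touching_pair <- function(radius_nm = 17.5, separation_factor = 1.8,
                                  voxel_size = 1.554, shape = c(56, 56, 56),
                                  direction = NULL) {
  nd <- length(shape)
  r_vx <- radius_nm / voxel_size
  if (is.null(direction)) {
    direction <- c(rep(0, nd - 1), 1)
  }
  direction <- direction / sqrt(sum(direction^2))
  ctr <- shape / 2
  off <- direction * separation_factor * r_vx / 2
  c1 <- ctr - off
  c2 <- ctr + off
  if (any(c(c1, c2) < r_vx + 2) ||
      any(c1 > shape - r_vx - 1) || any(c2 > shape - r_vx - 1)) {
    abort("spheres do not fit inside the volume")
  }
  lab <- array(0L, shape)
  for (k in 1:2) {
    cc <- if (k == 1) c1 else c2
    bb <- ball_mask_bbox(shape, cc, r_vx)
    keep <- bb$dist <= r_vx
    sub <- bb$sub[keep, , drop = FALSE]
    idx <- lin_index(sub, shape)
    if (k == 2) {
      d1 <- sqrt(rowSums((t(t(sub) - c1))^2))
      idx <- idx[d1 > bb$dist[keep]]  # strictly nearer to centre 2
    }
    lab[idx] <- k
  }
  new_labels(lab, voxel_size)
}

#' Oracle probability maps from ground-truth labels
#'
#' Stand-in for network output: the foreground channel is 1 inside objects,
#' the boundary channel is 1 on rim voxels (object voxels within `rim_width`
#' Chebyshev distance of background or of another object). With
#' `softness > 0` both channels are Gaussian-smoothed (boundary renormalised
#' to peak 1), emulating soft network predictions.
#'
#' @param labels A `syn_labels`.
#' @param rim_width Rim half-width in voxels (>= 1).
#' @param softness Gaussian SD in voxels; 0 keeps binary maps.
#' @return A [new_maps()] object.
#' @export
render_oracle_maps <- function(labels, rim_width = 1, softness = 0) {
  stopifnot(inherits(labels, "syn_labels"))
  if (rim_width < 1) abort("rim_width must be at least 1 voxel")
  lab <- labels$labels
  d <- dim(lab)
  fg <- array(as.numeric(lab > 0L), d)
  bd <- array(as.numeric(boundary_rim_cpp(lab, d, as.integer(rim_width))), d)
  if (softness > 0) {
    fg <- array(gaussian_blur_cpp(fg, d, rep(softness, length(d))), d)
    bd <- array(gaussian_blur_cpp(bd, d, rep(softness, length(d))), d)
    if (max(bd) > 0) bd <- bd / max(bd)
    fg <- pmin(pmax(fg, 0), 1)
    bd <- pmin(pmax(bd, 0), 1)
  }
  new_maps(array(fg, d), array(bd, d), voxel_size = labels$voxel_size)
}

#' Domain-shift corruption specification
#'
#' A deterministic analogue of the acquisition differences addressed by
#' domain adaptation: Gaussian blur, additive Gaussian noise scaled by the
#' data range, and a gamma contrast change. The zero spec (no blur, no
#' noise, gamma 1) is the identity.
#'
#' @param blur_sigma Blur SD in voxels (isotropic).
#' @param noise_scale Noise SD as a fraction of the data range.
#' @param contrast_gamma Gamma exponent applied to range-normalised data.
#' @param seed RNG seed for the noise draw.
#' @return A `syn_shift_spec`.
#' @export
domain_shift_spec <- function(blur_sigma = 0, noise_scale = 0,
                              contrast_gamma = 1, seed = 1) {
  stopifnot(blur_sigma >= 0, noise_scale >= 0, contrast_gamma > 0)
  structure(list(blur_sigma = blur_sigma, noise_scale = noise_scale,
                 contrast_gamma = contrast_gamma, seed = as.integer(seed)),
            class = "syn_shift_spec")
}

#' Apply a domain-shift corruption to a volume
#'
#' Blur, then additive noise (SD = `noise_scale` times the data range, taken
#' as 1 for constant input), then gamma. Deterministic given the spec seed.
#'
#' @param vol A `syn_volume`.
#' @param spec A [domain_shift_spec()].
#' @return The corrupted `syn_volume`.
#' @export
apply_domain_shift <- function(vol, spec) {
  stopifnot(inherits(vol, "syn_volume"), inherits(spec, "syn_shift_spec"))
  x <- vol$data
  d <- dim(x)
  if (spec$blur_sigma > 0) {
    x <- array(gaussian_blur_cpp(x, d, rep(spec$blur_sigma, length(d))), d)
  }
  if (spec$noise_scale > 0) {
    rng <- diff(range(x))
    if (rng == 0) rng <- 1
    x <- x + with_seed(spec$seed, function()
      array(rnorm(length(x), sd = spec$noise_scale * rng), d))
  }
  if (spec$contrast_gamma != 1) {
    lo <- min(x); hi <- max(x)
    if (hi > lo) {
      x <- lo + (hi - lo) * ((x - lo) / (hi - lo))^spec$contrast_gamma
    }
  }
  new_volume(array(x, d), vol$voxel_size, provenance = vol$provenance)
}
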