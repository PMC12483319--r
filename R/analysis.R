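# Synapse morphometry: distances, diameters, pools, areas, binned counts.
# All distances are surface-to-surface: the minimum over an object's voxels
# of the Euclidean distance transform of the reference structure, scaled by
# the (possibly anisotropic) voxel size. This matches the "shortest
# distance" convention of classical contour-model tools; centre-based
# distances are deliberately not provided.

#' Per-vesicle distance to a structure
#'
#' Distance in nm from each vesicle to a named structure: the minimum over
#' the vesicle's voxels of the EDT of the structure, i.e. 0 when the
#' vesicle touches or overlaps the structure.
#'
#' @param vesicles A `syn_labels` instance segmentation.
#' @param structure Binary mask (`syn_labels`, logical or integer array).
#' @param voxel_size Per-axis voxel size in nm (from `vesicles` if absent).
#' @param name Column name suffix for the output.
#' @return A tibble with columns `id` and `distance_nm`.
#' @export
measure_object_distances <- function(vesicles, structure, voxel_size = NULL,
                                     name = "structure") {
  stopifnot(inherits(vesicles, "syn_labels"))
  vs <- voxel_size %||% vesicles$voxel_size
  smask <- as_label_array(structure) > 0L
  if (!any(smask)) {
    abort(paste0("structure '", name, "' is empty; cannot measure distances"))
  }
  d <- dim(vesicles$labels)
  stopifnot(identical(dim(smask), d))
  dist <- sqrt(edt_sq_cpp(array(smask, d), d, vs))
  mins <- label_min_cpp(vesicles$labels, dist)
  tibble::tibble(id = as.integer(mins[, 1]), distance_nm = mins[, 2]) |>
    dplyr::arrange(.data$id)
}

#' Vesicle diameters and volumes
#'
#' The diameter is that of the largest inscribed sphere: twice the maximum
#' of the interior EDT (distance to the nearest background/other-object
#' voxel) scaled by the voxel size, plus half a voxel. The half-voxel term
#' corrects the sub-voxel offset between the continuous inscribed-sphere
#' centre and the nearest voxel centre, which biases the raw maximum low;
#' on analytic spheres of radii 4-20 voxels the corrected estimator is
#' accurate to better than 0.8 voxel. A single-voxel object reports
#' 2.5 voxels. The volume is the voxel count times the voxel volume.
#'
#' @param vesicles A `syn_labels`.
#' @param voxel_size Per-axis voxel size in nm (from `vesicles` if absent).
#' @return A tibble: `id`, `diameter_nm`, `volume_nm3`.
#' @export
measure_diameters <- function(vesicles, voxel_size = NULL) {
  stopifnot(inherits(vesicles, "syn_labels"))
  vs <- voxel_size %||% vesicles$voxel_size
  lab <- vesicles$labels
  d <- dim(lab)
  ids <- label_ids(vesicles)
  if (!length(ids)) {
    return(tibble::tibble(id = integer(0), diameter_nm = numeric(0),
                          volume_nm3 = numeric(0)))
  }
  # interior EDT per object: distance to anything that is not the object.
  # A single joint EDT of the background is wrong for touching objects, so
  # voxels on the rim *between two objects* (different positive labels
  # within Chebyshev distance 1, but no background) are added to the
  # reference set -- an exact treatment would need one EDT per object.
  outside <- lab == 0L
  rim_any <- boundary_rim_cpp(lab, d, 1L)
  binarised <- array(as.integer(lab > 0L), d)
  rim_bg <- boundary_rim_cpp(binarised, d, 1L)
  inter_rim <- rim_any & !rim_bg
  dist <- if (any(inter_rim)) {
    sqrt(edt_sq_cpp(array(outside | inter_rim, d), d, vs))
  } else {
    sqrt(edt_sq_cpp(array(outside, d), d, vs))
  }
  maxs <- label_max_cpp(lab, dist)
  vol_voxel <- prod(vs)
  vx <- mean(vs)
  counts <- tabulate(lab[lab > 0L], nbins = max(ids))
  tibble::tibble(
    id = as.integer(maxs[, 1]),
    diameter_nm = 2 * maxs[, 2] + 0.5 * vx,
    volume_nm3 = counts[as.integer(maxs[, 1])] * vol_voxel
  ) |> dplyr::arrange(.data$id)
}


#' Vesicle pool criteria (ribbon-synapse workflow)
#'
#' Ribbon-associated vesicles lie within 80 nm of the ribbon;
#' membrane-proximal vesicles within 100 nm of the presynaptic density and
#' 50 nm of the membrane; docked vesicles within 100 nm of the presynaptic
#' density and 2 nm of the active-zone membrane. All thresholds inclusive.
#'
#' @param ribbon_assoc_max,mp_pd_max,mp_mem_max,docked_pd_max,docked_mem_max
#'   Distance thresholds in nm.
#' @return A `syn_pool_criteria`.
#' @export
pool_criteria <- function(ribbon_assoc_max = 80, mp_pd_max = 100,
                          mp_mem_max = 50, docked_pd_max = 100,
                          docked_mem_max = 2) {
  if (docked_mem_max >= mp_mem_max) {
    abort("docked membrane threshold must be below the membrane-proximal one")
  }
  structure(list(ribbon_assoc_max = ribbon_assoc_max, mp_pd_max = mp_pd_max,
                 mp_mem_max = mp_mem_max, docked_pd_max = docked_pd_max,
                 docked_mem_max = docked_mem_max),
            class = "syn_pool_criteria")
}

#' Assign vesicles to pools
#'
#' Precedence: docked, then membrane-proximal, then ribbon-associated,
#' else unassigned. Docked vesicles always also satisfy the
#' membrane-proximal membrane criterion (2 nm < 50 nm).
#'
#' @param records Tibble with columns `id`, `dist_ribbon_nm`, `dist_pd_nm`,
#'   `dist_membrane_nm` (missing columns are only allowed when no
#'   criterion needs them).
#' @param criteria A [pool_criteria()].
#' @return `records` with a `pool` factor column.
#' @export
assign_vesicle_pools <- function(records, criteria = pool_criteria()) {
  need <- c("dist_ribbon_nm", "dist_pd_nm", "dist_membrane_nm")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste0("missing distance columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  records |>
    dplyr::mutate(pool = factor(dplyr::case_when(
      .data$dist_pd_nm <= criteria$docked_pd_max &
        .data$dist_membrane_nm <= criteria$docked_mem_max ~ "docked",
      .data$dist_pd_nm <= criteria$mp_pd_max &
        .data$dist_membrane_nm <= criteria$mp_mem_max ~ "membrane_proximal",
      .data$dist_ribbon_nm <= criteria$ribbon_assoc_max ~ "ribbon_associated",
      TRUE ~ "unassigned"
    ), levels = c("docked", "membrane_proximal", "ribbon_associated",
                  "unassigned")))
}

#' Docked versus nonattached classification (active-zone workflow)
#'
#' A vesicle is docked when there is no measurable gap between its membrane
#' and the active-zone membrane; at a voxel size of 1.554 nm such vesicles
#' fall into the 0-2 nm distance bin, hence the 2 nm default.
#'
#' @param records Tibble with an AZ distance column.
#' @param distance_col Name of that column.
#' @param docked_max Distance threshold in nm (inclusive).
#' @return `records` with a `docked_state` factor column.
#' @export
classify_docked_az <- function(records, distance_col = "dist_az_nm",
                               docked_max = 2) {
  if (!distance_col %in% names(records)) {
    abort(paste0("missing column: ", distance_col))
  }
  records |>
    dplyr::mutate(docked_state = factor(
      ifelse(.data[[distance_col]] <= docked_max, "docked", "nonattached"),
      levels = c("docked", "nonattached")))
}

#' Mesh surface area of a binary structure
#'
#' The mask is (optionally) Gaussian-smoothed and an iso-0.5 surface mesh
#' is extracted by a marching-tetrahedra scan (the marching-cubes family:
#' each grid cell is split into six tetrahedra with linearly interpolated
#' crossing points, which avoids the ambiguous cube cases); the area is
#' the sum of triangle areas with vertices scaled by the voxel size.
#' Smoothing matters for binary input: without it the iso-surface follows
#' the voxel staircase and overestimates curved areas.
#'
#' @param structure Binary mask (`syn_labels` or array), 3D.
#' @param voxel_size Per-axis voxel size in nm.
#' @param smooth_sigma Pre-smoothing SD in voxels (0 disables).
#' @return Surface area in nm^2.
#' @export
mesh_surface_area <- function(structure, voxel_size = NULL,
                              smooth_sigma = 1) {
  mask <- as_label_array(structure) > 0L
  if (!any(mask)) abort("empty mask has no surface")
  vs <- voxel_size %||%
    (if (inherits(structure, "syn_labels")) structure$voxel_size else
       abort("voxel_size required"))
  d <- dim(mask)
  if (length(d) != 3) abort("mesh surface area requires a 3D mask")
  # pad so surfaces at the volume border are closed
  m <- array(0, d + 2L)
  m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask)
  if (smooth_sigma > 0) {
    m <- array(gaussian_blur_cpp(m, dim(m), rep(smooth_sigma, 3)), dim(m))
  }
  mtetra_area_cpp(as.numeric(m), dim(m), 0.5, vs)
}

#' Area-normalised binned vesicle counts near the active zone
#'
#' Histogram of vesicle-to-AZ distances over half-open bins
#' `[e_i, e_{i+1})`, with each count normalised to the number of vesicles
#' per 0.01 um^2 of active-zone area.
#'
#' @param distances Vesicle distances in nm.
#' @param az_area Active-zone surface area in nm^2. The mesh-derived area
#'   is convention-sensitive; an externally measured area may be supplied
#'   instead.
#' @param bin_edges Ascending bin edges in nm (default the 0/5/10/20/30/40
#'   scheme).
#' @return A tibble: `bin`, `lower_nm`, `upper_nm`, `count`,
#'   `count_per_001um2`.
#' @export
binned_az_occupancy <- function(distances, az_area,
                                bin_edges = c(0, 5, 10, 20, 30, 40)) {
  if (az_area <= 0) abort("az_area must be positive")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort("bin edges must be strictly ascending")
  }
  nb <- length(bin_edges) - 1
  counts <- vapply(seq_len(nb), function(i)
    sum(distances >= bin_edges[i] & distances < bin_edges[i + 1]), 1.0)
  norm <- az_area / 1e4  # 0.01 um^2 = 1e4 nm^2
  tibble::tibble(
    bin = paste0("[", bin_edges[-length(bin_edges)], ",", bin_edges[-1], ")"),
    lower_nm = bin_edges[-length(bin_edges)],
    upper_nm = bin_edges[-1],
    count = counts,
    count_per_001um2 = counts / norm
  )
}

#' Restrict vesicles to the compartment containing most of them
#'
#' Selects the compartment overlapping the largest number of vesicle ids
#' (any shared voxel counts; ties go to the lower compartment id) and
#' drops vesicles that do not overlap it. An empty compartment map keeps
#' all vesicles and warns.
#'
#' @param vesicles A `syn_labels`.
#' @param compartments A `syn_labels` of compartment instances.
#' @return The filtered `syn_labels`.
#' @export
restrict_to_compartment <- function(vesicles, compartments) {
  stopifnot(inherits(vesicles, "syn_labels"))
  comp <- as_label_array(compartments)
  lab <- vesicles$labels
  stopifnot(identical(dim(comp), dim(lab)))
  if (!any(comp > 0L)) {
    warn("empty compartment map; keeping all vesicles")
    return(vesicles)
  }
  tab <- overlap_table_cpp(as.integer(comp), as.integer(lab))
  tab <- tab[tab[, 1] > 0 & tab[, 2] > 0, , drop = FALSE]
  if (nrow(tab) == 0) {
    warn("no vesicle overlaps any compartment; keeping all vesicles")
    return(vesicles)
  }
  per_comp <- tapply(tab[, 2], tab[, 1], function(v) length(unique(v)))
  best <- as.integer(names(per_comp)[which.max(per_comp)])
  keep_ids <- unique(tab[tab[, 1] == best, 2])
  out <- lab
  out[!(out %in% keep_ids)] <- 0L
  new_labels(out, vesicles$voxel_size)
}

#' Full vesicle table for a segmented synapse
#'
#' Convenience wrapper joining diameters, volumes and distances to the
#' supplied structures into one tidy per-vesicle table.
#'
#' @param vesicles A `syn_labels`.
#' @param structures Named list of binary structure masks; names become
#'   `dist_<name>_nm` columns.
#' @param criteria Optional [pool_criteria()]; when the required
#'   structures (ribbon, pd, membrane) are present, pools are assigned.
#' @return A tibble, one row per vesicle.
#' @export
vesicle_table <- function(vesicles, structures = list(), criteria = NULL) {
  tab <- measure_diameters(vesicles)
  for (nm in names(structures)) {
    dd <- measure_object_distances(vesicles, structures[[nm]], name = nm)
    names(dd)[2] <- paste0("dist_", nm, "_nm")
    tab <- dplyr::left_join(tab, dd, by = "id")
  }
  if (!is.null(criteria)) {
    tab <- assign_vesicle_pools(tab, criteria)
  }
  class(tab) <- c("syn_vesicle_table", class(tab))
  tab
}
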