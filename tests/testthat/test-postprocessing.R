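# Postprocessing: watershed instances, active-zone filtering, compartment
# merging, ribbon-structure selection.

test_that("watershed on oracle maps: isolated, touching and empty cases", {
  # isolated sphere: one instance equal to the foreground mask
  one <- generate_phantom(phantom_spec(shape = c(40, 40, 40), n_vesicles = 1,
                                       vesicle_radius_range = c(12, 12),
                                       seed = 5))
  maps <- render_oracle_maps(one$labels$vesicles)
  seg <- distance_watershed_instances(maps, watershed_params(0.5, 4, 0.5))
  expect_length(label_ids(seg), 1)
  expect_identical(seg$labels > 0L, maps$foreground > 0.5)

  # touching spheres at 1.9 radii, production vesicle preset: exactly two
  pair <- phantom_touching_pair(radius_nm = 17.5, separation_factor = 1.9)
  pseg <- distance_watershed_instances(render_oracle_maps(pair),
                                       watershed_preset("vesicles"))
  expect_length(label_ids(pseg), 2)
  mr <- matched_f1(pseg, pair)
  expect_true(all(mr$matches$iou > 0.5))
  expect_equal(mr$f1, 1)

  # all-zero foreground: empty segmentation, not an error
  zero <- new_maps(array(0, c(8, 8, 8)), array(0, c(8, 8, 8)), voxel_size = 1)
  expect_length(label_ids(distance_watershed_instances(zero)), 0)
})

test_that("watershed partitions the mask and preserves the seed count", {
  # radii from 10 nm up: every vesicle interior clears the 4-voxel seed
  # threshold, so each mask component is guaranteed a seed
  ph <- generate_phantom(phantom_spec(shape = c(64, 64, 64), n_vesicles = 15,
                                      vesicle_radius_range = c(10, 15),
                                      seed = 8))
  maps <- render_oracle_maps(ph$labels$vesicles)
  params <- watershed_params(0.5, 4, 0.5)
  seg <- distance_watershed_instances(maps, params)
  mask <- maps$foreground > params$foreground_threshold
  # instances partition the foreground mask exactly
  expect_identical(seg$labels > 0L, mask)
  # instance count equals seed-component count
  d <- dim(mask)
  dist_b <- sqrt(synrec:::edt_sq_cpp(maps$boundary > 0.5, d, c(1, 1, 1)))
  seeds <- array(synrec:::label_components_cpp(array(dist_b > 4, d), d, 2L), d)
  # seeds intersecting the mask (the far-from-everything background region
  # also seeds, but lies outside the foreground mask and yields no instance)
  expect_identical(length(label_ids(seg)),
                   length(setdiff(unique(seeds[mask]), 0L)))
})

test_that("active-zone size filter keeps >= 500-voxel components only", {
  d <- c(12, 24, 24)
  p <- array(0, d)
  p[2:4, 2:21, 2:21] <- 0.9   # 3*20*20 = 1200 voxels
  p[8:9, 2:11, 2:21] <- 0.9   # 2*10*20 = 400 voxels
  maps <- new_maps(p, array(0, d), voxel_size = 1)
  seg <- segment_active_zone(maps, threshold = 0.5, min_size = 500)
  expect_true(all(seg$labels[2:4, 2:21, 2:21] == 1L))
  expect_true(all(seg$labels[8:9, , ] == 0L))

  # below-threshold probabilities yield an empty mask
  low <- new_maps(array(0.49, d), array(0, d), voxel_size = 1)
  expect_identical(max(segment_active_zone(low)$labels), 0L)

  # a component of exactly 500 voxels survives (strict "smaller than")
  q <- array(0, c(10, 25, 10))
  q[3:7, 3:22, 4:8] <- 0  # placeholder block below
  q[1:5, 1:20, 1:5] <- 0.9  # 5*20*5 = 500
  m2 <- new_maps(q, array(0, dim(q)), voxel_size = 1)
  expect_identical(max(segment_active_zone(m2)$labels), 1L)
})

test_that("compartment merging: stacks merge, disjoint stacks stay apart", {
  d <- c(10, 32, 32)
  bd <- array(0, d)
  # boundary walls around one disc region per slice
  disc <- function(cy, cx, r) {
    m <- outer(((1:32) - cy)^2, ((1:32) - cx)^2, "+") <= r^2
    m
  }
  ring <- function(cy, cx, r) disc(cy, cx, r) & !disc(cy, cx, r - 2)
  for (z in 1:10) bd[z, , ][ring(16, 16, 12)] <- 1
  maps <- new_maps(array(0, d), bd, voxel_size = 1)
  seg <- segment_compartments(maps, compartment_params(
    slice_params = watershed_params(0.5, 3, 0.5)))
  inner <- array(FALSE, d)
  for (z in 1:10) inner[z, , ][disc(16, 16, 9)] <- TRUE
  expect_length(unique(seg$labels[inner]), 1)  # one stack, one label
  expect_true(all(seg$labels[inner] > 0L))

  # two laterally disjoint stacks -> two labels
  bd2 <- array(0, d)
  for (z in 1:10) {
    bd2[z, , ][ring(9, 9, 7)] <- 1
    bd2[z, , ][ring(24, 24, 7)] <- 1
  }
  # wall between the two discs so fragments cannot leak together
  maps2 <- new_maps(array(0, d), bd2, voxel_size = 1)
  seg2 <- segment_compartments(maps2, compartment_params(
    slice_params = watershed_params(0.5, 3, 0.5)))
  la <- unique(seg2$labels[cbind(1:10, 9, 9)])
  lb <- unique(seg2$labels[cbind(1:10, 24, 24)])
  expect_length(la, 1)
  expect_length(lb, 1)
  expect_false(la == lb)

  # z-order reversal yields the same clustering
  rev2 <- new_maps(array(0, d), bd2[10:1, , ], voxel_size = 1)
  segr <- segment_compartments(rev2, compartment_params(
    slice_params = watershed_params(0.5, 3, 0.5)))
  expect_identical(matched_f1(segr$labels[10:1, , ], seg2$labels)$f1, 1)
})

test_that("fragments with zero overlap are never merged", {
  d <- c(2, 16, 16)
  # boundary fills each slice except one disc interior: slice 1 has its
  # fragment left, slice 2 right, with zero vertical overlap
  bd <- array(1, d)
  bd[1, , ][outer(((1:16) - 8)^2, ((1:16) - 4)^2, "+") <= 3^2] <- 0
  bd[2, , ][outer(((1:16) - 8)^2, ((1:16) - 13)^2, "+") <= 3^2] <- 0
  maps <- new_maps(array(0, d), bd, voxel_size = 1)
  seg <- segment_compartments(maps, compartment_params(
    slice_params = watershed_params(0.5, 1.5, 0.5)))
  l1 <- seg$labels[1, 8, 4]
  l2 <- seg$labels[2, 8, 13]
  expect_true(l1 > 0L && l2 > 0L)
  expect_false(l1 == l2)
})

test_that("ribbon filtering keeps the vesicle-rich and ribbon-near components", {
  d <- c(24, 48, 48)
  vs <- 2  # nm per voxel
  ves <- array(0L, d)
  # thirty vesicles around (12, 12, 12), two far away
  set.seed(1)
  id <- 0L
  for (i in 1:30) {
    c0 <- pmin(pmax(round(c(12, 12, 12) + runif(3, -9, 9)), 2), 46)
    id <- id + 1L
    ves[c0[1], c0[2], c0[3]] <- id
  }
  for (i in 1:2) {
    id <- id + 1L
    ves[20, 40 + i, 40] <- id
  }
  ribbon_cand <- array(0L, d)
  ribbon_cand[10:14, 10:14, 10:14] <- 1L   # near the 30 vesicles
  ribbon_cand[18:22, 38:42, 38:42] <- 1L   # near the 2 vesicles
  pd_cand <- array(0L, d)
  pd_cand[16:17, 10:12, 10:12] <- 1L       # ~5 nm from chosen ribbon
  pd_cand[2:3, 30:32, 30:32] <- 1L         # far
  ves_lab <- new_labels(ves, vs)
  res <- filter_ribbon_structures(ribbon_cand, pd_cand, ves_lab,
                                  proximity_radius = 40)
  expect_true(all(res$ribbon$labels[10:14, 10:14, 10:14] == 1L))
  expect_true(all(res$ribbon$labels[18:22, 38:42, 38:42] == 0L))
  expect_true(all(res$presynaptic_density$labels[16:17, 10:12, 10:12] == 1L))
  expect_true(all(res$presynaptic_density$labels[2:3, 30:32, 30:32] == 0L))

  # no candidates: empty outputs with a warning status
  expect_warning(
    empty <- filter_ribbon_structures(array(0L, d), pd_cand, ves_lab),
    "no ribbon")
  expect_identical(max(empty$ribbon$labels), 0L)
})
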