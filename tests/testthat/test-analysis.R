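# Morphometry: distances, diameters, pools, areas, binned occupancy,
# compartment restriction.

test_that("structure distances: arithmetic, overlap, brute-force oracle", {
  d <- c(20, 20, 20)
  vs <- 1.554
  ves <- array(0L, d)
  ves[5, 5, 3] <- 1L           # 10 voxels from the structure plane along x
  st <- array(0L, d)
  st[, , 13:20] <- 1L
  tab <- measure_object_distances(new_labels(ves, vs), st)
  expect_equal(tab$distance_nm, 10 * 1.554, tolerance = 1e-9)

  # overlapping vesicle: zero distance
  ves2 <- array(0L, d)
  ves2[5, 5, 12:14] <- 2L
  t2 <- measure_object_distances(new_labels(ves2, vs), st)
  expect_equal(t2$distance_nm, 0)

  # brute-force agreement on irregular fixtures
  set.seed(9)
  lab <- random_label_fixture(d, 3, seed = 21)
  struct <- array(0L, d)
  struct[15:18, 2:6, 9:16] <- 1L
  lab[struct > 0L] <- 0L
  res <- measure_object_distances(new_labels(lab, vs), struct)
  for (r in seq_len(nrow(res))) {
    bf <- brute_force_min_distance(lab == res$id[r], struct > 0L,
                                   rep(vs, 3))
    expect_equal(res$distance_nm[r], bf, tolerance = 1e-9)
  }
  expect_error(measure_object_distances(new_labels(lab, vs),
                                        array(0L, d), name = "az"), "az")
})

test_that("distances are invariant under joint translation", {
  d <- c(24, 24, 24)
  ves <- array(0L, d); ves[4:6, 4:6, 4:6] <- 1L
  st <- array(0L, d); st[4:6, 4:6, 14:16] <- 1L
  t1 <- measure_object_distances(new_labels(ves, 1), st)
  sh <- function(a) { b <- array(0L, d); b[7:24, 7:24, 7:24] <- a[1:18, 1:18, 1:18]; b }
  t2 <- measure_object_distances(new_labels(sh(ves), 1), sh(st))
  expect_equal(t1$distance_nm, t2$distance_nm)
})

test_that("diameter recovery on spheres and anisotropic handling", {
  errs <- vapply(4:12, function(r) {
    set.seed(r)
    n <- 2 * r + 8
    g <- digital_sphere(n, n / 2 + runif(3), r)
    m <- measure_diameters(new_labels(g, 1.0))
    abs(m$diameter_nm - 2 * r)
  }, 1.0)
  expect_lt(max(errs), 1)  # within one voxel across radii

  # ellipsoid: inscribed sphere is governed by the smallest semi-axis
  n <- 28
  ctr <- n / 2 + 0.3
  g <- array(0L, c(n, n, n))
  for (k in 1:n) {
    g[, , k] <- as.integer(outer((((1:n) - ctr) / 10)^2,
                                 (((1:n) - ctr) / 6)^2, "+") +
                             ((k - ctr) / 6)^2 <= 1)
  }
  m <- measure_diameters(new_labels(g, 2.0))
  expect_lt(abs(m$diameter_nm - 2 * 6 * 2.0), 2 * 2.0)

  # single-voxel object: finite small diameter, volume = one voxel
  s <- array(0L, c(5, 5, 5)); s[3, 3, 3] <- 1L
  ms <- measure_diameters(new_labels(s, 1.5))
  expect_equal(ms$volume_nm3, 1.5^3)
  expect_equal(ms$diameter_nm, 2 * 1.5 + 0.75)  # 2*EDT + half-voxel term

  # volumes: voxel count times voxel volume
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48), n_vesicles = 5,
                                      seed = 13))
  mm <- measure_diameters(ph$labels$vesicles)
  counts <- table(ph$labels$vesicles$labels[ph$labels$vesicles$labels > 0])
  expect_equal(mm$volume_nm3, as.numeric(counts) * 1.554^3)
})

test_that("pool assignment reproduces the distance-rule truth table", {
  grid <- tidyr::expand_grid(
    dist_ribbon_nm = c(0, 40, 80, 81, 200),
    dist_pd_nm = c(0, 50, 100, 101, 300),
    dist_membrane_nm = c(0, 1, 2, 2.5, 30, 50, 51, 120)
  ) |> dplyr::mutate(id = dplyr::row_number())
  out <- assign_vesicle_pools(grid)
  ref <- with(grid, ifelse(
    dist_pd_nm <= 100 & dist_membrane_nm <= 2, "docked",
    ifelse(dist_pd_nm <= 100 & dist_membrane_nm <= 50, "membrane_proximal",
           ifelse(dist_ribbon_nm <= 80, "ribbon_associated", "unassigned"))))
  expect_identical(as.character(out$pool), ref)
  # every record gets exactly one pool
  expect_false(any(is.na(out$pool)))
  # docked records always satisfy the membrane-proximal membrane criterion
  docked <- out |> dplyr::filter(pool == "docked")
  expect_true(all(docked$dist_membrane_nm <= 50))
  # spec-quoted examples
  ex <- tibble::tibble(dist_ribbon_nm = c(70, 300, 300, 300),
                       dist_pd_nm = c(300, 90, 90, 300),
                       dist_membrane_nm = c(120, 1.5, 30, 120))
  expect_identical(as.character(assign_vesicle_pools(ex)$pool),
                   c("ribbon_associated", "docked", "membrane_proximal",
                     "unassigned"))
  expect_error(assign_vesicle_pools(ex[, 1:2]), "missing distance")
})

test_that("docked/nonattached split at the 0-2 nm bin", {
  rec <- tibble::tibble(id = 1:3, dist_az_nm = c(0, 1.554, 5))
  out <- classify_docked_az(rec)
  expect_identical(as.character(out$docked_state),
                   c("docked", "docked", "nonattached"))
})

test_that("mesh surface areas match analytic sphere and slab", {
  n <- 48
  g <- digital_sphere(n, rep(24.5, 3), 20)
  a <- mesh_surface_area(new_labels(g, 1))
  expect_lt(abs(a / (4 * pi * 20^2) - 1), 0.05)

  # 1-voxel-thick slab: area about twice the face area
  d <- c(40, 40, 3)
  slab <- array(0L, d)
  slab[, , 2] <- 1L
  as <- mesh_surface_area(new_labels(slab, 1), smooth_sigma = 0)
  expect_lt(abs(as / (2 * 40 * 40) - 1), 0.1)

  # voxel-size scaling
  a2 <- mesh_surface_area(new_labels(g, 2))
  expect_lt(abs(a2 / (4 * pi * 40^2) - 1), 0.05)
  expect_error(mesh_surface_area(new_labels(array(0L, c(4, 4, 4)), 1)),
               "empty")
})

test_that("binned occupancy normalises to counts per 0.01 um^2", {
  out <- binned_az_occupancy(c(1, 3, 7, 25), az_area = 2e4,
                             bin_edges = c(0, 5, 10, 20, 30, 40))
  expect_equal(out$count_per_001um2, c(1, 0.5, 0, 0.5, 0))
  zero <- binned_az_occupancy(numeric(0), az_area = 1e4)
  expect_true(all(zero$count == 0))
  ident <- binned_az_occupancy(c(1, 6), az_area = 1e4,
                               bin_edges = c(0, 5, 10))
  expect_equal(ident$count, ident$count_per_001um2)
  expect_error(binned_az_occupancy(1, 1e4, c(0, 10, 5)), "ascending")
  expect_error(binned_az_occupancy(1, 0), "positive")
})

test_that("compartment restriction keeps the vesicle-richest compartment", {
  d <- c(10, 30, 30)
  comp <- array(0L, d)
  comp[, 1:14, ] <- 1L
  comp[, 16:30, ] <- 2L
  ves <- array(0L, d)
  for (i in 1:10) ves[5, 2 + i, 5] <- i        # 10 in compartment 1
  ves[5, 20, 5] <- 11L; ves[5, 25, 5] <- 12L   # 2 in compartment 2
  out <- restrict_to_compartment(new_labels(ves, 1), new_labels(comp, 1))
  expect_setequal(label_ids(out), 1:10)

  # tie: lower compartment id wins
  ves_tie <- array(0L, d)
  for (i in 1:5) { ves_tie[5, 2 + i, 5] <- i; ves_tie[5, 19 + i, 5] <- 5L + i }
  out_tie <- restrict_to_compartment(new_labels(ves_tie, 1),
                                     new_labels(comp, 1))
  expect_setequal(label_ids(out_tie), 1:5)

  expect_warning(
    keep <- restrict_to_compartment(new_labels(ves, 1),
                                    new_labels(array(0L, d), 1)),
    "empty compartment")
  expect_setequal(label_ids(keep), 1:12)
})

test_that("cumulative distance curves are monotone and end at one", {
  set.seed(2)
  dists <- runif(40, 0, 100)
  p <- plot_cumulative_distances(dists)
  df <- p$data
  expect_true(!is.unsorted(df$cumulative))
  expect_equal(max(df$cumulative), 1)
  expect_true(!is.unsorted(df$distance_nm))
})

test_that("vesicle table joins measurements and assigns pools", {
  ph <- generate_phantom(phantom_spec(
    shape = c(48, 64, 64), n_vesicles = 8,
    structures = c("active_zone", "ribbon", "presynaptic_density"),
    seed = 4))
  tab <- vesicle_table(
    ph$labels$vesicles,
    structures = list(ribbon = ph$labels$ribbon,
                      pd = ph$labels$presynaptic_density,
                      membrane = ph$labels$active_zone),
    criteria = pool_criteria())
  expect_identical(nrow(tab), 8L)
  expect_true(all(c("diameter_nm", "volume_nm3", "dist_ribbon_nm",
                    "dist_pd_nm", "dist_membrane_nm", "pool") %in%
                    names(tab)))
  expect_false(any(is.na(tab$pool)))
  p <- autoplot(tab)
  expect_s3_class(p, "ggplot")
})
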