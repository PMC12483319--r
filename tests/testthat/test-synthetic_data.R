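# Phantom generator: geometry, determinism, oracle maps, domain shifts.

test_that("phantom vesicles are disjoint, counted, and deterministic", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_vesicles = 20,
                       vesicle_radius_range = c(8, 15), seed = 42)
  ph <- generate_phantom(spec)
  ids <- label_ids(ph$labels$vesicles)
  expect_length(ids, 20)
  # exhaustive pairwise-overlap check: every voxel carries at most one id,
  # and no two spheres touch (centre distance exceeds the radius sum)
  ctr <- ph$vesicle_centers
  rad <- ph$vesicle_radii_vx
  for (i in 1:19) {
    for (j in (i + 1):20) {
      expect_gt(sqrt(sum((ctr[i, ] - ctr[j, ])^2)), rad[i] + rad[j])
    }
  }
  ph2 <- generate_phantom(spec)
  expect_identical(ph2$volume$data, ph$volume$data)
  expect_identical(ph2$labels$vesicles$labels, ph$labels$vesicles$labels)

  empty <- generate_phantom(phantom_spec(n_vesicles = 0, seed = 1))
  expect_identical(label_ids(empty$labels$vesicles), integer(0))
})

test_that("rendered membrane geometry is consistent with the labels", {
  # the dark rim centroid of an isolated sphere lies on the label surface
  spec <- phantom_spec(shape = c(48, 48, 48), n_vesicles = 1,
                       vesicle_radius_range = c(12, 12), noise_sd = 0,
                       seed = 3)
  ph <- generate_phantom(spec)
  dark <- ph$volume$data < 0.5 & ph$labels$vesicles$labels > 0L
  pts <- which(dark, arr.ind = TRUE)
  ctr <- ph$vesicle_centers[1, ]
  radial <- sqrt(rowSums((t(t(pts) - ctr))^2))
  r_vx <- ph$vesicle_radii_vx[1]
  expect_lt(abs(mean(radial) - (r_vx - 1)), 1.5)  # membrane hugs the surface
})

test_that("structures are rendered with distinct label volumes", {
  spec <- phantom_spec(shape = c(48, 64, 64), n_vesicles = 5,
                       structures = c("active_zone", "compartments",
                                      "ribbon", "presynaptic_density",
                                      "mitochondrion"),
                       seed = 7)
  ph <- generate_phantom(spec)
  expect_setequal(names(ph$labels),
                  c("vesicles", "active_zone", "compartments", "ribbon",
                    "presynaptic_density", "mitochondrion"))
  expect_identical(sort(unique(as.integer(ph$labels$compartments$labels))),
                   c(0L, 1L, 2L))
  expect_true(any(ph$labels$active_zone$labels > 0L))
})

test_that("oracle maps put unit boundary on rims and nothing elsewhere", {
  spec <- phantom_spec(shape = c(40, 40, 40), n_vesicles = 1,
                       vesicle_radius_range = c(10, 10), seed = 5)
  ph <- generate_phantom(spec)
  maps <- render_oracle_maps(ph$labels$vesicles, rim_width = 2)
  lab <- ph$labels$vesicles$labels
  expect_identical(maps$foreground > 0.5, lab > 0L)
  # boundary support: only within rim_width of the surface, inside the label
  # rim_width is a Chebyshev radius: reach extends to 2*sqrt(3) Euclidean
  interior <- sqrt(edt_voxels(lab == 0L)) > 2 * sqrt(3)
  expect_true(all(maps$boundary[lab == 0L] == 0))
  expect_true(all(maps$boundary[interior & lab > 0L] == 0))
  expect_true(all(maps$boundary >= 0 & maps$boundary <= 1))

  empty <- render_oracle_maps(new_labels(array(0L, c(8, 8)), 1))
  expect_true(all(empty$foreground == 0) && all(empty$boundary == 0))
  expect_error(render_oracle_maps(ph$labels$vesicles, rim_width = 0),
               "rim_width")
})

test_that("domain shift: identity at zero, calibrated noise, determinism", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48), n_vesicles = 8,
                                      seed = 2))
  id <- apply_domain_shift(ph$volume, domain_shift_spec())
  expect_identical(id$data, ph$volume$data)

  const <- new_volume(array(0.5, c(50, 50, 50)), 1)
  noisy <- apply_domain_shift(const, domain_shift_spec(noise_scale = 0.15,
                                                       seed = 9))
  expect_lt(abs(stats::sd(noisy$data) / 0.15 - 1), 0.05)  # >= 1e5 voxels

  s <- domain_shift_spec(blur_sigma = 1.5, noise_scale = 0.05, seed = 4)
  a <- apply_domain_shift(ph$volume, s)
  b <- apply_domain_shift(ph$volume, s)
  expect_identical(a$data, b$data)
})

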