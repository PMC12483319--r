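# UNet architecture contracts, analytic gradients, loss/scheduler
# behaviour, and tiled prediction.

test_that("architecture: widths, downsample factors, output contract", {
  cfg <- unet_config(dimensionality = 3, levels = 4, initial_features = 32)
  expect_identical(cfg$widths, c(32L, 64L, 128L, 256L))
  expect_identical(cfg$pool_factors,
                   list(c(1L, 2L, 2L), c(2L, 2L, 2L), c(2L, 2L, 2L)))

  m <- build_unet(unet_config(dimensionality = 3, levels = 3,
                              initial_features = 8), seed = 1)
  x <- array(rnorm(8 * 16 * 16), c(8, 16, 16))
  fw <- synrec:::unet_forward(m, x)
  expect_identical(nrow(fw$prob), 8L * 16L * 16L)  # spatial shape preserved
  expect_identical(ncol(fw$prob), 2L)
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))

  # patch shape must divide by the cumulative downsampling
  expect_error(synrec:::unet_forward(m, array(0, c(7, 16, 16))),
               "divisible")
})

test_that("backprop matches numerical gradients on a small network", {
  cfg <- unet_config(dimensionality = 2, levels = 3, initial_features = 4)
  m <- build_unet(cfg, seed = 7)
  set.seed(1)
  x <- array(rnorm(16 * 16), c(16, 16))
  tg <- matrix(as.numeric(runif(16 * 16 * 2) > 0.5), 256, 2)
  fw <- synrec:::unet_forward(m, x, keep_cache = TRUE)
  ls <- synrec:::dice_loss(fw$prob, tg)
  g <- synrec:::unet_backward(m, fw, ls$grad)
  eps <- 1e-6
  for (nm in c("enc1_c1_W", "enc3_c2_W", "dec1_c1_W", "out_W", "dec2_c2_b")) {
    i <- 3L
    mp <- m
    mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    fw2 <- synrec:::unet_forward(mp, x)
    num <- (synrec:::dice_loss(fw2$prob, tg)$loss - ls$loss) / eps
    expect_equal(g[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("negative Dice loss is -1 for a perfect prediction", {
  tg <- matrix(c(rep(1, 10), rep(0, 22)), 16, 2)
  ls <- synrec:::dice_loss(tg, tg)
  expect_equal(ls$loss, -1, tolerance = 1e-5)
})

test_that("plateau schedule halves the rate exactly once on constant loss", {
  st <- synrec:::plateau_init()
  lr <- 1e-3
  for (epoch in 1:6) {  # constant-loss stub, patience 5
    st <- synrec:::plateau_step(st, loss = 1, lr = lr, factor = 0.5,
                                patience = 5)
    lr <- st$lr
  }
  expect_equal(lr, 5e-4)  # halved once, not twice
  # an improving loss resets the counter and keeps the rate
  st2 <- synrec:::plateau_init()
  lr2 <- 1e-3
  for (loss in c(1, 0.9, 0.8, 0.7, 0.6, 0.5)) {
    st2 <- synrec:::plateau_step(st2, loss, lr2, 0.5, 5)
    lr2 <- st2$lr
  }
  expect_equal(lr2, 1e-3)
})

test_that("training on oracle phantoms reduces the validation loss", {
  phs <- lapply(1:5, function(s) {
    ph <- generate_phantom(phantom_spec(shape = c(64, 64), n_vesicles = 5,
                                        vesicle_radius_range = c(8, 13),
                                        seed = s))
    list(volume = ph$volume, labels = ph$labels$vesicles)
  })
  model <- build_unet(unet_config(dimensionality = 2, levels = 3,
                                  initial_features = 8), seed = 2)
  cfg <- train_config(iterations = 60, iters_per_epoch = 20,
                      patch_shape = c(64, 64), learning_rate = 1e-3,
                      seed = 3)
  tm <- train_supervised(model, phs, cfg)
  log <- tidy(tm)
  expect_identical(nrow(log), 3L)
  expect_lt(log$val_loss[nrow(log)], log$val_loss[1])
  expect_error(train_supervised(model, list(), cfg), "empty")
})

test_that("tiled prediction is seamless and shape preserving", {
  ph <- generate_phantom(phantom_spec(shape = c(96, 96), n_vesicles = 8,
                                      vesicle_radius_range = c(8, 15),
                                      seed = 11))
  m <- build_unet(unet_config(dimensionality = 2, levels = 3,
                              initial_features = 8), seed = 4)
  # halo of 24 exceeds the one-sided receptive field of the 3-level net,
  # so tiling must be exactly seamless
  whole <- predict_tiled(m, ph$volume, halo = 24)
  expect_identical(dim(whole$foreground), c(96L, 96L))
  expect_true(all(whole$foreground >= 0 & whole$foreground <= 1))
  tiled <- predict_tiled(m, ph$volume, tile_shape = c(48, 48), halo = 24)
  expect_lt(max(abs(tiled$foreground - whole$foreground)), 1e-4)
  expect_lt(max(abs(tiled$boundary - whole$boundary)), 1e-4)
})

test_that("checkpoints are self-describing and round trip", {
  m <- build_unet(unet_config(dimensionality = 2, levels = 2,
                              initial_features = 4), seed = 9)
  m$voxel_size <- c(1.554, 1.554)
  p <- file.path(withr::local_tempdir(), "model.rds")
  save_model(m, p)
  back <- load_model(p)
  expect_identical(back$params, m$params)
  expect_identical(back$cfg$widths, m$cfg$widths)
  expect_identical(back$voxel_size, m$voxel_size)
})
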