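# Mean-teacher mechanics: confidence masking, EMA arithmetic, masked-loss
# gradients, and adaptation contracts.

test_that("confidence mask keeps confident voxels with strict inequalities", {
  expect_equal(as.numeric(confidence_mask(c(0.9, 0.5, 0.1), 0.75)),
               c(1, 0, 1))
  # the limit case selects everything except exactly 0.5
  expect_equal(as.numeric(confidence_mask(c(0.2, 0.5, 0.8), 0.5)),
               c(1, 0, 1))
  # boundary values are excluded (strict)
  expect_equal(as.numeric(confidence_mask(rep(0.75, 4), 0.75)), rep(0, 4))
  expect_equal(as.numeric(confidence_mask(rep(0.25, 4), 0.75)), rep(0, 4))
  expect_error(confidence_mask(0.5, 0.4), "t_c")
  expect_error(confidence_mask(0.5, 1), "t_c")
})

test_that("EMA update arithmetic and fixed points", {
  m <- build_unet(unet_config(dimensionality = 2, levels = 2,
                              initial_features = 2), seed = 1)
  pair <- ts_pair(m)
  expect_identical(pair$teacher, pair$student)  # initialisation contract

  pair$teacher <- lapply(pair$teacher, function(p) p * 0 + 1)
  pair$student <- lapply(pair$student, function(p) p * 0)
  up <- ema_update(pair, 0.999)
  expect_equal(up$teacher[[1]][1], 0.999)
  expect_identical(up$student, pair$student)  # student untouched

  up0 <- ema_update(pair, 0)
  expect_equal(up0$teacher, pair$student)  # alpha 0 copies the student

  fixed <- pair
  fixed$student <- fixed$teacher
  upf <- ema_update(fixed, 0.7)
  expect_equal(upf$teacher, fixed$teacher)  # w_t = w_s is a fixed point

  # teacher moves by at most (1 - alpha) * max|w_s - w_t| elementwise
  set.seed(2)
  pair$student <- lapply(pair$student, function(p) p + rnorm(length(p)))
  a <- 0.99
  upd <- ema_update(pair, a)
  for (nm in names(pair$teacher)) {
    delta <- abs(upd$teacher[[nm]] - pair$teacher[[nm]])
    bound <- (1 - a) * max(abs(pair$student[[nm]] - pair$teacher[[nm]]))
    expect_true(all(delta <= bound + 1e-12))
  }
})

test_that("masked Dice loss has zero gradient on masked-out voxels", {
  set.seed(5)
  pred <- matrix(runif(40), 20, 2)
  tgt <- matrix(runif(40) > 0.5, 20, 2) * 1
  mask <- matrix(0, 20, 2)
  mask[c(1:5, 25:30)] <- 1
  ls <- synrec:::dice_loss(pred, tgt, mask = mask)
  expect_true(all(ls$grad[mask == 0] == 0))
  expect_true(any(ls$grad[mask == 1] != 0))
  # and the loss value ignores masked-out voxels entirely
  pred2 <- pred
  pred2[mask == 0] <- runif(sum(mask == 0))
  expect_equal(synrec:::dice_loss(pred2, tgt, mask = mask)$loss, ls$loss)
})

test_that("adaptation contracts: initialisation, degenerate fixed point", {
  ph <- generate_phantom(phantom_spec(shape = c(64, 64), n_vesicles = 5,
                                      vesicle_radius_range = c(8, 13),
                                      seed = 31))
  m <- build_unet(unet_config(dimensionality = 2, levels = 3,
                              initial_features = 8), seed = 3)
  # iteration 0: the teacher equals the pretrained model
  pair <- ts_pair(m)
  fw0 <- synrec:::unet_forward(synrec:::model_with(m, pair$teacher),
                               array(synrec:::normalize_input(ph$volume$data),
                                     dim(ph$volume$data)))
  fw1 <- synrec:::unet_forward(m, array(synrec:::normalize_input(ph$volume$data),
                                        dim(ph$volume$data)))
  expect_identical(fw0$prob, fw1$prob)

  # alpha = 1 with zero learning rate: teacher constant across iterations
  res <- adapt_model(m, list(ph$volume),
                     da_config(alpha = 1, learning_rate = 0,
                               iterations = 3, patch_shape = c(64, 64),
                               seed = 2))
  expect_equal(res$model$params, m$params)
  expect_error(adapt_model(m, list(), da_config()), "empty")
})

test_that("adaptation on confident targets decreases the masked loss", {
  # noiseless smoke test: blur-shifted phantoms, few iterations, loss trend
  phs <- lapply(41:43, function(s) {
    ph <- generate_phantom(phantom_spec(shape = c(64, 64), n_vesicles = 5,
                                        vesicle_radius_range = c(8, 13),
                                        noise_sd = 0.05, seed = s))
    apply_domain_shift(ph$volume, domain_shift_spec(blur_sigma = 1.5,
                                                    seed = s))
  })
  m <- build_unet(unet_config(dimensionality = 2, levels = 3,
                              initial_features = 8), seed = 4)
  res <- adapt_model(m, phs,
                     da_config(iterations = 30, patch_shape = c(64, 64),
                               noise_range = c(0, 0), blur_range = c(0, 0),
                               learning_rate = 1e-3, seed = 5))
  log <- res$log[!is.na(res$log$loss), ]
  first <- mean(head(log$loss, 5))
  last <- mean(tail(log$loss, 5))
  expect_lt(last, first + 1e-6)
})
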