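# Shared desk-scale training fixtures. Training is expensive, so the smoke
# model and phantom sets are built once per test run and memoised; both the
# supervised and the domain-adaptation checks reuse them.

.train_cache <- new.env(parent = emptyenv())

smoke_phantom_2d <- function(seed, noise_sd = 0.1) {
  generate_phantom(phantom_spec(shape = c(96, 96), n_vesicles = 12,
                                vesicle_radius_range = c(8, 15),
                                noise_sd = noise_sd, seed = seed))
}

# phantom watershed preset: seed distance scaled to the 8-15 nm phantom
# vesicles (the production preset value 8 assumes 30-50 nm vesicles)
phantom_ws_params <- function() watershed_params(0.5, 4, 0.5)

smoke_training_sets <- function() {
  if (is.null(.train_cache$sets)) {
    train <- lapply(1:10, function(s) {
      ph <- smoke_phantom_2d(s)
      list(volume = ph$volume, labels = ph$labels$vesicles)
    })
    test <- lapply(11:15, smoke_phantom_2d)
    .train_cache$sets <- list(train = train, test = test)
  }
  .train_cache$sets
}

smoke_trained_model <- function() {
  if (is.null(.train_cache$model)) {
    sets <- smoke_training_sets()
    model <- build_unet(unet_config(dimensionality = 2), seed = 1)
    cfg <- train_config(iterations = 600, iters_per_epoch = 50,
                        patch_shape = c(64, 64), learning_rate = 1e-4,
                        seed = 1)
    .train_cache$model <- train_supervised(model, sets$train, cfg)
  }
  .train_cache$model
}

held_out_f1 <- function(model, phantoms, params = phantom_ws_params()) {
  vapply(phantoms, function(ph) {
    maps <- predict_tiled(model, ph$volume)
    seg <- distance_watershed_instances(maps, params)
    matched_f1(seg, ph$labels$vesicles)$f1
  }, 1.0)
}
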