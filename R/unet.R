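# 2D/3D UNet for foreground + boundary prediction, implemented directly on
# dense GEMM-based convolution primitives (src/nn.cpp). Feature maps are
# (npix x channels) matrices whose rows follow R's array linear order; the
# encoder downsamples by max pooling, the decoder upsamples by nearest
# neighbour and concatenates skip features; all outputs are sigmoid-bounded.

#' UNet architecture configuration
#'
#' The default architecture has four levels and 32 initial features, with
#' feature width doubling per level (widths 32, 64, 128, 256). For 3D
#' networks the first downsampling step is in-plane only (factors (1, 2, 2)),
#' accounting for the smaller depth extent and the missing-wedge elongation
#' of tomograms; later steps are isotropic.
#'
#' @param dimensionality 2 or 3.
#' @param levels Number of levels (>= 2).
#' @param initial_features Feature width of the first level.
#' @param feature_growth Width growth factor per level.
#' @param anisotropic_first_downsample 3D only: first pooling in-plane.
#' @param out_channels Character vector naming the semantic output channels,
#'   e.g. `c("foreground", "boundary")`; may include `"boundary_distance"`
#'   for the compartment variant.
#' @param in_channels Number of input channels (1 for raw data).
#' @return A `syn_unet_config`.
#' @export
unet_config <- function(dimensionality = 3, levels = 4, initial_features = 32,
                        feature_growth = 2,
                        anisotropic_first_downsample = dimensionality == 3,
                        out_channels = c("foreground", "boundary"),
                        in_channels = 1) {
  stopifnot(dimensionality %in% 2:3, levels >= 2, initial_features >= 1,
            feature_growth >= 1, length(out_channels) >= 1)
  widths <- as.integer(round(initial_features * feature_growth^(0:(levels - 1))))
  nd <- dimensionality
  factors <- lapply(seq_len(levels - 1), function(l) {
    if (nd == 3 && anisotropic_first_downsample && l == 1) c(1L, 2L, 2L)
    else rep(2L, nd)
  })
  structure(
    list(dimensionality = nd, levels = levels,
         initial_features = initial_features, feature_growth = feature_growth,
         anisotropic_first_downsample = anisotropic_first_downsample,
         out_channels = out_channels, in_channels = in_channels,
         widths = widths, pool_factors = factors),
    class = "syn_unet_config"
  )
}

#' Build a UNet with randomly initialised weights
#'
#' @param cfg A [unet_config()].
#' @param seed Seed for the (He-scaled) weight initialisation.
#' @return A `syn_unet` model object.
#' @export
build_unet <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "syn_unet_config"))
  nd <- cfg$dimensionality
  K <- 3^nd
  w <- cfg$widths
  L <- cfg$levels
  params <- list()
  add_conv <- function(params, name, cin, cout, k) {
    sd <- sqrt(2 / (cin * k))
    params[[paste0(name, "_W")]] <- matrix(rnorm(cin * k * cout, sd = sd),
                                           cin * k, cout)
    params[[paste0(name, "_b")]] <- rep(0, cout)
    params
  }
  params <- with_seed(seed, function() {
    p <- list()
    for (l in seq_len(L)) {
      cin <- if (l == 1) cfg$in_channels else w[l - 1]
      p <- add_conv(p, paste0("enc", l, "_c1"), cin, w[l], K)
      p <- add_conv(p, paste0("enc", l, "_c2"), w[l], w[l], K)
    }
    for (l in rev(seq_len(L - 1))) {
      p <- add_conv(p, paste0("dec", l, "_c1"), w[l + 1] + w[l], w[l], K)
      p <- add_conv(p, paste0("dec", l, "_c2"), w[l], w[l], K)
    }
    add_conv(p, "out", w[1], length(cfg$out_channels), 1)
  })
  structure(list(cfg = cfg, params = params, voxel_size = NULL,
                 log = NULL),
            class = "syn_unet")
}

#' @export
print.syn_unet <- function(x, ...) {
  npar <- sum(vapply(x$params, length, 1L))
  cat("<syn_unet> ", x$cfg$dimensionality, "D, ", x$cfg$levels, " levels, ",
      "widths ", paste(x$cfg$widths, collapse = "/"), ", ",
      format(npar, big.mark = ","), " parameters; channels: ",
      paste(x$cfg$out_channels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_patch_shape <- function(cfg, dims) {
  total <- rep(1L, cfg$dimensionality)
  for (f in cfg$pool_factors) total <- total * f
  if (any(dims %% total != 0)) {
    abort(paste0("patch shape (", paste(dims, collapse = ", "),
                 ") must be divisible by the cumulative downsampling (",
                 paste(total, collapse = ", "), ")"))
  }
}

# Forward pass. x: numeric array (spatial dims) or (npix x C) matrix with
# dims supplied. Returns probabilities and, if keep_cache, everything the
# backward pass needs.
unet_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg
  nd <- cfg$dimensionality
  if (is.array(x) || is.matrix(x)) {
    if (is.matrix(x) && !is.null(attr(x, "spatial_dims"))) {
      dims <- attr(x, "spatial_dims")
      X <- x
    } else {
      dims <- dim(x)
      if (length(dims) != nd) abort("input dimensionality mismatch")
      X <- matrix(as.numeric(x), ncol = cfg$in_channels)
    }
  } else abort("input must be an array")
  check_patch_shape(cfg, dims)
  p <- model$params
  L <- cfg$levels
  ops <- list()
  skips <- vector("list", L)
  sdims <- vector("list", L)
  cur <- X
  curdim <- dims
  conv_relu <- function(name, cur, curdim) {
    Z <- conv_fw_cpp(cur, curdim, p[[paste0(name, "_W")]],
                     p[[paste0(name, "_b")]], 3L)
    Y <- Z * (Z > 0)
    if (keep_cache) {
      ops[[length(ops) + 1]] <<- list(type = "conv_relu", name = name,
                                      X = cur, dims = curdim, Y = Y)
    }
    Y
  }
  for (l in seq_len(L)) {
    cur <- conv_relu(paste0("enc", l, "_c1"), cur, curdim)
    cur <- conv_relu(paste0("enc", l, "_c2"), cur, curdim)
    skips[[l]] <- cur
    sdims[[l]] <- curdim
    if (l < L) {
      pl <- maxpool_fw_cpp(cur, curdim, cfg$pool_factors[[l]])
      if (keep_cache) {
        ops[[length(ops) + 1]] <- list(type = "pool", l = l, idx = pl$idx,
                                       n_in = nrow(cur))
      }
      cur <- pl$Y
      curdim <- as.integer(pl$out_dim)
    }
  }
  for (l in rev(seq_len(L - 1))) {
    up <- upsample_fw_cpp(cur, curdim, cfg$pool_factors[[l]])
    if (keep_cache) {
      ops[[length(ops) + 1]] <- list(type = "up_concat", l = l,
                                     dim_low = curdim,
                                     factors = cfg$pool_factors[[l]],
                                     n_up = ncol(cur))
    }
    cur <- cbind(up, skips[[l]])
    curdim <- sdims[[l]]
    cur <- conv_relu(paste0("dec", l, "_c1"), cur, curdim)
    cur <- conv_relu(paste0("dec", l, "_c2"), cur, curdim)
  }
  Z <- conv_fw_cpp(cur, curdim, p$out_W, p$out_b, 1L)
  if (keep_cache) {
    ops[[length(ops) + 1]] <- list(type = "out", X = cur, dims = curdim)
  }
  P <- 1 / (1 + exp(-Z))
  list(prob = P, dims = curdim, cache = if (keep_cache) ops else NULL)
}

# Backward pass from dL/dP. Returns gradients named like params.
unet_backward <- function(model, fw, dP) {
  p <- model$params
  P <- fw$prob
  dZ <- dP * P * (1 - P)
  grads <- list()
  pend <- list()  # skip-connection gradients waiting for the encoder side
  d <- dZ
  for (op in rev(fw$cache)) {
    if (op$type == "out") {
      g <- conv_bw_cpp(op$X, op$dims, p$out_W, d, 1L)
      grads$out_W <- g$dW
      grads$out_b <- as.numeric(g$db)
      d <- g$dX
    } else if (op$type == "conv_relu") {
      dZl <- d * (op$Y > 0)
      g <- conv_bw_cpp(op$X, op$dims, p[[paste0(op$name, "_W")]], dZl, 3L)
      grads[[paste0(op$name, "_W")]] <- g$dW
      grads[[paste0(op$name, "_b")]] <- as.numeric(g$db)
      d <- g$dX
    } else if (op$type == "up_concat") {
      dUp <- d[, seq_len(op$n_up), drop = FALSE]
      dSkip <- d[, -seq_len(op$n_up), drop = FALSE]
      pend[[as.character(op$l)]] <- dSkip
      d <- upsample_bw_cpp(dUp, op$dim_low, op$factors)
    } else if (op$type == "pool") {
      d <- maxpool_bw_cpp(d, op$idx, op$n_in)
      key <- as.character(op$l)
      if (!is.null(pend[[key]])) {
        d <- d + pend[[key]]
        pend[[key]] <- NULL
      }
    }
  }
  grads
}

# Soft Dice loss (negative Dice), optionally restricted to a confidence
# mask. pred/target: (npix x C). Perfect overlap gives -1.
dice_loss <- function(pred, target, mask = NULL) {
  eps <- 1e-6
  C <- ncol(pred)
  loss <- 0
  grad <- matrix(0, nrow(pred), C)
  for (c in seq_len(C)) {
    pc <- pred[, c]
    tc <- target[, c]
    m <- if (is.null(mask)) 1 else mask[, c]
    num <- 2 * sum(m * pc * tc) + eps
    den <- sum(m * pc) + sum(m * tc) + eps
    loss <- loss - num / den
    grad[, c] <- -((2 * tc * den - num) * m) / den^2
  }
  list(loss = loss / C, grad = grad / C)
}

# AdamW with decoupled weight decay (beta 0.9/0.999, eps 1e-8).
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: they carry the architecture
#' configuration, the training voxel size and the training log alongside
#' the weights.
#'
#' @param model A `syn_unet`.
#' @param path Destination file.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "syn_unet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "syn_unet")) abort("not a syn_unet checkpoint")
  model
}
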