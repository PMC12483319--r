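# Unsupervised mean-teacher domain adaptation. A pretrained network is
# duplicated into a teacher and a student; the student learns from the
# teacher's confident predictions (pseudo-labels) on unannotated target
# data, and the teacher tracks the student by an exponential moving
# average, gradually improving the pseudo-labels.

#' Domain-adaptation configuration
#'
#' The confidence threshold `t_c = 0.75` and EMA coefficient
#' `alpha = 0.999` are the settings used for all reference experiments;
#' augmentations are Gaussian blur with bandwidth drawn uniformly from
#' `blur_range` (voxels) and additive Gaussian noise with SD drawn from
#' `noise_range` (fraction of the patch data range). Optimisation mirrors
#' the supervised recipe (AdamW, learning rate 1e-4), re-instantiated
#' fresh for adaptation.
#'
#' @param t_c Confidence threshold in `[0.5, 1)`.
#' @param alpha Teacher EMA coefficient in `[0, 1]`.
#' @param blur_range,noise_range Augmentation sampling intervals.
#' @param iterations Number of student update steps.
#' @param patch_shape Patch extracted from target volumes.
#' @param batch_size Patches per step.
#' @param learning_rate AdamW step size for the student.
#' @param seed Seed for sampling and augmentation draws.
#' @return A `syn_da_config`.
#' @export
da_config <- function(t_c = 0.75, alpha = 0.999, blur_range = c(0, 2.5),
                      noise_range = c(0, 0.15), iterations = 500,
                      patch_shape = c(64, 64), batch_size = 1,
                      learning_rate = 1e-4, seed = 1) {
  if (t_c < 0.5 || t_c >= 1) abort("t_c must lie in [0.5, 1)")
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  structure(
    list(t_c = t_c, alpha = alpha, blur_range = blur_range,
         noise_range = noise_range, iterations = iterations,
         patch_shape = as.integer(patch_shape),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "syn_da_config"
  )
}

#' Confidence mask of a teacher prediction
#'
#' Selects the voxels the teacher is confident about: probability strictly
#' above `t_c` (confident foreground) or strictly below `1 - t_c`
#' (confident background). Only these voxels contribute to the
#' pseudo-label loss.
#'
#' @param probs Probability array/matrix in `[0, 1]`.
#' @param t_c Confidence threshold in `[0.5, 1)`.
#' @return Binary mask of the same shape.
#' @export
confidence_mask <- function(probs, t_c = 0.75) {
  if (t_c < 0.5 || t_c >= 1) abort("t_c must lie in [0.5, 1)")
  out <- (probs > t_c) | (probs < 1 - t_c)
  storage.mode(out) <- "double"
  out
}

#' Teacher-student weight pair
#'
#' At initialisation both members carry the pretrained weights.
#'
#' @param model A pretrained `syn_unet`.
#' @return A `syn_ts_pair` with `teacher` and `student` parameter lists.
#' @export
ts_pair <- function(model) {
  stopifnot(inherits(model, "syn_unet"))
  structure(list(teacher = model$params, student = model$params,
                 iteration = 0L, cfg = model$cfg,
                 voxel_size = model$voxel_size),
            class = "syn_ts_pair")
}

#' Exponential-moving-average teacher update
#'
#' `w_t <- alpha * w_t + (1 - alpha) * w_s`, elementwise; the student is
#' unchanged.
#'
#' @param pair A [ts_pair()].
#' @param alpha EMA coefficient.
#' @return The updated pair.
#' @export
ema_update <- function(pair, alpha) {
  stopifnot(inherits(pair, "syn_ts_pair"))
  pair$teacher <- purrr::map2(pair$teacher, pair$student,
                              function(t, s) alpha * t + (1 - alpha) * s)
  pair$iteration <- pair$iteration + 1L
  pair
}

#' Adapt a pretrained model to an unannotated target domain
#'
#' Per iteration: a target patch is sampled; the teacher predicts on the
#' original patch (no gradients) and the confidence mask selects reliable
#' pseudo-label voxels channelwise; the student predicts on an augmented
#' copy (blur + noise) and is updated by the masked negative-Dice loss
#' against the teacher's continuous probabilities; finally the teacher
#' tracks the student by EMA. Returns the final teacher.
#'
#' The asymmetry direction -- clean view to the teacher, corrupted view to
#' the student -- is the consistency-training formulation: the teacher's
#' pseudo-labels come from the most reliable view while the student is
#' forced to reproduce them under corruption. The opposite assignment
#' (teacher on augmented input) degrades the pseudo-labels themselves and
#' collapses the student on blur-shifted data; see the methods vignette.
#'
#' @param pretrained A trained `syn_unet`.
#' @param target_volumes List of `syn_volume`s from the target domain
#'   (no annotations).
#' @param cfg A [da_config()].
#' @return A list with `model` (adapted teacher as `syn_unet`), `log`
#'   (tibble: iteration, loss, masked fraction) and `pair` (final
#'   teacher/student weights).
#' @export
adapt_model <- function(pretrained, target_volumes, cfg = da_config()) {
  stopifnot(inherits(pretrained, "syn_unet"))
  if (length(target_volumes) == 0) abort("empty target volume set")
  with_seed(cfg$seed, function() adapt_model_impl(pretrained, target_volumes,
                                                  cfg))
}

adapt_model_impl <- function(pretrained, target_volumes, cfg) {
  patch <- cfg$patch_shape
  check_patch_shape(pretrained$cfg, patch)
  vols <- lapply(target_volumes, function(v) v$data)
  pair <- ts_pair(pretrained)
  opt <- adamw_init(pair$student)
  log <- vector("list", cfg$iterations)
  skipped <- 0L
  for (it in seq_len(cfg$iterations)) {
    gacc <- NULL
    lacc <- 0
    macc <- 0
    used <- 0L
    for (b in seq_len(cfg$batch_size)) {
      v <- vols[[sample.int(length(vols), 1L)]]
      org <- sample_patch_origin(dim(v), patch)
      raw <- extract_patch(v, org, patch)
      sg <- runif(1, cfg$blur_range[1], cfg$blur_range[2])
      ns <- runif(1, cfg$noise_range[1], cfg$noise_range[2])
      aug <- raw
      if (sg > 0) {
        aug <- array(gaussian_blur_cpp(aug, dim(aug),
                                       rep(sg, length(dim(aug)))), dim(aug))
      }
      if (ns > 0) {
        rngv <- diff(range(aug))
        if (rngv == 0) rngv <- 1
        aug <- aug + array(rnorm(length(aug), sd = ns * rngv), dim(aug))
      }
      x_t <- array(normalize_input(raw), dim(raw))
      x_s <- array(normalize_input(aug), dim(aug))
      tfw <- unet_forward(model_with(pretrained, pair$teacher), x_t,
                          keep_cache = FALSE)
      mask <- confidence_mask(tfw$prob, cfg$t_c)  # channelwise
      if (sum(mask) == 0) next
      sfw <- unet_forward(model_with(pretrained, pair$student), x_s,
                          keep_cache = TRUE)
      ls <- dice_loss(sfw$prob, tfw$prob, mask = mask)
      g <- unet_backward(model_with(pretrained, pair$student), sfw, ls$grad)
      gacc <- if (is.null(gacc)) g else purrr::map2(gacc, g, `+`)
      lacc <- lacc + ls$loss
      macc <- macc + mean(mask)
      used <- used + 1L
    }
    if (used == 0L) {
      skipped <- skipped + 1L
      log[[it]] <- tibble::tibble(iteration = it, loss = NA_real_,
                                  masked_fraction = 0)
      next
    }
    if (used > 1L) gacc <- lapply(gacc, function(x) x / used)
    st <- adamw_step(pair$student, gacc, opt, cfg$learning_rate)
    pair$student <- st$params
    opt <- st$state
    pair <- ema_update(pair, cfg$alpha)
    log[[it]] <- tibble::tibble(iteration = it, loss = lacc / used,
                                masked_fraction = macc / used)
  }
  adapted <- model_with(pretrained, pair$teacher)
  adapted$log <- dplyr::bind_rows(log)
  adapted$da_config <- cfg
  list(model = adapted, log = adapted$log, pair = pair,
       skipped_iterations = skipped)
}

#' Post-adaptation sanity report
#'
#' Failed adaptation cannot be detected from the loss alone; this report
#' compares instance counts of the source and adapted models on the same
#' volumes so gross failures (empty or exploding segmentations) surface
#' quantitatively.
#'
#' @param source,adapted `syn_unet` models.
#' @param volumes List of `syn_volume`s.
#' @param params Watershed parameters used for both models.
#' @return A tibble: volume, instances before/after, relative drift.
#' @export
adaptation_report <- function(source, adapted, volumes,
                              params = watershed_params()) {
  rows <- purrr::imap(volumes, function(v, i) {
    n0 <- length(label_ids(distance_watershed_instances(
      predict_tiled(source, v), params)))
    n1 <- length(label_ids(distance_watershed_instances(
      predict_tiled(adapted, v), params)))
    tibble::tibble(volume = i, instances_source = n0,
                   instances_adapted = n1,
                   drift = (n1 - n0) / max(n0, 1))
  })
  dplyr::bind_rows(rows)
}
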