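# ---------------------------------------------------------------------------
# Two-stage cascade.
#
# Stage 1 segments the pancreas on the full slice. The stage-1 probability
# map is binarized, its bounding box enlarged by a margin, and the crop —
# intensity-reweighted by the probability map through the differentiable
# salient-change module — becomes stage 2's input, so gradients from the
# tumor losses reach the pancreas network. Stage 2 runs its own multi-scale
# U-Net, reduces the five decoder features with 1x1 convolutions, localizes
# on the deepest level with the non-local module and refines level by level
# with four focusing modules.
#
# Training follows the three-step schedule S -> I -> J: S decouples the
# stages (ground-truth crop, no saliency weighting), I turns the saliency
# coupling on while still cropping from ground truth, and J crops from the
# stage-1 output so training matches test-time behaviour. One optimizer
# spans both stages and persists across steps.
# ---------------------------------------------------------------------------

#' Cascade model configuration
#'
#' @param base_channels Backbone width for both stages (32 default; tests
#'   run 8).
#' @param stage2_input_size Side length of the resized stage-2 input
#'   (divisible by 16).
#' @param reduce_channels Width of the five 1x1 channel-reduction
#'   convolutions feeding localization/focusing.
#' @param crop_threshold Binarization threshold applied to the stage-1
#'   probability map when deriving the crop box.
#' @param crop_margin Margin K in pixels added around the bounding box;
#'   `NULL` scales the reference margin of 20 px at 512 resolution
#'   proportionally to the image.
#' @param saliency_eps Floor of the multiplicative saliency weighting
#'   (stage-2 input is `image * (eps + (1-eps) * P)`).
#' @param use_localization,use_focusing Ablation switches for the non-local
#'   localization module and the focusing modules.
#' @export
cascade_config <- function(base_channels = 32L,
                           stage2_input_size = 96L,
                           reduce_channels = 32L,
                           crop_threshold = 0.5,
                           crop_margin = NULL,
                           saliency_eps = 0.5,
                           use_localization = TRUE,
                           use_focusing = TRUE) {
  if (stage2_input_size %% 16L != 0L)
    stop("stage2_input_size must be divisible by 16")
  structure(list(base_channels = as.integer(base_channels),
                 stage2_input_size = as.integer(stage2_input_size),
                 reduce_channels = as.integer(reduce_channels),
                 crop_threshold = crop_threshold,
                 crop_margin = if (is.null(crop_margin)) NULL
                               else as.integer(crop_margin),
                 saliency_eps = saliency_eps,
                 use_localization = use_localization,
                 use_focusing = use_focusing),
            class = "cascade_config")
}

#' Construct the full two-stage cascade model
#'
#' @param config A [cascade_config()].
#' @param seed Seed for parameter initialization.
#' @return A `pancseg_model`.
#' @export
cascade_new <- function(config = cascade_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- config$base_channels
  R <- config$reduce_channels
  stage1 <- backbone_new(backbone_config(1L, b))
  s2_backbone <- backbone_new(backbone_config(1L, b))
  feat_widths <- c(bb_width(b, 1L), bb_width(b, 2L), bb_width(b, 3L),
                   bb_width(b, 4L), 2L * bb_width(b, 4L))
  reduce <- lapply(feat_widths, function(wd) conv_block(wd, R, 1L))
  loc <- nonlocal_new(R)
  foc <- if (config$use_focusing) lapply(1:4, function(i) focusing_new(R))
         else NULL
  structure(list(config = config,
                 stage1 = stage1,
                 stage2 = list(backbone = s2_backbone, reduce = reduce,
                               loc = loc, foc = foc)),
            class = "pancseg_model")
}

# --- crop geometry ----------------------------------------------------------

default_margin <- function(image_size) max(1L, as.integer(round(20 * image_size / 512)))

#' Bounding box of a binarized probability map
#'
#' Binarizes `P >= threshold`, takes the minimal axis-aligned box containing
#' every nonzero pixel, enlarges it by `margin` pixels on each side and
#' clamps to the image. An all-zero binarization falls back to the full
#' image so inference never fails on a missed pancreas.
#'
#' @param P Probability map (matrix in [0,1]) or binary mask.
#' @param threshold Binarization threshold (default 0.5).
#' @param margin Margin K in pixels; `NULL` uses the resolution-scaled
#'   default (20 px at 512).
#' @return A `crop_region`: 0-based half-open bounds `row_min`, `row_max`,
#'   `col_min`, `col_max` plus the margin used.
#' @export
binarize_and_box <- function(P, threshold = 0.5, margin = NULL) {
  P <- ag_value(P)
  H <- nrow(P); W <- ncol(P)
  if (is.null(margin)) margin <- default_margin(max(H, W))
  z <- P >= threshold
  if (!any(z)) {
    region <- list(row_min = 0L, row_max = H, col_min = 0L, col_max = W,
                   margin = as.integer(margin))
  } else {
    idx <- which(z, arr.ind = TRUE)
    region <- list(
      row_min = max(0L, min(idx[, 1]) - 1L - margin),
      row_max = min(H, max(idx[, 1]) + margin),
      col_min = max(0L, min(idx[, 2]) - 1L - margin),
      col_max = min(W, max(idx[, 2]) + margin),
      margin = as.integer(margin))
    region <- lapply(region, as.integer)
  }
  structure(region, class = "crop_region")
}

region_rows <- function(region) (region$row_min + 1L):region$row_max
region_cols <- function(region) (region$col_min + 1L):region$col_max

#' Salient-change module: probability-weighted crop for stage 2
#'
#' Crops the image and the stage-1 probability map to `region` and forms
#' `image * (eps + (1 - eps) * P)`, so stage-1 confidence reweights the
#' intensities while gradients flow back into stage 1; the result is
#' bilinearly resized to the stage-2 input size. With
#' `use_saliency = FALSE` the raw image crop is resized instead (training
#' step S).
#'
#' @param image Full image (matrix or tensor).
#' @param P Stage-1 probability map (tensor for joint training).
#' @param region A `crop_region`.
#' @param out_size Stage-2 input side length.
#' @param eps Saliency floor in [0,1).
#' @param use_saliency Apply the probability weighting?
#' @return (out_size, out_size, 1) tensor.
#' @export
salient_change <- function(image, P, region, out_size, eps = 0.5,
                           use_saliency = TRUE) {
  rows <- region_rows(region); cols <- region_cols(region)
  if (length(rows) < 1L || length(cols) < 1L)
    stop("degenerate crop region after clamping")
  img_t <- if (is_ag_tensor(image)) image else ag_const(image)
  img_c <- ag_crop(img_t, rows, cols)
  if (use_saliency) {
    P_t <- if (is_ag_tensor(P)) P else ag_const(P)
    P_c <- ag_crop(P_t, rows, cols)
    w <- ag_add(ag_mul(P_c, 1 - eps), eps)
    x <- ag_mul(img_c, w)
  } else {
    x <- img_c
  }
  xv <- ag_value(x)
  x3 <- ag_node(array(ag_value(x), dim = c(dim(xv), 1L)), list(x),
                list(function(g) matrix(g, dim(xv)[1], dim(xv)[2])))
  ag_bilinear(x3, out_size, out_size)
}

# Crop + nearest-neighbour resize of a target mask (plain numeric).
crop_resize_mask <- function(mask, region, out_size) {
  m <- mask[region_rows(region), region_cols(region), drop = FALSE]
  resize_nearest(m, out_size, out_size)
}

#' Paste a stage-2 prediction back into full-image coordinates
#'
#' Bilinearly resizes the cropped prediction to the region's size,
#' thresholds it, and writes it into an all-zero full-size mask (everything
#' outside the crop region stays 0).
#'
#' @param pred_fine Probability matrix over the stage-2 crop.
#' @param region The `crop_region` used for the crop.
#' @param full_shape `c(H, W)` of the original image.
#' @param threshold Binarization threshold (default 0.5).
#' @return H x W 0/1 matrix.
#' @export
paste_back <- function(pred_fine, region, full_shape, threshold = 0.5) {
  pred_fine <- ag_value(pred_fine)
  rows <- region_rows(region); cols <- region_cols(region)
  patch <- resize_bilinear(pred_fine, length(rows), length(cols))
  out <- matrix(0, full_shape[1], full_shape[2])
  out[rows, cols] <- as.numeric(patch > threshold)
  out
}

# --- stage 2 ----------------------------------------------------------------

#' Stage-2 forward pass
#'
#' Backbone encode/decode, five 1x1 channel reductions, non-local
#' localization on the deepest feature, then focusing refinement from the
#' coarsest level to the finest. Predictions are returned coarse to fine as
#' logits at native level sizes plus upsampled probability maps at the
#' input size.
#'
#' @param model A `pancseg_model`.
#' @param x Stage-2 input tensor ((S, S, 1)).
#' @return List with `logits` (list of tensors, coarse first; length 5, or
#'   1 when focusing is ablated) and `probs` (matching upsampled (S, S)
#'   probability tensors).
#' @export
stage2_forward <- function(model, x) {
  s2 <- model$stage2
  S <- dim(ag_value(x))[1]
  bb <- backbone_forward(s2$backbone, x)
  red <- lapply(1:5, function(l) conv_forward(s2$reduce[[l]], bb$features[[l]]))
  if (model$config$use_localization) {
    locres <- nonlocal_localize(s2$loc, red[[5]])
    f_h <- locres$features
    pred_h <- locres$logits
  } else {
    f_h <- red[[5]]
    pred_h <- conv_forward(s2$loc$head, red[[5]])
  }
  logits <- list(pred_h)
  if (!is.null(s2$foc)) {
    for (k in 1:4) {                       # levels 4, 3, 2, 1
      l <- 5L - k
      res <- focusing_refine(s2$foc[[k]], red[[l]], f_h, pred_h)
      f_h <- res$features
      pred_h <- res$logits
      logits[[k + 1L]] <- pred_h
    }
  }
  probs <- lapply(logits, function(lg)
    ag_squeeze(ag_sigmoid(ag_bilinear(lg, S, S))))
  list(logits = logits, probs = probs)
}

# --- losses for one slice ---------------------------------------------------

#' Compute all cascade losses for one slice
#'
#' @param model A `pancseg_model`.
#' @param sample A `pancseg_slice`.
#' @param saliency_on Couple the stages through the salient-change module?
#' @param crop_source `"ground_truth"` (steps S, I) or `"model"` (step J).
#' @param mu,k Focusing-loss weight-map parameters.
#' @param alpha,beta Total-loss mixing weights.
#' @return List of loss tensors/values: `seg1_t`, `seg2_t`, `total_t`
#'   (differentiable, excludes the non-differentiable ISB term), and
#'   numeric `seg1`, `seg2`, `isb`, `total` (reported total includes
#'   `beta * isb`).
#' @export
cascade_losses <- function(model, sample, saliency_on = TRUE,
                           crop_source = c("model", "ground_truth"),
                           mu = 5, k = 15L, alpha = 0.9, beta = 0.4,
                           level_weights = stage2_level_weights()) {
  crop_source <- match.arg(crop_source)
  cfg <- model$config
  s1 <- backbone_forward(model$stage1, sample$image)
  P_t <- ag_squeeze(s1$prob)
  seg1_t <- dice_loss(P_t, sample$pancreas_mask)
  region <- if (crop_source == "ground_truth") {
    binarize_and_box(sample$pancreas_mask, 0.5, cfg$crop_margin)
  } else {
    binarize_and_box(ag_value(P_t), cfg$crop_threshold, cfg$crop_margin)
  }
  x2 <- salient_change(sample$image, P_t, region, cfg$stage2_input_size,
                       eps = cfg$saliency_eps, use_saliency = saliency_on)
  out2 <- stage2_forward(model, x2)
  gt2 <- crop_resize_mask(sample$tumor_mask, region, cfg$stage2_input_size)
  if (length(out2$probs) == 5L) {
    seg2_t <- stage2_total(out2$probs[[1]], out2$probs[2:5], gt2,
                           mu = mu, k = k, weights = level_weights)
  } else {
    seg2_t <- localization_loss(out2$probs[[1]], gt2)
  }
  finest <- out2$probs[[length(out2$probs)]]
  isb <- isb_loss(ag_value(finest), matrix(1L + as.integer(gt2 > 0.5),
                                           nrow(gt2), ncol(gt2)), 2L)
  total_t <- ag_add(seg1_t, ag_mul(seg2_t, alpha))
  list(seg1_t = seg1_t, seg2_t = seg2_t, total_t = total_t,
       seg1 = as.numeric(ag_value(seg1_t)),
       seg2 = as.numeric(ag_value(seg2_t)),
       isb = isb,
       total = as.numeric(ag_value(total_t)) + beta * isb,
       region = region)
}

# --- training schedule ------------------------------------------------------

#' The three-step training schedule
#'
#' @param epochs_S,epochs_I,epochs_J Epochs per step (defaults 2, 4, 50).
#' @return Tibble with one row per step: step name, epochs, crop source and
#'   whether the saliency coupling is active.
#' @export
train_schedule <- function(epochs_S = 2L, epochs_I = 4L, epochs_J = 50L) {
  tibble::tibble(step = c("S", "I", "J"),
                 epochs = as.integer(c(epochs_S, epochs_I, epochs_J)),
                 crop_source = c("ground_truth", "ground_truth", "model"),
                 saliency = c(FALSE, TRUE, TRUE))
}

#' Train the cascade with the S/I/J schedule
#'
#' Step S decouples the stages (ground-truth crops, saliency off, so
#' stage-2 losses send no gradient to stage 1); step I activates the
#' saliency coupling with ground-truth crops; step J crops from the stage-1
#' output, matching test-time behaviour. One SGD optimizer (momentum 0.9 by
#' default) spans both stages and persists across steps.
#'
#' @param model A `pancseg_model`.
#' @param samples List of `pancseg_slice` training samples.
#' @param schedule A [train_schedule()] tibble.
#' @param lr,momentum,weight_decay SGD hyperparameters (defaults 1e-5, 0.9,
#'   1e-7).
#' @param alpha,beta,mu Loss hyperparameters (defaults 0.9, 0.4, 5).
#' @param weight_pool Box size of the boundary-emphasis filter (15).
#' @param level_weights Deep-supervision weights for the four focusing
#'   levels, coarse first (default [stage2_level_weights()]).
#' @param seed Seed controlling per-epoch shuffling.
#' @param shuffle Shuffle sample order each epoch?
#' @param checkpoint_dir If non-NULL, parameter snapshots are written there
#'   at each step boundary.
#' @param verbose Print per-epoch losses?
#' @return A `pancseg_fit`: list with the trained `model`, the per-epoch
#'   `log` tibble (columns step, epoch, loss_seg1, loss_seg2, loss_isb,
#'   total) and the hyperparameters used.
#' @export
run_schedule <- function(model, samples, schedule = train_schedule(),
                         lr = 1e-5, momentum = 0.9, weight_decay = 1e-7,
                         alpha = 0.9, beta = 0.4, mu = 5, weight_pool = 15L,
                         level_weights = stage2_level_weights(),
                         seed = 1L, shuffle = TRUE,
                         checkpoint_dir = NULL, verbose = FALSE) {
  if (length(samples) == 0L) stop("empty training set")
  opt <- sgd_new(collect_params(model), lr = lr, momentum = momentum,
                 weight_decay = weight_decay)
  set.seed(seed)
  log_rows <- list()
  epoch_global <- 0L
  for (si in seq_len(nrow(schedule))) {
    step <- schedule$step[si]
    for (ep in seq_len(schedule$epochs[si])) {
      order <- if (shuffle) sample.int(length(samples)) else seq_along(samples)
      acc <- c(seg1 = 0, seg2 = 0, isb = 0, total = 0)
      for (ix in order) {
        losses <- cascade_losses(model, samples[[ix]],
                                 saliency_on = schedule$saliency[si],
                                 crop_source = schedule$crop_source[si],
                                 mu = mu, k = weight_pool,
                                 alpha = alpha, beta = beta,
                                 level_weights = level_weights)
        ag_backward(losses$total_t)
        opt <- sgd_step(opt)
        acc <- acc + c(losses$seg1, losses$seg2, losses$isb, losses$total)
      }
      acc <- acc / length(samples)
      epoch_global <- epoch_global + 1L
      log_rows[[epoch_global]] <- tibble::tibble(
        step = step, epoch = ep,
        loss_seg1 = acc[["seg1"]], loss_seg2 = acc[["seg2"]],
        loss_isb = acc[["isb"]], total = acc[["total"]])
      if (verbose)
        message(sprintf("[%s %d] seg1=%.4f seg2=%.4f isb=%.5f total=%.4f",
                        step, ep, acc[["seg1"]], acc[["seg2"]],
                        acc[["isb"]], acc[["total"]]))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(model, file.path(checkpoint_dir,
                                       sprintf("step_%s.rds", step)))
    }
  }
  structure(list(model = model,
                 log = dplyr::bind_rows(log_rows),
                 hyper = list(lr = lr, momentum = momentum,
                              weight_decay = weight_decay, alpha = alpha,
                              beta = beta, mu = mu, seed = seed)),
            class = "pancseg_fit")
}

# --- inference --------------------------------------------------------------

#' Segment one slice with the trained cascade
#'
#' Runs stage 1, derives the crop box from its probability map (with
#' full-image fallback), applies the salient-change weighting, runs stage 2
#' and pastes the finest prediction back into full-image coordinates.
#'
#' @param model A `pancseg_model`.
#' @param image H x W matrix in [0,1].
#' @param threshold Final binarization threshold.
#' @return List with `stage1_prob`, `region`, `stage2_probs` (coarse to
#'   fine, at the stage-2 input size) and `final_mask` (H x W 0/1; zero
#'   outside the crop region).
#' @export
predict_slice <- function(model, image, threshold = 0.5) {
  cfg <- model$config
  s1 <- backbone_forward(model$stage1, image)
  P <- ag_value(ag_squeeze(s1$prob))
  region <- binarize_and_box(P, cfg$crop_threshold, cfg$crop_margin)
  x2 <- salient_change(image, ag_const(P), region, cfg$stage2_input_size,
                       eps = cfg$saliency_eps, use_saliency = TRUE)
  out2 <- stage2_forward(model, x2)
  probs <- lapply(out2$probs, ag_value)
  final <- paste_back(probs[[length(probs)]], region, dim(image), threshold)
  list(stage1_prob = P, region = region, stage2_probs = probs,
       final_mask = final)
}

#' Predict every slice of a sample list
#'
#' @param model A `pancseg_model`.
#' @param samples List of `pancseg_slice`.
#' @return Named list of [predict_slice()] results keyed by
#'   `case_id_sNNN`.
#' @export
predict_samples <- function(model, samples) {
  out <- lapply(samples, function(s) predict_slice(model, s$image))
  names(out) <- vapply(samples, slice_key, character(1))
  out
}

slice_key <- function(sample) sprintf("%s_s%03d", sample$case_id, sample$slice_index)

# --- checkpointing ----------------------------------------------------------

#' Save / load model parameters
#'
#' Checkpoints are RDS files holding the configuration and a flat list of
#' parameter arrays in construction order.
#' @param model A `pancseg_model`.
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  params <- collect_params(model)
  # `+ 0` forces a copy so later in-place optimizer updates cannot touch
  # the serialized snapshot.
  saveRDS(list(config = model$config,
               values = lapply(params, function(p) p$value + 0)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- cascade_new(ck$config)
  params <- collect_params(model)
  if (length(params) != length(ck$values))
    stop("checkpoint has ", length(ck$values), " parameter tensors, model has ",
         length(params))
  for (i in seq_along(params)) params[[i]]$value <- ck$values[[i]]
  model
}
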