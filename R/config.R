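# ---------------------------------------------------------------------------
# Run configuration: defaults, YAML loading with strict key checking, and
# deep merging of command-line overrides. The defaults encode the training
# recipe: SGD with momentum 0.9, learning rate 1e-5, weight decay 1e-7,
# batch size 1, loss weights alpha 0.9 / beta 0.4, and the S/I/J schedule
# of 2/4/50 epochs.
# ---------------------------------------------------------------------------

#' Default run configuration
#'
#' @return Nested named list covering the phantom generator, model, crop,
#'   saliency, training and evaluation settings.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    phantom = list(
      image_size = 64L,
      pancreas_area_frac_range = c(0.02, 0.08),
      tumor_area_frac_range = c(0.002, 0.02),
      tumor_contrast_delta = 0.05,
      noise_sigma = 0.03,
      texture_sigma = 0.04,
      slices_per_case = 8L,
      tumor_slice_range = c(3L, 6L)
    ),
    model = list(
      base_channels = 32L,
      stage2_input_size = 96L,
      reduce_channels = 32L,
      use_localization = TRUE,
      use_focusing = TRUE
    ),
    crop = list(threshold = 0.5, margin = NULL),
    saliency = list(eps = 0.5),
    train = list(
      lr = 1e-5,
      momentum = 0.9,
      weight_decay = 1e-7,
      batch_size = 1L,
      epochs_S = 2L,
      epochs_I = 4L,
      epochs_J = 50L,
      alpha = 0.9,
      beta = 0.4,
      mu = 5,
      weight_pool = 15L,
      level_weights = c(4, 2, 1, 0.5)
    ),
    eval = list(final_threshold = 0.5)
  )
}

# Recursive merge of `new` into `base`; unknown keys are an error so config
# typos fail loudly.
merge_config <- function(base, new, path = "") {
  for (key in names(new)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && is.list(new[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], new[[key]], full)
    } else {
      base[[key]] <- new[[key]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Starts from [default_config()], deep-merges an optional YAML file, then
#' deep-merges explicit overrides. Keys absent from the defaults raise an
#' error naming the offending key.
#'
#' @param path Optional YAML file path (an empty file yields pure
#'   defaults).
#' @param overrides Optional nested list of overrides applied last.
#' @return Merged configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file does not exist: ", path)
    from_file <- yaml::read_yaml(path)
    if (!is.null(from_file)) cfg <- merge_config(cfg, from_file)
  }
  if (length(overrides) > 0L) cfg <- merge_config(cfg, overrides)
  cfg
}

config_phantom <- function(cfg) {
  phantom_config(image_size = cfg$phantom$image_size,
                 pancreas_area_frac_range = cfg$phantom$pancreas_area_frac_range,
                 tumor_area_frac_range = cfg$phantom$tumor_area_frac_range,
                 tumor_contrast_delta = cfg$phantom$tumor_contrast_delta,
                 noise_sigma = cfg$phantom$noise_sigma,
                 texture_sigma = cfg$phantom$texture_sigma,
                 slices_per_case = cfg$phantom$slices_per_case,
                 tumor_slice_range = cfg$phantom$tumor_slice_range,
                 seed = cfg$seed)
}

config_model <- function(cfg) {
  cascade_config(base_channels = cfg$model$base_channels,
                 stage2_input_size = cfg$model$stage2_input_size,
                 reduce_channels = cfg$model$reduce_channels,
                 crop_threshold = cfg$crop$threshold,
                 crop_margin = cfg$crop$margin,
                 saliency_eps = cfg$saliency$eps,
                 use_localization = cfg$model$use_localization,
                 use_focusing = cfg$model$use_focusing)
}

config_hash <- function(cfg) {
  # Stable short fingerprint of the resolved configuration for run logs.
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  sprintf("%08x", sum(utf8ToInt(s) * seq_len(nchar(s))) %% .Machine$integer.max)
}
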