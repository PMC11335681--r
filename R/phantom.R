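# ---------------------------------------------------------------------------
# Synthetic CT-phantom generator.
#
# Emulates the properties that make pancreatic-tumor segmentation hard: the
# tumor occupies a tiny fraction of the image, sits inside a larger pancreas
# region, and differs from it only by a small mean-intensity offset on a
# textured, noisy background. Every slice is a pure function of (config,
# seed), so the whole test suite runs without any external dataset.
# ---------------------------------------------------------------------------

#' Phantom generator configuration
#'
#' @param image_size Side length in pixels of the square slice (default 64;
#'   512 matches the real-data resolution).
#' @param pancreas_area_frac_range Fraction of the image area covered by the
#'   pancreas ellipse, sampled uniformly from this range.
#' @param tumor_area_frac_range Fraction of the image area covered by the
#'   tumor ellipse. Its maximum must stay below the pancreas minimum so the
#'   tumor is strictly the smaller structure.
#' @param tumor_contrast_delta Mean-intensity offset of tumor over pancreas,
#'   in [0,1] display units. Small values give the low-contrast regime.
#' @param noise_sigma Standard deviation of additive i.i.d. Gaussian noise.
#' @param texture_sigma Standard deviation of the smoothed (low-pass) noise
#'   field that textures the whole slice. Textured background deliberately
#'   creates false-positive-prone structure.
#' @param background_mean,pancreas_mean Region mean intensities (fixed
#'   conventions: background 0.35, pancreas 0.5, tumor 0.5 + delta).
#' @param slices_per_case Number of axial slices per synthetic case.
#' @param tumor_slice_range Integer range `c(min, max)`: how many contiguous
#'   slices of a case contain tumor (mirrors real cases where only a subset
#'   of slices shows tumor).
#' @param seed Integer seed for dataset-level generation.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(image_size = 64L,
                           pancreas_area_frac_range = c(0.02, 0.08),
                           tumor_area_frac_range = c(0.002, 0.02),
                           tumor_contrast_delta = 0.05,
                           noise_sigma = 0.03,
                           texture_sigma = 0.04,
                           background_mean = 0.35,
                           pancreas_mean = 0.5,
                           slices_per_case = 8L,
                           tumor_slice_range = c(3L, 6L),
                           seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              pancreas_area_frac_range = as.numeric(pancreas_area_frac_range),
              tumor_area_frac_range = as.numeric(tumor_area_frac_range),
              tumor_contrast_delta = tumor_contrast_delta,
              noise_sigma = noise_sigma,
              texture_sigma = texture_sigma,
              background_mean = background_mean,
              pancreas_mean = pancreas_mean,
              slices_per_case = as.integer(slices_per_case),
              tumor_slice_range = as.integer(tumor_slice_range),
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(cfg$image_size >= 16L,
            length(cfg$pancreas_area_frac_range) == 2L,
            length(cfg$tumor_area_frac_range) == 2L,
            cfg$slices_per_case >= 1L)
  if (max(cfg$tumor_area_frac_range) > min(cfg$pancreas_area_frac_range))
    stop("tumor_area_frac_range max must not exceed pancreas_area_frac_range min")
  if (cfg$pancreas_mean + cfg$tumor_contrast_delta > 1)
    stop("tumor mean intensity exceeds 1; reduce tumor_contrast_delta")
  if (any(cfg$tumor_slice_range > cfg$slices_per_case))
    stop("tumor_slice_range exceeds slices_per_case")
  invisible(cfg)
}

# Rasterize a rotated ellipse: a pixel belongs iff its centre satisfies the
# ellipse inequality (no anti-aliasing, so masks are exactly reproducible).
rasterize_ellipse <- function(H, W, cy, cx, a, b, theta) {
  r <- matrix(seq_len(H), H, W) - cy
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- cos(theta) * c_ + sin(theta) * r
  v <- -sin(theta) * c_ + cos(theta) * r
  (u / a)^2 + (v / b)^2 <= 1
}

# Smoothed white-noise texture field with standard deviation `sigma`.
phantom_texture <- function(H, W, sigma) {
  z <- matrix(stats::rnorm(H * W), H, W)
  z <- box_mean_cpp(z, 9L)
  s <- stats::sd(z)
  if (s < .Machine$double.eps) return(matrix(0, H, W))
  z / s * sigma
}

# Sample one ellipse whose rasterized pixel count lands inside the requested
# area-fraction band; resamples geometry up to `retries` times.
sample_ellipse_mask <- function(H, W, frac_range, inside = NULL,
                                retries = 200L) {
  n_px <- H * W
  lo <- frac_range[1] * n_px * 0.8
  hi <- frac_range[2] * n_px * 1.2
  for (i in seq_len(retries)) {
    frac <- stats::runif(1, frac_range[1], frac_range[2])
    area <- frac * n_px
    q <- stats::runif(1, 0.55, 1)           # axis ratio b/a
    a <- sqrt(area / (pi * q))
    b <- a * q
    theta <- stats::runif(1, 0, pi)
    if (is.null(inside)) {
      rad <- max(a, b) + 1
      if (2 * rad >= min(H, W)) next
      cy <- stats::runif(1, rad, H - rad)
      cx <- stats::runif(1, rad, W - rad)
    } else {
      idx <- which(inside, arr.ind = TRUE)
      pick <- idx[sample.int(nrow(idx), 1L), ]
      cy <- pick[1]; cx <- pick[2]
    }
    m <- rasterize_ellipse(H, W, cy, cx, a, b, theta)
    cnt <- sum(m)
    if (cnt < lo || cnt > hi) next
    if (!is.null(inside) && any(m & !inside)) next
    return(m)
  }
  stop("could not place an ellipse satisfying the geometric constraints ",
       "after ", retries, " attempts")
}

#' Generate one phantom slice
#'
#' Draws geometry and noise from the current RNG state (seed it, or use
#' [generate_case()] / [generate_dataset()] for fully reproducible streams).
#' The tumor ellipse is always strictly inside the pancreas ellipse; masks
#' record the exact pre-noise ellipse supports.
#'
#' @param config A [phantom_config()].
#' @param case_id,slice_index Identity stamped on the sample.
#' @param with_tumor Generate a tumor ellipse? Slices outside a case's tumor
#'   range carry an all-zero tumor mask.
#' @return A `pancseg_slice`: list with `image` (H x W in [0,1]),
#'   `pancreas_mask`, `tumor_mask` (0/1 matrices), `case_id`, `slice_index`.
#' @export
generate_slice <- function(config, case_id = "case", slice_index = 0L,
                           with_tumor = TRUE) {
  validate_phantom_config(config)
  H <- config$image_size; W <- config$image_size
  tex <- phantom_texture(H, W, config$texture_sigma)
  panc <- sample_ellipse_mask(H, W, config$pancreas_area_frac_range)
  if (with_tumor) {
    tum <- sample_ellipse_mask(H, W, config$tumor_area_frac_range,
                               inside = panc)
  } else {
    tum <- matrix(FALSE, H, W)
  }
  img <- matrix(config$background_mean, H, W)
  img[panc] <- config$pancreas_mean
  img[tum] <- config$pancreas_mean + config$tumor_contrast_delta
  img <- img + tex + matrix(stats::rnorm(H * W, sd = config$noise_sigma), H, W)
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img,
                 pancreas_mask = matrix(as.numeric(panc), H, W),
                 tumor_mask = matrix(as.numeric(tum), H, W),
                 case_id = case_id,
                 slice_index = as.integer(slice_index)),
            class = "pancseg_slice")
}

#' Generate a coherent phantom case
#'
#' The pancreas is present on every slice; the tumor occupies one contiguous
#' subrange of slices whose length is drawn from `tumor_slice_range`.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; the case identity is derived from it, so
#'   different seeds give different `case_id`s.
#' @return List of `pancseg_slice` objects.
#' @export
generate_case <- function(config, seed) {
  validate_phantom_config(config)
  set.seed(seed)
  n <- config$slices_per_case
  kr <- seq(config$tumor_slice_range[1], config$tumor_slice_range[2])
  k <- kr[sample.int(length(kr), 1L)]
  start <- sample.int(n - k + 1L, 1L)
  case_id <- sprintf("case_%09d", as.integer(seed))
  lapply(seq_len(n), function(i) {
    generate_slice(config, case_id = case_id, slice_index = i - 1L,
                   with_tumor = (i >= start && i < start + k))
  })
}

#' Generate and write a phantom dataset
#'
#' Writes 8-bit grayscale PNG images and 0/255 PNG masks plus a JSON manifest
#' via the package's data writers. With the same config and seed the output
#' files are byte-identical across runs.
#'
#' @param config A [phantom_config()]; its `seed` drives the per-case seeds.
#' @param n_cases Number of cases (0 gives an empty manifest).
#' @param out_dir Writable output directory (created if needed).
#' @return The dataset manifest as a tibble (also written to
#'   `manifest.json` in `out_dir`).
#' @export
generate_dataset <- function(config, n_cases, out_dir) {
  validate_phantom_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  case_seeds <- sample.int(2147483646L, n_cases)
  rows <- list()
  for (ci in seq_len(n_cases)) {
    slices <- generate_case(config, case_seeds[ci])
    for (s in slices) {
      rec <- write_slice(s, out_dir)
      rows[[length(rows) + 1L]] <- rec
    }
  }
  manifest <- if (length(rows) == 0L) empty_manifest() else dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  manifest
}
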