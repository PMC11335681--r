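# ---------------------------------------------------------------------------
# Data input/output: PNG slice/mask pairs, NIfTI volume-to-slice conversion
# with the labeled-slice selection rule, JSON manifests and case-level
# train/test splitting. PNG handling goes through the `png` package, NIfTI
# through `RNifti`.
# ---------------------------------------------------------------------------

manifest_cols <- c("case_id", "slice_index", "image_path",
                   "pancreas_mask_path", "tumor_mask_path", "has_tumor")

empty_manifest <- function() {
  tibble::tibble(case_id = character(), slice_index = integer(),
                 image_path = character(), pancreas_mask_path = character(),
                 tumor_mask_path = character(), has_tumor = logical())
}

# Quantize to the 8-bit grid before writing so that write -> read is an exact
# round trip at 1/255 resolution.
write_image_png <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  png::writePNG(round(img * 255) / 255, path)
  path
}

write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  path
}

# Write one slice sample (image + both masks); returns its manifest row.
write_slice <- function(sample, out_dir) {
  stem <- sprintf("%s_s%03d", sample$case_id, sample$slice_index)
  image_path <- file.path(out_dir, paste0(stem, ".png"))
  panc_path <- file.path(out_dir, paste0(stem, "_pancreas.png"))
  tum_path <- file.path(out_dir, paste0(stem, "_tumor.png"))
  write_image_png(sample$image, image_path)
  write_mask_png(sample$pancreas_mask, panc_path)
  write_mask_png(sample$tumor_mask, tum_path)
  tibble::tibble(case_id = sample$case_id,
                 slice_index = sample$slice_index,
                 image_path = image_path,
                 pancreas_mask_path = panc_path,
                 tumor_mask_path = tum_path,
                 has_tumor = sum(sample$tumor_mask) > 0)
}

#' Read a slice and its masks from PNG files
#'
#' The image is scaled to [0,1]; masks are binarized at 127 on the 0-255
#' scale (tolerant of rescaled but lossless mask files). A missing mask path
#' (`NULL` or `NA`) yields an all-zero mask with a warning.
#'
#' @param image_path Path to an 8-bit grayscale PNG.
#' @param pancreas_mask_path,tumor_mask_path Optional mask paths.
#' @param case_id,slice_index Identity recorded on the returned sample.
#' @return A `pancseg_slice`.
#' @export
read_slice <- function(image_path, pancreas_mask_path = NULL,
                       tumor_mask_path = NULL,
                       case_id = "case", slice_index = 0L) {
  if (!file.exists(image_path))
    stop("image file does not exist: ", image_path)
  img <- read_png_gray(image_path)
  read_mask <- function(path, what) {
    if (is.null(path) || is.na(path) || !nzchar(path)) {
      warning("no ", what, " mask for ", image_path, "; using an empty mask")
      return(matrix(0, nrow(img), ncol(img)))
    }
    if (!file.exists(path)) stop("mask file does not exist: ", path)
    m <- read_png_gray(path)
    if (!all(dim(m) == dim(img)))
      stop(sprintf("mask %s is %dx%d but image is %dx%d", path,
                   nrow(m), ncol(m), nrow(img), ncol(img)))
    matrix(as.numeric(m * 255 > 127), nrow(m), ncol(m))
  }
  structure(list(image = img,
                 pancreas_mask = read_mask(pancreas_mask_path, "pancreas"),
                 tumor_mask = read_mask(tumor_mask_path, "tumor"),
                 case_id = case_id,
                 slice_index = as.integer(slice_index)),
            class = "pancseg_slice")
}

read_png_gray <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

read_manifest_slices <- function(manifest) {
  purrr::pmap(manifest, function(case_id, slice_index, image_path,
                                 pancreas_mask_path, tumor_mask_path, ...) {
    read_slice(image_path, pancreas_mask_path, tumor_mask_path,
               case_id = case_id, slice_index = slice_index)
  })
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = FALSE)
  path
}

read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest does not exist: ", path)
  m <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  if (nrow(m) == 0L) return(empty_manifest())
  if (check_paths) {
    missing <- m$image_path[!file.exists(m$image_path)]
    if (length(missing) > 0L)
      stop("manifest references missing files, e.g. ", missing[1])
  }
  m
}

#' Convert a NIfTI volume + label volume to per-slice PNG pairs
#'
#' Slices are taken along the last (axial) axis, 0-based. Image intensities
#' are windowed to [0,1] (by default min-max over the whole volume; set
#' `window_center`/`window_width` for a fixed linear window) and written as
#' 8-bit grayscale PNG; per-class labels become 0/255 mask PNGs.
#'
#' @param volume_path,label_path NIfTI files (.nii or .nii.gz) on the same
#'   voxel grid. Label values: `pancreas_label` marks pancreas (the tumor is
#'   also counted as pancreas tissue), `tumor_label` marks tumor.
#' @param out_dir Output directory.
#' @param keep_rule `"labeled_only"` keeps only slices whose tumor label is
#'   nonzero (how a tumor-slice dataset is constructed); `"all"` keeps every
#'   slice.
#' @param case_id Case identity; defaults to the volume file name.
#' @param pancreas_label,tumor_label Integer label codes (1 and 2 by
#'   convention).
#' @param window_center,window_width Optional linear intensity window.
#' @return Tibble of written slice records (a manifest fragment).
#' @export
nifti_to_slices <- function(volume_path, label_path, out_dir,
                            keep_rule = c("labeled_only", "all"),
                            case_id = NULL,
                            pancreas_label = 1L, tumor_label = 2L,
                            window_center = NULL, window_width = NULL) {
  keep_rule <- match.arg(keep_rule)
  vol <- as.array(RNifti::readNifti(volume_path))
  lab <- as.array(RNifti::readNifti(label_path))
  if (length(dim(vol)) != 3L || length(dim(lab)) != 3L)
    stop("expected 3D volumes, got dims ",
         paste(dim(vol), collapse = "x"), " and ",
         paste(dim(lab), collapse = "x"))
  if (!all(dim(vol) == dim(lab)))
    stop(sprintf("volume grid %s does not match label grid %s",
                 paste(dim(vol), collapse = "x"),
                 paste(dim(lab), collapse = "x")))
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(volume_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(window_center) && !is.null(window_width)) {
    lo <- window_center - window_width / 2
    hi <- window_center + window_width / 2
  } else {
    lo <- min(vol); hi <- max(vol)
  }
  rng <- if (hi > lo) hi - lo else 1
  rows <- list()
  for (z in seq_len(dim(vol)[3])) {
    lab_z <- lab[, , z]
    has_tumor <- any(lab_z == tumor_label)
    if (keep_rule == "labeled_only" && !has_tumor) next
    img <- pmin(pmax((vol[, , z] - lo) / rng, 0), 1)
    s <- structure(list(image = img,
                        pancreas_mask = (lab_z == pancreas_label) |
                          (lab_z == tumor_label),
                        tumor_mask = lab_z == tumor_label,
                        case_id = case_id, slice_index = z - 1L),
                   class = "pancseg_slice")
    rows[[length(rows) + 1L]] <- write_slice(s, out_dir)
  }
  if (length(rows) == 0L) return(empty_manifest())
  dplyr::bind_rows(rows)
}

#' Split a manifest into train and test sets by case
#'
#' The split is at case level: all slices of a case share one tag, matching
#' how patient-level CT datasets must be split to avoid leakage. Cases are
#' shuffled deterministically by `seed` and the first
#' `ceiling(train_fraction * n_cases)` become the training set.
#'
#' @param manifest A manifest tibble.
#' @param train_fraction Fraction of cases tagged `"train"`, in (0,1).
#' @param seed Integer seed for the shuffle.
#' @return The manifest with a `split` column.
#' @export
split_cases <- function(manifest, train_fraction, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  cases <- unique(manifest$case_id)
  if (length(cases) < 2L) stop("need at least 2 cases to split")
  set.seed(seed)
  shuffled <- sample(cases)
  n_train <- ceiling(train_fraction * length(cases))
  train_ids <- shuffled[seq_len(n_train)]
  manifest$split <- ifelse(manifest$case_id %in% train_ids, "train", "test")
  manifest
}

#' Write a minimal NIfTI volume (used for conversion round-trip workflows)
#'
#' Stacks per-slice matrices into a 3D array along the last axis and writes
#' it with RNifti. Intended for small synthetic volumes.
#'
#' @param slices List of H x W matrices.
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_stack <- function(slices, path) {
  arr <- array(unlist(slices, use.names = FALSE),
               dim = c(dim(slices[[1]]), length(slices)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}
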