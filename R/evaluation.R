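# ---------------------------------------------------------------------------
# Evaluation: pixel confusion counts, Dice / sensitivity / specificity, and
# per-slice / per-case / overall aggregation, plus a contour-overlay PNG
# writer for qualitative inspection.
# ---------------------------------------------------------------------------

#' Pixel confusion counts between two binary masks
#'
#' @param pred_mask,gt_mask Binary (0/1) matrices of identical shape.
#' @return List with integer `TP`, `FP`, `FN`, `TN` (summing to the pixel
#'   count).
#' @export
confusion <- function(pred_mask, gt_mask) {
  pred_mask <- ag_value(pred_mask); gt_mask <- ag_value(gt_mask)
  if (!all(dim(pred_mask) == dim(gt_mask)))
    stop("mask shapes differ")
  if (!all(pred_mask %in% c(0, 1)) || !all(gt_mask %in% c(0, 1)))
    stop("confusion counts require strictly binary masks")
  p <- pred_mask > 0.5; g <- gt_mask > 0.5
  list(TP = sum(p & g), FP = sum(p & !g), FN = sum(!p & g), TN = sum(!p & !g))
}

#' Dice, sensitivity and specificity from confusion counts
#'
#' `Dice = 2TP/(2TP+FP+FN)`, `SEN = TP/(TP+FN)`, `SPE = TN/(FP+TN)`.
#' Empty-denominator convention: if the relevant reference set is empty the
#' metric is 1 when the prediction agrees (no spurious pixels) and 0
#' otherwise.
#'
#' @param counts A list from [confusion()].
#' @return Scalar in [0,1].
#' @export
dice_coef <- function(counts) {
  d <- 2 * counts$TP + counts$FP + counts$FN
  if (d == 0) return(1)
  2 * counts$TP / d
}

#' @rdname dice_coef
#' @export
sen <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) return(if (counts$FP == 0) 1 else 0)
  counts$TP / d
}

#' @rdname dice_coef
#' @export
spe <- function(counts) {
  d <- counts$FP + counts$TN
  if (d == 0) return(if (counts$FN == 0) 1 else 0)
  counts$TN / d
}

slice_metrics <- function(pred_mask, gt_mask) {
  cts <- confusion(pred_mask, gt_mask)
  tibble::tibble(dice = dice_coef(cts), sen = sen(cts), spe = spe(cts),
                 TP = cts$TP, FP = cts$FP, FN = cts$FN, TN = cts$TN)
}

#' Evaluate a set of predictions against ground truth
#'
#' Produces per-slice metrics, per-case means, and overall rows under both
#' aggregation conventions: the mean of per-slice metrics and the
#' pixel-pooled metrics computed from summed confusion counts (reported
#' because single headline numbers can follow either convention). Slices
#' with empty ground truth are excluded from the SEN average (undefined
#' denominator) but counted in the `n_empty_gt` attribute.
#'
#' @param predictions Named list of binary full-size masks (or
#'   [predict_slice()] results), keyed like `slice_key()` =
#'   `"<case_id>_sNNN"`.
#' @param samples List of ground-truth `pancseg_slice` objects.
#' @param target Which mask to score: `"tumor"` or `"pancreas"`.
#' @return A `pancseg_report` tibble with columns `level` ("slice",
#'   "case", "overall_slice_mean", "overall_pixel_pooled"), `case_id`,
#'   `slice_index`, `dice`, `sen`, `spe` and confusion counts.
#' @export
evaluate_dataset <- function(predictions, samples,
                             target = c("tumor", "pancreas")) {
  target <- match.arg(target)
  keys <- vapply(samples, slice_key, character(1))
  missing <- setdiff(keys, names(predictions))
  if (length(missing) > 0L)
    stop("missing predictions for slices: ", paste(missing, collapse = ", "))
  rows <- purrr::map2(samples, keys, function(s, key) {
    pred <- predictions[[key]]
    if (is.list(pred)) pred <- pred$final_mask
    gt <- if (target == "tumor") s$tumor_mask else s$pancreas_mask
    m <- slice_metrics(pred, gt)
    m$level <- "slice"; m$case_id <- s$case_id; m$slice_index <- s$slice_index
    m$empty_gt <- sum(gt) == 0
    m
  })
  per_slice <- dplyr::bind_rows(rows)
  agg <- function(df) {
    tibble::tibble(
      dice = mean(df$dice),
      sen = if (any(!df$empty_gt)) mean(df$sen[!df$empty_gt]) else NA_real_,
      spe = mean(df$spe),
      TP = sum(df$TP), FP = sum(df$FP), FN = sum(df$FN), TN = sum(df$TN))
  }
  per_case <- dplyr::bind_rows(lapply(split(per_slice, per_slice$case_id),
                                      function(df) {
    out <- agg(df)
    out$case_id <- df$case_id[1]
    out
  }))
  per_case$level <- "case"
  pooled_counts <- list(TP = sum(per_slice$TP), FP = sum(per_slice$FP),
                        FN = sum(per_slice$FN), TN = sum(per_slice$TN))
  overall <- dplyr::bind_rows(
    dplyr::mutate(agg(per_slice), level = "overall_slice_mean"),
    tibble::tibble(level = "overall_pixel_pooled",
                   dice = dice_coef(pooled_counts), sen = sen(pooled_counts),
                   spe = spe(pooled_counts),
                   TP = pooled_counts$TP, FP = pooled_counts$FP,
                   FN = pooled_counts$FN, TN = pooled_counts$TN))
  report <- dplyr::bind_rows(per_slice, per_case, overall)
  report <- report[, c("level", intersect(c("case_id", "slice_index"),
                                          names(report)),
                       "dice", "sen", "spe", "TP", "FP", "FN", "TN",
                       intersect("empty_gt", names(report)))]
  attr(report, "n_empty_gt") <- sum(per_slice$empty_gt)
  class(report) <- c("pancseg_report", class(report))
  report
}

#' Write an evaluation report as JSON plus an aligned text table
#'
#' @param report A `pancseg_report`.
#' @param path_json,path_txt Output paths (either may be NULL to skip).
#' @export
write_report <- function(report, path_json = NULL, path_txt = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(as.data.frame(report), path_json,
                         dataframe = "rows", na = "null", digits = NA)
  if (!is.null(path_txt)) {
    df <- as.data.frame(report)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
    utils::write.table(format(df), path_txt, quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

# Contour of a binary mask: foreground pixels with a 4-neighbour outside.
mask_contour <- function(mask) {
  m <- mask > 0.5
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  m & !inner
}

#' Write a qualitative overlay PNG
#'
#' Grayscale slice with the prediction contour in green and the
#' ground-truth contour in red.
#'
#' @param image H x W matrix in [0,1].
#' @param pred_mask,gt_mask Binary masks.
#' @param path Output PNG path.
#' @export
write_overlay <- function(image, pred_mask, gt_mask, path) {
  H <- nrow(image); W <- ncol(image)
  rgb <- array(rep(pmin(pmax(image, 0), 1), 3L), dim = c(H, W, 3L))
  pc <- mask_contour(pred_mask); gc_ <- mask_contour(gt_mask)
  rgb[, , 1][pc] <- 0; rgb[, , 2][pc] <- 1; rgb[, , 3][pc] <- 0
  rgb[, , 1][gc_] <- 1; rgb[, , 2][gc_] <- 0; rgb[, , 3][gc_] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}
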