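test_that("confusion counts enumerate the 2x2 toy case", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)   # rows: (1,1) / (0,0)
  gt <- matrix(c(1, 1, 0, 0), 2, 2)     # rows: (1,0) / (1,0)
  cts <- confusion(pred, gt)
  expect_equal(cts, list(TP = 1L, FP = 1L, FN = 1L, TN = 1L),
               ignore_attr = TRUE)
  expect_equal(cts$TP + cts$FP + cts$FN + cts$TN, 4L)

  same <- confusion(gt, gt)
  expect_equal(same$FP, 0L); expect_equal(same$FN, 0L)
  inv <- confusion(1 - gt, gt)
  expect_equal(inv$TP, 0L); expect_equal(inv$TN, 0L)
  expect_error(confusion(matrix(0.5, 2, 2), gt), "strictly binary")
})

test_that("Dice, SEN and SPE follow their closed forms and conventions", {
  expect_equal(dice_coef(list(TP = 2, FP = 1, FN = 1, TN = 0)), 2 / 3,
               tolerance = 1e-12)
  expect_equal(sen(list(TP = 1, FP = 0, FN = 1, TN = 0)), 0.5)
  perfect <- confusion(matrix(c(0, 1), 1, 2), matrix(c(0, 1), 1, 2))
  expect_equal(dice_coef(perfect), 1)
  expect_equal(sen(perfect), 1)
  expect_equal(spe(perfect), 1)
  # empty ground truth: clean prediction scores 1, any spurious pixel 0
  expect_equal(dice_coef(list(TP = 0, FP = 0, FN = 0, TN = 4)), 1)
  expect_equal(sen(list(TP = 0, FP = 0, FN = 0, TN = 4)), 1)
  expect_equal(sen(list(TP = 0, FP = 2, FN = 0, TN = 2)), 0)

  set.seed(81)
  for (i in 1:50) {
    p <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    g <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    cts <- confusion(p, g)
    expect_gte(sen(cts), 0); expect_lte(sen(cts), 1)
    expect_gte(spe(cts), 0); expect_lte(spe(cts), 1)
    expect_lte(dice_coef(cts), 1)
    # metric pair consistency with the soft loss on hard masks
    expect_equal(dice_coef(cts), 1 - dice_loss(p, g), tolerance = 1e-5)
    # simultaneous spatial permutation changes nothing
    perm <- sample(64)
    pp <- matrix(p[perm], 8, 8); gp <- matrix(g[perm], 8, 8)
    expect_equal(confusion(pp, gp), cts)
  }
})

test_that("dataset evaluation aggregates per slice, case and overall", {
  set.seed(82)
  cfg <- slim_phantom_config(32L, slices_per_case = 2L,
                             tumor_slice_range = c(2L, 2L))
  samples <- c(generate_case(cfg, 1L), generate_case(cfg, 2L))
  # synthetic predictions: perfect for case 1, empty for case 2
  preds <- lapply(samples, function(s) s$tumor_mask)
  names(preds) <- vapply(samples, pancseg:::slice_key, character(1))
  empty_keys <- names(preds)[3:4]
  for (k in empty_keys) preds[[k]] <- preds[[k]] * 0
  report <- evaluate_dataset(preds, samples)
  slice_rows <- report[report$level == "slice", ]
  expect_equal(nrow(slice_rows), 4L)
  case_rows <- report[report$level == "case", ]
  expect_equal(nrow(case_rows), 2L)
  expect_equal(sort(case_rows$dice), c(0, 1))
  overall <- report[report$level == "overall_slice_mean", ]
  expect_equal(overall$dice, 0.5)
  expect_equal(nrow(report), 4L + 2L + 2L)   # slices + cases + two overalls

  # ground truth against itself: everything is 1
  perfect <- lapply(samples, function(s) s$tumor_mask)
  names(perfect) <- names(preds)
  rp <- evaluate_dataset(perfect, samples)
  ov <- rp[rp$level %in% c("overall_slice_mean", "overall_pixel_pooled"), ]
  expect_true(all(ov$dice == 1 & ov$sen == 1 & ov$spe == 1))

  expect_error(evaluate_dataset(preds[-1], samples), "missing predictions")
})

test_that("two slices with Dice 0.4 and 0.6 average to a case mean of 0.5", {
  gt <- matrix(0, 10, 10); gt[1, 1:5] <- 1
  # Dice = 2TP/(2TP+FP+FN): overlap 2 of 5 pred/5 gt -> 0.4; 3 of 5 -> 0.6
  p40 <- matrix(0, 10, 10); p40[1, 4:5] <- 1; p40[2, 1:3] <- 1
  p60 <- matrix(0, 10, 10); p60[1, 3:5] <- 1; p60[2, 1:2] <- 1
  s1 <- structure(list(image = gt, pancreas_mask = gt, tumor_mask = gt,
                       case_id = "c", slice_index = 0L),
                  class = "pancseg_slice")
  s2 <- structure(list(image = gt, pancreas_mask = gt, tumor_mask = gt,
                       case_id = "c", slice_index = 1L),
                  class = "pancseg_slice")
  preds <- list(c_s000 = p40, c_s001 = p60)
  report <- evaluate_dataset(preds, list(s1, s2))
  expect_equal(report$dice[report$level == "slice"], c(0.4, 0.6))
  expect_equal(report$dice[report$level == "case"], 0.5)
})

test_that("overlay PNGs draw prediction and ground-truth contours", {
  set.seed(83)
  s <- generate_slice(slim_phantom_config(32L), "ov", 0L)
  path <- file.path(tempdir(), "overlay.png")
  write_overlay(s$image, s$pancreas_mask, s$tumor_mask, path)
  img <- png::readPNG(path)
  expect_equal(dim(img), c(32, 32, 3))
  # green prediction contour pixels exist
  expect_true(any(img[, , 2] == 1 & img[, , 1] == 0))
  # red ground-truth contour pixels exist
  expect_true(any(img[, , 1] == 1 & img[, , 2] == 0))
})
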