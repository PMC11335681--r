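test_that("binarize_and_box matches the worked example and the brute-force scan", {
  P <- matrix(0, 64, 64)
  P[11:21, 31:41] <- 0.9          # rows 10..20, cols 30..40 in 0-based terms
  r <- binarize_and_box(P, 0.5, margin = 5L)
  expect_equal(r$row_min, 5L); expect_equal(r$row_max, 26L)
  expect_equal(r$col_min, 25L); expect_equal(r$col_max, 46L)

  # all-zero map falls back to the full image
  r0 <- binarize_and_box(matrix(0, 64, 64), 0.5, margin = 5L)
  expect_equal(unlist(r0[1:4]), c(row_min = 0L, row_max = 64L,
                                  col_min = 0L, col_max = 64L))

  # absurd margin clamps to the image
  rK <- binarize_and_box(P, 0.5, margin = 1000L)
  expect_equal(unlist(rK[1:4]), c(row_min = 0L, row_max = 64L,
                                  col_min = 0L, col_max = 64L))

  set.seed(71)
  for (i in 1:100) {
    Pr <- matrix(runif(256), 16, 16) * (runif(1) < 0.9)
    K <- sample(0:4, 1)
    reg <- binarize_and_box(Pr, 0.5, margin = K)
    z <- Pr >= 0.5
    if (!any(z)) {
      expect_equal(unlist(reg[1:4]), c(row_min = 0L, row_max = 16L,
                                       col_min = 0L, col_max = 16L))
    } else {
      rows <- range(row(Pr)[z]); cols <- range(col(Pr)[z])
      expect_equal(reg$row_min, max(0L, rows[1] - 1L - K))
      expect_equal(reg$row_max, min(16L, rows[2] + K))
      expect_equal(reg$col_min, max(0L, cols[1] - 1L - K))
      expect_equal(reg$col_max, min(16L, cols[2] + K))
    }
  }
})

test_that("the salient-change module weights the crop as documented", {
  set.seed(72)
  img <- matrix(runif(32 * 32), 32, 32)
  region <- binarize_and_box(matrix(1, 32, 32), 0.5, margin = 0L)
  # P == 1 inside the region: identity weighting
  x1 <- salient_change(img, matrix(1, 32, 32), region, 32L, eps = 0.5)
  expect_lt(max(abs(ag_value(x1)[, , 1] - img)), 1e-9)
  # P == 0: the eps floor scales intensities by 0.5
  x0 <- salient_change(img, matrix(0, 32, 32), region, 32L, eps = 0.5)
  expect_lt(max(abs(ag_value(x0)[, , 1] - img / 2)), 1e-9)
  # saliency off ignores P entirely
  xs <- salient_change(img, matrix(0, 32, 32), region, 32L,
                       use_saliency = FALSE)
  expect_lt(max(abs(ag_value(xs)[, , 1] - img)), 1e-9)
})

test_that("paste_back restores coordinates and handles degenerate predictions", {
  pred <- matrix(0, 16, 16)
  pred[5:8, 9:12] <- 1
  full <- c(32L, 32L)
  region <- structure(list(row_min = 4L, row_max = 20L, col_min = 8L,
                           col_max = 24L, margin = 0L),
                      class = "crop_region")
  out <- paste_back(pred, region, full, 0.5)
  expect_equal(dim(out), c(32, 32))
  expect_equal(sum(out), 16)           # same-size paste: no resize at all
  expect_equal(out[9:12, 17:20], matrix(1, 4, 4))
  expect_true(all(out[-(5:20), ] == 0))
  expect_equal(sum(paste_back(matrix(0, 16, 16), region, full)), 0)

  # single above-threshold pixel lands inside the region bounds
  p1 <- matrix(0, 16, 16); p1[1, 1] <- 1
  o1 <- paste_back(p1, region, full, 0.5)
  hit <- which(o1 > 0, arr.ind = TRUE)
  expect_true(all(hit[, 1] >= 5 & hit[, 1] <= 20))
  expect_true(all(hit[, 2] >= 9 & hit[, 2] <= 24))
})

test_that("crop and paste round-trip exactly when no resizing occurs", {
  set.seed(73)
  mask <- matrix(rbinom(1024, 1, 0.2), 32, 32)
  region <- structure(list(row_min = 8L, row_max = 24L, col_min = 4L,
                           col_max = 20L, margin = 0L),
                      class = "crop_region")
  cropped <- mask[pancseg:::region_rows(region), pancseg:::region_cols(region)]
  out <- paste_back(cropped, region, c(32L, 32L), 0.5)
  expect_equal(out[pancseg:::region_rows(region),
                   pancseg:::region_cols(region)], cropped)
  expect_true(all(out[1:8, ] == 0))
})

test_that("stage-2 forward emits five coarse-to-fine predictions (one when ablated)", {
  set.seed(74)
  model <- cascade_new(slim_cascade_config(32L), seed = 74)
  x <- pancseg:::ag_const(array(runif(32 * 32), c(32, 32, 1)))
  out <- stage2_forward(model, x)
  expect_length(out$logits, 5L)
  sizes <- vapply(out$logits, function(t) dim(ag_value(t))[1], numeric(1))
  expect_equal(sizes, c(2, 4, 8, 16, 32))
  for (p in out$probs) {
    v <- ag_value(p)
    expect_equal(dim(v), c(32, 32))
    expect_true(all(v > 0 & v < 1))
  }
  abl <- cascade_config(base_channels = 8L, stage2_input_size = 32L,
                        reduce_channels = 16L, use_focusing = FALSE)
  model_abl <- cascade_new(abl, seed = 74)
  out_abl <- stage2_forward(model_abl, x)
  expect_length(out_abl$logits, 1L)
})

test_that("saliency coupling controls whether stage-2 losses reach stage-1 parameters", {
  set.seed(75)
  cfgm <- slim_cascade_config(32L)
  model <- cascade_new(cfgm, seed = 75)
  s <- generate_slice(slim_phantom_config(32L), "g", 0L)
  p1 <- collect_params(model$stage1)

  # step-S conditions: decoupled
  l <- cascade_losses(model, s, saliency_on = FALSE,
                      crop_source = "ground_truth")
  ag_backward(l$seg2_t)
  g_off <- vapply(p1, function(p) if (is.null(p$grad)) 0 else sum(abs(p$grad)),
                  numeric(1))
  expect_true(all(g_off == 0))
  for (p in collect_params(model)) p$grad <- NULL

  # step-I conditions: coupled through the salient-change module
  l <- cascade_losses(model, s, saliency_on = TRUE,
                      crop_source = "ground_truth")
  ag_backward(l$seg2_t)
  g_on <- vapply(p1, function(p) if (is.null(p$grad)) 0 else sum(abs(p$grad)),
                 numeric(1))
  expect_gt(sum(g_on), 0)
})

test_that("a miniature schedule logs one row per epoch with persistent optimizer", {
  set.seed(76)
  model <- cascade_new(slim_cascade_config(32L), seed = 76)
  samples <- lapply(1:2, function(i)
    generate_slice(slim_phantom_config(32L), "t", i - 1L))
  sched <- train_schedule(1L, 1L, 2L)
  fit <- run_schedule(model, samples, sched, lr = 1e-4, seed = 76)
  expect_s3_class(fit$log, "tbl_df")
  expect_equal(nrow(fit$log), 4L)
  expect_equal(fit$log$step, c("S", "I", "J", "J"))
  expect_true(all(is.finite(fit$log$total)))
  expect_error(run_schedule(model, list(), sched), "empty")

  # fixed seed reproduces the epoch-0 loss from a fresh model
  m1 <- cascade_new(slim_cascade_config(32L), seed = 99)
  f1 <- run_schedule(m1, samples, train_schedule(1L, 0L, 0L), lr = 1e-4,
                     seed = 5)
  m2 <- cascade_new(slim_cascade_config(32L), seed = 99)
  f2 <- run_schedule(m2, samples, train_schedule(1L, 0L, 0L), lr = 1e-4,
                     seed = 5)
  expect_equal(f1$log$total, f2$log$total, tolerance = 1e-12)

  # broom-style accessors
  expect_equal(nrow(tidy(fit)), 4L)
  expect_equal(glance(fit)$epochs, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("checkpoints round-trip model parameters", {
  set.seed(77)
  model <- cascade_new(slim_cascade_config(32L), seed = 77)
  path <- file.path(tempdir(), "ck.rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  img <- matrix(runif(32 * 32), 32, 32)
  p1 <- predict_slice(model, img)
  p2 <- predict_slice(back, img)
  expect_equal(p1$stage1_prob, p2$stage1_prob, tolerance = 1e-12)
  expect_equal(p1$final_mask, p2$final_mask)
})
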