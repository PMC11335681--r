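# Closed-form loss values are hand-derived; the shared-boundary matrix is
# checked against a brute-force edge-enumeration oracle.

test_that("dice loss matches hand counts and complements the Dice metric", {
  # |X| = 2, |Y| = 4, overlap 2 -> 1 - 4/6 = 1/3
  pred <- matrix(0, 4, 4); pred[1, 1:2] <- 1
  gt <- matrix(0, 4, 4); gt[1, 1:4] <- 1
  expect_equal(dice_loss(pred, gt), 1 / 3, tolerance = 1e-6)
  expect_equal(dice_loss(gt, gt), 0, tolerance = 1e-6)
  disj <- matrix(0, 4, 4); disj[4, 1:2] <- 1
  expect_equal(dice_loss(disj, gt), 1, tolerance = 1e-6)
  expect_error(dice_loss(matrix(0, 2, 2), gt), "shapes differ")

  set.seed(61)
  for (i in 1:100) {
    p <- matrix(rbinom(64, 1, 0.4), 8, 8)
    g <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(dice_loss(p, g), 1 - dice_coef(confusion(p, g)),
                 tolerance = 1e-5)
  }
})

test_that("localization loss matches the single-pixel closed form", {
  expect_equal(localization_loss(matrix(0.5), matrix(1)), log(2) + 0.5,
               tolerance = 1e-6)
  # saturated perfect prediction: both terms vanish
  p_hi <- matrix(1 / (1 + exp(-20)), 3, 3)
  g <- matrix(1, 3, 3)
  expect_lt(localization_loss(p_hi, g), 1e-3)
  set.seed(62)
  for (i in 1:20) {
    l <- localization_loss(matrix(runif(16), 4, 4),
                           matrix(rbinom(16, 1, 0.5), 4, 4))
    expect_gte(l, 0)
  }
})

test_that("boundary weights emphasize edges and the focusing loss degenerates correctly", {
  gt <- matrix(0, 9, 9); gt[3:7, 3:7] <- 1
  w <- boundary_weight_map(gt, mu = 5, k = 3L)
  border_px <- cbind(c(3, 3, 7, 5), c(3, 5, 7, 7))
  interior_px <- cbind(5, 5)
  expect_gt(min(w[border_px]), w[interior_px])

  # spatially constant gt: weights are exactly 1 away from the zero-padded
  # frame, and the loss reduces to plain BCE + IoU when weights are all 1
  gt1 <- matrix(1, 9, 9)
  w1 <- boundary_weight_map(gt1, mu = 5, k = 3L)
  expect_true(all(w1[2:8, 2:8] == 1))
  set.seed(63)
  p <- matrix(runif(81), 9, 9)
  expect_equal(focusing_loss(p, gt1, mu = 0), localization_loss(p, gt1),
               tolerance = 1e-9)

  # hand-computed 3x3 case with mu = 5
  g3 <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  p3 <- matrix(0.5, 3, 3)
  w3 <- 1 + 5 * abs(pancseg:::box_mean_cpp(g3, 3L) - g3)
  ce <- -(g3 * log(0.5) + (1 - g3) * log(0.5))
  wbce <- sum(w3 * ce) / sum(w3)
  inter <- sum(w3 * p3 * g3)
  union <- sum(w3 * (p3 + g3 - p3 * g3))
  wiou <- 1 - (inter + 1e-6) / (union + 1e-6)
  expect_equal(focusing_loss(p3, g3, mu = 5, k = 3L), wbce + wiou,
               tolerance = 1e-9)
})

test_that("stage-2 aggregation uses the 2^(4-i) deep-supervision weights", {
  expect_equal(stage2_level_weights(), c(4, 2, 1, 0.5))
  expect_equal(sum(c(1, stage2_level_weights()) * 1), 8.5)
  set.seed(64)
  gt <- matrix(rbinom(64, 1, 0.3), 8, 8)
  loc <- matrix(runif(64), 8, 8)
  focs <- lapply(1:4, function(i) matrix(runif(64), 8, 8))
  total <- stage2_total(loc, focs, gt)
  manual <- localization_loss(loc, gt) +
    sum(stage2_level_weights() *
          vapply(focs, function(p) focusing_loss(p, gt), numeric(1)))
  expect_equal(total, manual, tolerance = 1e-9)
  expect_error(stage2_total(loc, focs[1:3], gt), "expected 4")
})

test_that("hard labels take the argmax with ties to the lowest class", {
  probs <- array(0, c(1, 2, 2))
  probs[1, 1, ] <- c(0.9, 0.1)
  probs[1, 2, ] <- c(0.5, 0.5)
  lab <- hard_labels(probs)
  expect_equal(lab[1, 1], 1L)
  expect_equal(lab[1, 2], 1L)      # documented tie rule
  expect_error(hard_labels(array(1, c(2, 2, 1))), "n_c >= 2")
  expect_equal(binary_labels(matrix(c(0.4, 0.6), 1, 2)),
               matrix(c(1L, 2L), 1, 2))
})

test_that("the shared-boundary matrix matches the worked 3x3 example exactly", {
  lab <- matrix(2L, 3, 3)
  lab[1:2, 1:2] <- 1L
  m <- isb_matrix(lab, 2L)
  # class 1: 4 border edges + 4 inter-class edges -> perimeter 8, shared 4
  expect_equal(m[1, 2], 0.5)
  # class 2: 8 border edges + 4 shared -> 4/12
  expect_equal(m[2, 1], 1 / 3)
  expect_equal(diag(m), c(0, 0))
  # single-class map: no boundaries at all
  expect_equal(isb_matrix(matrix(1L, 3, 3), 2L), matrix(0, 2, 2))
  expect_error(isb_matrix(matrix(5L, 2, 2), 2L), "labels must lie")
})

test_that("isb_matrix equals the brute-force edge-enumeration oracle", {
  set.seed(65)
  for (i in 1:200) {
    n_c <- sample(2:4, 1)
    lab <- matrix(sample.int(n_c, 64, replace = TRUE), 8, 8)
    m <- isb_matrix(lab, n_c)
    expect_identical(m, oracle_isb(lab, n_c))
    expect_true(all(rowSums(m) <= 1 + 1e-12))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("the shared-boundary loss is an MSE over matrices with known cases", {
  gt_lab <- matrix(2L, 3, 3); gt_lab[1:2, 1:2] <- 1L
  # prediction that is all class 2 -> zero matrix
  pred_probs <- array(0, c(3, 3, 2)); pred_probs[, , 2] <- 1
  m_gt <- isb_matrix(gt_lab, 2L)
  expect_equal(isb_loss(pred_probs, gt_lab, 2L),
               (m_gt[1, 2]^2 + m_gt[2, 1]^2) / 4, tolerance = 1e-12)
  # exact match -> 0
  exact <- array(0, c(3, 3, 2))
  exact[, , 1] <- (gt_lab == 1L); exact[, , 2] <- (gt_lab == 2L)
  expect_equal(isb_loss(exact, gt_lab, 2L), 0)
  set.seed(66)
  for (i in 1:25) {
    pp <- matrix(runif(64), 8, 8)
    gl <- matrix(sample.int(2L, 64, replace = TRUE), 8, 8)
    l <- isb_loss(pp, gl, 2L)
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("the total loss mixes components with alpha and beta", {
  expect_equal(total_loss(1, 1, 1, alpha = 0.9, beta = 0.4), 2.3,
               tolerance = 1e-12)
  expect_equal(total_loss(0.3, 0.7, 0.1, beta = 0), 0.3 + 0.9 * 0.7)
  expect_equal(total_loss(0, 0, 0), 0)
})
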