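test_that("foreground and background attention split reconstructs the features", {
  set.seed(51)
  fc <- rand_feat(8, 8, 8)
  pred <- rand_feat(4, 4, 1)
  att <- split_attention(ag_const(fc), ag_const(pred))
  expect_lt(max(abs(ag_value(att$fa) + ag_value(att$ba) - fc)), 1e-6)
  expect_true(all(ag_value(att$a) >= 0 & ag_value(att$a) <= 1))

  # saturated logits: everything is foreground
  att_hi <- split_attention(ag_const(fc), ag_const(array(40, c(8, 8, 1))))
  expect_lt(max(abs(ag_value(att_hi$fa) - fc)), 1e-6)
  expect_lt(max(abs(ag_value(att_hi$ba))), 1e-6)

  # zero logits: both halves get exactly half
  att_0 <- split_attention(ag_const(fc), ag_const(array(0, c(8, 8, 1))))
  expect_equal(ag_value(att_0$fa), fc / 2, tolerance = 1e-12)
  expect_equal(ag_value(att_0$ba), fc / 2, tolerance = 1e-12)

  expect_error(split_attention(ag_const(fc), ag_const(rand_feat(2, 2, 1))),
               "resolution")
})

test_that("context exploration preserves spatial size and has growing receptive fields", {
  set.seed(52)
  ce <- context_exploration_new(8L)
  for (hw in list(c(6L, 6L), c(9L, 5L), c(17L, 17L))) {
    out <- context_exploration(ce, ag_const(rand_feat(hw[1], hw[2], 8)))
    expect_equal(dim(ag_value(out)), c(hw, 8L))
  }
  rf <- context_exploration_receptive_fields()
  expect_equal(length(rf), 4L)
  expect_true(all(diff(rf) > 0))
  # branch 1: 3x3 reduce + 1x1 local + 3x3 dilation-1 = 5-pixel extent
  expect_equal(rf[1], 5L)
  # zero input stays zero through conv + BN(beta = 0) + ReLU
  z <- context_exploration(ce, ag_const(array(0, c(6, 6, 8))))
  expect_true(all(ag_value(z) == 0))
})

test_that("the false-positive and false-negative paths share no parameters", {
  set.seed(53)
  mod <- focusing_new(8L)
  ids_fp <- vapply(collect_params(mod$ce_fp), function(p) p$id, numeric(1))
  ids_fn <- vapply(collect_params(mod$ce_fn), function(p) p$id, numeric(1))
  expect_length(intersect(ids_fp, ids_fn), 0L)
  expect_equal(length(ids_fp), length(ids_fn))
})

test_that("with lambda = gamma = 0 the refined features ignore the current level", {
  set.seed(54)
  mod <- focusing_new(8L)
  mod$lambda$value <- 0
  mod$gamma$value <- 0
  fh <- rand_feat(4, 4, 8)
  pred <- rand_feat(4, 4, 1)
  f_c1 <- rand_feat(8, 8, 8)
  f_c2 <- rand_feat(8, 8, 8)        # completely different current features
  r1 <- focusing_refine(mod, ag_const(f_c1), ag_const(fh), ag_const(pred))
  r2 <- focusing_refine(mod, ag_const(f_c2), ag_const(fh), ag_const(pred))
  expect_lt(max(abs(ag_value(r1$features) - ag_value(r2$features))), 1e-9)
  expect_lt(max(abs(ag_value(r1$logits) - ag_value(r2$logits))), 1e-9)
})

test_that("the refinement follows the subtract-then-add interference algebra", {
  set.seed(55)
  mod <- focusing_new(8L)
  fc <- rand_feat(8, 8, 8)
  fh <- rand_feat(4, 4, 8)
  pred <- rand_feat(4, 4, 1)
  res <- focusing_refine(mod, ag_const(fc), ag_const(fh), ag_const(pred))
  # independent recomputation from the module's own pieces with plain math
  bn_ref <- function(x, gamma, beta, eps = 1e-5) {
    dm <- dim(x); N <- dm[1] * dm[2]
    xm <- matrix(x, N, dm[3])
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    xh <- (xm - rep(mu, each = N)) / rep(sqrt(v + eps), each = N)
    array(xh * rep(gamma, each = N) + rep(beta, each = N), dim = dm)
  }
  f_up <- ag_value(ag_bilinear(conv_forward(mod$cbr, ag_const(fh)), 8L, 8L))
  f_fpd <- ag_value(res$fpd)
  f_fnd <- ag_value(res$fnd)
  f_r <- pmax(bn_ref(f_up - mod$lambda$value * f_fpd,
                     mod$br1$gamma$value, mod$br1$beta$value), 0)
  f_rp <- pmax(bn_ref(f_r + mod$gamma$value * f_fnd,
                      mod$br2$gamma$value, mod$br2$beta$value), 0)
  expect_lt(max(abs(ag_value(res$features) - f_rp)), 1e-8)
})

test_that("gradient reaches lambda and gamma from a loss on the refined prediction", {
  set.seed(56)
  mod <- focusing_new(8L)
  res <- focusing_refine(mod, ag_const(rand_feat(8, 8, 8)),
                         ag_const(rand_feat(4, 4, 8)),
                         ag_const(rand_feat(4, 4, 1)))
  ag_backward(ag_sum(ag_mul(res$logits, res$logits)))
  expect_gt(abs(mod$lambda$grad), 0)
  expect_gt(abs(mod$gamma$grad), 0)
})

test_that("a bright distractor outside the target raises false-positive interference there", {
  set.seed(57)
  # fixed-seed fixture: features with an active blob outside the predicted
  # foreground region produce larger FP-interference energy in the blob's
  # support than elsewhere, after a short fit pushing prediction toward gt
  mod <- focusing_new(4L)
  H <- 12L
  fc <- array(0.1, c(H, H, 4))
  blob <- matrix(FALSE, H, H); blob[9:11, 9:11] <- TRUE
  for (c_ in 1:4) fc[, , c_][blob] <- 2.5     # distractor far from target
  target <- matrix(0, H, H); target[2:4, 2:4] <- 1
  pred_h <- array(-2, c(6, 6, 1)); pred_h[1:2, 1:2, 1] <- 2
  fh <- rand_feat(6, 6, 4)
  opt <- sgd_new(collect_params(mod), lr = 1e-2, momentum = 0.9,
                 weight_decay = 0)
  for (i in 1:30) {
    res <- focusing_refine(mod, ag_const(fc), ag_const(fh), ag_const(pred_h))
    loss <- focusing_loss(pancseg:::ag_squeeze(ag_sigmoid(res$logits)), target)
    ag_backward(loss)
    opt <- sgd_step(opt)
  }
  res <- focusing_refine(mod, ag_const(fc), ag_const(fh), ag_const(pred_h))
  fpd_energy <- apply(abs(ag_value(res$fpd)), c(1, 2), mean)
  expect_gte(mean(fpd_energy[blob]), mean(fpd_energy[!blob]))
})
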