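# ---------------------------------------------------------------------------
# Focusing module: reverse-attention refinement with context exploration.
#
# The higher level's prediction is upsampled and squashed to an attention
# map a in [0,1]; the current level's features split exactly into
# foreground-attended F_fa = F_c * a and background-attended
# F_ba = F_c * (1 - a) (so F_fa + F_ba == F_c). Two *separate* context-
# exploration blocks mine false-positive interference from F_fa and
# false-negative interference from F_ba. The refinement then subtracts the
# false-positive term and adds the false-negative term around an upsampled
# projection of the higher-level features:
#   F_up = U(CBR(F_h)); F_r = BR(F_up - lambda*F_fpd);
#   F_r' = BR(F_r + gamma*F_fnd)
# with lambda, gamma learnable scales initialized at 1, U bilinear
# upsampling, and BR batch-norm + ReLU. A 3x3 head on F_r' gives the level's
# refined prediction.
# ---------------------------------------------------------------------------

CE_KERNELS <- c(1L, 3L, 5L, 7L)
CE_DILATIONS <- c(1L, 2L, 4L, 8L)

#' Construct a context-exploration block
#'
#' Four chained branches; branch i applies a 3x3 channel-reduction
#' convolution, a K_i x K_i local convolution and a 3x3 dilated convolution
#' with rate r_i, K = (1,3,5,7), r = (1,2,4,8), every convolution followed
#' by BN + ReLU. Branch i's output is added to branch (i+1)'s reduced input,
#' chaining receptive fields; the four outputs are concatenated and fused by
#' a 3x3 convolution.
#'
#' @param channels Input/output channel count; each branch runs at
#'   `max(1, channels/4)`.
#' @return A `pancseg_context_exploration` module.
#' @export
context_exploration_new <- function(channels) {
  C <- as.integer(channels)
  cb <- max(1L, C %/% 4L)
  branches <- lapply(1:4, function(i) {
    list(reduce = conv_block(C, cb, 3L),
         local = conv_block(cb, cb, CE_KERNELS[i]),
         dilated = conv_block(cb, cb, 3L, dil = CE_DILATIONS[i]))
  })
  structure(list(channels = C, branch_width = cb, branches = branches,
                 fuse = conv_block(4L * cb, C, 3L)),
            class = "pancseg_context_exploration")
}

#' Context-exploration forward pass
#'
#' @param ce A [context_exploration_new()] module.
#' @param f_in Input feature tensor (H, W, C); spatial size is preserved.
#' @return Interference feature tensor (H, W, C).
#' @export
context_exploration <- function(ce, f_in) {
  if (!is_ag_tensor(f_in)) f_in <- ag_const(f_in)
  outs <- vector("list", 4L)
  prev <- NULL
  for (i in 1:4) {
    br <- ce$branches[[i]]
    h <- conv_forward(br$reduce, f_in)
    if (!is.null(prev)) h <- ag_add(h, prev)
    h <- conv_forward(br$dilated, conv_forward(br$local, h))
    outs[[i]] <- h
    prev <- h
  }
  conv_forward(ce$fuse, ag_concat(outs))
}

#' Analytic receptive field of each context-exploration branch
#'
#' One-sided kernel extents accumulate along the chained convolution path
#' (reduce 3x3, then for each branch up to i: K_i local + dilated 3x3 at
#' rate r_i), so the receptive field grows strictly from branch 1 to 4.
#' @return Integer vector of receptive-field side lengths for branches 1..4.
#' @export
context_exploration_receptive_fields <- function() {
  rf <- integer(4)
  acc <- 0L
  for (i in 1:4) {
    # each branch's own path: local K_i then dilated 3x3 rate r_i
    acc <- acc + (CE_KERNELS[i] - 1L) + CE_DILATIONS[i] * 2L
    rf[i] <- 1L + 2L + acc                 # + reduce conv's 3x3
  }
  rf
}

#' Construct a focusing module
#'
#' @param channels Channel count of the (reduced) decoder features at this
#'   level.
#' @return A `pancseg_focusing` module with two independent
#'   context-exploration blocks (false-positive and false-negative paths),
#'   a CBR projection for the higher-level features, two BR stages, the
#'   learnable scales `lambda` and `gamma` (both initialized at 1) and a
#'   3x3 prediction head.
#' @export
focusing_new <- function(channels) {
  C <- as.integer(channels)
  structure(list(
    channels = C,
    ce_fp = context_exploration_new(C),
    ce_fn = context_exploration_new(C),
    cbr = conv_block(C, C, 3L),
    br1 = list(gamma = new_param(rep(1, C)), beta = new_param(rep(0, C))),
    br2 = list(gamma = new_param(rep(1, C)), beta = new_param(rep(0, C))),
    lambda = new_param(1),
    gamma = new_param(1),
    head = list(type = "conv", k = 3L, pad = 1L, dil = 1L, bn = FALSE,
                act = "none", W = new_param(he_init(1L, C * 9L)),
                b = new_param(rep(0, 1)))
  ), class = "pancseg_focusing")
}

#' Split features into foreground- and background-attended parts
#'
#' The higher-level prediction logits are upsampled to the current level's
#' size and squashed with the logistic function (the two-class softmax on a
#' single-channel map); `F_fa = F_c * a`, `F_ba = F_c * (1 - a)`, so the
#' two parts always sum back to `F_c`.
#'
#' @param f_c Current-level feature tensor (H, W, C).
#' @param pred_h Higher-level prediction logits ((h, w, 1) tensor) at the
#'   same or half the resolution of `f_c`.
#' @return List with `fa`, `ba` and the attention map `a`.
#' @export
split_attention <- function(f_c, pred_h) {
  if (!is_ag_tensor(f_c)) f_c <- ag_const(f_c)
  if (!is_ag_tensor(pred_h)) pred_h <- ag_const(pred_h)
  dc <- dim(ag_value(f_c)); dh <- dim(ag_value(pred_h))
  ratio <- dc[1] / dh[1]
  if (!(ratio %in% c(1, 2)) || dc[2] / dh[2] != ratio)
    stop(sprintf("prediction resolution %dx%d must equal or halve feature resolution %dx%d",
                 dh[1], dh[2], dc[1], dc[2]))
  a <- ag_squeeze(ag_sigmoid(ag_bilinear(pred_h, dc[1], dc[2])))
  fa <- ag_mul_map(f_c, a)
  ba <- ag_mul_map(f_c, ag_sub(1, a))
  list(fa = fa, ba = ba, a = a)
}

#' Focusing refinement
#'
#' Mines false-positive interference from the foreground-attended features
#' and false-negative interference from the background-attended features
#' (two context-exploration blocks with disjoint parameters), removes the
#' former and restores the latter around the upsampled higher-level
#' features, and predicts from the refined features.
#'
#' @param mod A [focusing_new()] module.
#' @param f_c Current-level (reduced) feature tensor.
#' @param f_h Higher-level refined feature tensor (same channel count; at
#'   the same or half the spatial size of `f_c`).
#' @param pred_h Higher-level prediction logits.
#' @return List with `features` (F_r'), `logits` (refined prediction,
#'   (H, W, 1) tensor at `f_c`'s size) and the interference maps `fpd`,
#'   `fnd`.
#' @export
focusing_refine <- function(mod, f_c, f_h, pred_h) {
  if (!is_ag_tensor(f_c)) f_c <- ag_const(f_c)
  if (!is_ag_tensor(f_h)) f_h <- ag_const(f_h)
  att <- split_attention(f_c, pred_h)
  f_fpd <- context_exploration(mod$ce_fp, att$fa)
  f_fnd <- context_exploration(mod$ce_fn, att$ba)
  dc <- dim(ag_value(f_c))
  f_up <- ag_bilinear(conv_forward(mod$cbr, f_h), dc[1], dc[2])
  f_r <- ag_relu(ag_batchnorm(ag_sub(f_up, ag_scale(f_fpd, mod$lambda)),
                              mod$br1$gamma, mod$br1$beta))
  f_rp <- ag_relu(ag_batchnorm(ag_add(f_r, ag_scale(f_fnd, mod$gamma)),
                               mod$br2$gamma, mod$br2$beta))
  list(features = f_rp,
       logits = conv_forward(mod$head, f_rp),
       fpd = f_fpd, fnd = f_fnd)
}
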