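# ---------------------------------------------------------------------------
# Dual-encoder multi-scale U-Net backbone.
#
# Two contraction branches run in parallel: branch 1 stacks two 3x3
# convolutions per block; branch 2 runs a 1x1 -> 3x3 path and a 5x5 -> 3x3
# path, concatenates them and restores the nominal width with a trailing 1x1.
# Both branches end each block with 2x2 max pooling. A central layer fuses
# three paths (1x1 -> 3x3 from branch 1, 3x3 -> 3x3 and 5x5 -> 3x3 from
# branch 2) by concatenation plus a fusing 1x1. The decoder upsamples with
# stride-2 transposed convolutions and has TWO skip connections per level:
# branch 1's pre-pool features are concatenated after the upsample, branch
# 2's after the first decoder convolution.
#
# Channel plan (a design choice; widths are not dictated by the
# architecture): a stem maps the image to `base_channels`; each block doubles
# the width, so pre-pool skip widths are base*2^l at level l = 1..4; the
# central layer keeps per-path width base*16 and fuses 3 paths down to
# base*32. Every convolution is followed by batch normalization and ReLU
# unless noted. All of it is configuration-driven so tests can run a slim
# base-8 variant.
# ---------------------------------------------------------------------------

#' Backbone configuration
#'
#' @param in_channels Input image channels (1 for grayscale CT).
#' @param base_channels Width of the stem block; each of the four
#'   contraction blocks doubles it (default 32; tests use 8).
#' @param out_channels Output channels of the probability head (1 for a
#'   binary map).
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(in_channels = 1L, base_channels = 32L,
                            out_channels = 1L) {
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 out_channels = as.integer(out_channels),
                 depth = 4L),
            class = "backbone_config")
}

# Skip width at level l (pre-pool output of block l).
bb_width <- function(base, l) base * 2L^l

#' Construct a multi-scale U-Net backbone
#'
#' @param config A [backbone_config()].
#' @return A `pancseg_backbone` module (list of layers and parameters).
#' @export
backbone_new <- function(config = backbone_config()) {
  base <- config$base_channels
  stem <- conv_block(config$in_channels, base, 3L)
  blocks <- lapply(1:4, function(l) {
    cin <- if (l == 1L) base else bb_width(base, l - 1L)
    cout <- bb_width(base, l)
    list(
      b1 = list(conv_block(cin, cout, 3L), conv_block(cout, cout, 3L)),
      b2 = list(p1a = conv_block(cin, cout, 1L),
                p1b = conv_block(cout, cout, 3L),
                p2a = conv_block(cin, cout, 5L),
                p2b = conv_block(cout, cout, 3L),
                fuse = conv_block(2L * cout, cout, 1L))
    )
  })
  w5 <- bb_width(base, 4L)
  central <- list(p1a = conv_block(w5, w5, 1L), p1b = conv_block(w5, w5, 3L),
                  p2a = conv_block(w5, w5, 3L), p2b = conv_block(w5, w5, 3L),
                  p3a = conv_block(w5, w5, 5L), p3b = conv_block(w5, w5, 3L),
                  fuse = conv_block(3L * w5, 2L * w5, 1L))
  decoders <- lapply(4:1, function(l) {
    sw <- bb_width(base, l)               # skip width at this level
    din <- if (l == 4L) 2L * w5 else bb_width(base, l + 1L)
    list(up = deconv_block(din, sw),
         c1 = conv_block(2L * sw, sw, 3L),
         c2 = conv_block(2L * sw, sw, 3L))
  })
  head <- list(type = "conv", k = 1L, pad = 0L, dil = 1L, bn = FALSE,
               act = "none",
               W = new_param(he_init(config$out_channels, bb_width(base, 1L))),
               b = new_param(rep(0, config$out_channels)))
  structure(list(config = config, stem = stem, blocks = blocks,
                 central = central, decoders = decoders, head = head),
            class = "pancseg_backbone")
}

#' Analytic parameter count of a backbone
#'
#' Pure function of the configuration (conv weights + biases + batch-norm
#' affine parameters), cross-checked in tests against the instantiated
#' module.
#' @param config A [backbone_config()].
#' @export
backbone_param_count <- function(config) {
  base <- config$base_channels
  conv_n <- function(cin, cout, k, bn = TRUE) cin * cout * k * k +
    (if (bn) 2 * cout else cout)
  n <- conv_n(config$in_channels, base, 3)
  for (l in 1:4) {
    cin <- if (l == 1L) base else bb_width(base, l - 1L)
    cout <- bb_width(base, l)
    n <- n + conv_n(cin, cout, 3) + conv_n(cout, cout, 3) +     # branch 1
      conv_n(cin, cout, 1) + conv_n(cout, cout, 3) +            # branch 2 p1
      conv_n(cin, cout, 5) + conv_n(cout, cout, 3) +            # branch 2 p2
      conv_n(2 * cout, cout, 1)                                 # fuse
  }
  w5 <- bb_width(base, 4L)
  n <- n + conv_n(w5, w5, 1) + conv_n(w5, w5, 3) +
    conv_n(w5, w5, 3) + conv_n(w5, w5, 3) +
    conv_n(w5, w5, 5) + conv_n(w5, w5, 3) +
    conv_n(3 * w5, 2 * w5, 1)
  for (l in 4:1) {
    sw <- bb_width(base, l)
    din <- if (l == 4L) 2L * w5 else bb_width(base, l + 1L)
    n <- n + din * sw * 4 + sw +                                # deconv
      conv_n(2 * sw, sw, 3) + conv_n(2 * sw, sw, 3)
  }
  n + bb_width(base, 1L) * config$out_channels + config$out_channels
}

#' Branch-1 contraction step
#'
#' Two 3x3 convolutions (each BN + ReLU) then 2x2 max pooling. Returns both
#' the pooled output (next block's input) and the pre-pool features used as
#' the level's first skip connection.
#'
#' @param block One element of a backbone's `blocks` list.
#' @param x Input tensor (H, W, C).
#' @return List with `pooled` and `skip` tensors.
#' @export
encode_branch1 <- function(block, x) {
  skip <- seq_forward(block$b1, x)
  list(pooled = ag_maxpool2(skip), skip = skip)
}

#' Branch-2 contraction step
#'
#' Two parallel paths (1x1 -> 3x3 and 5x5 -> 3x3) over the same input,
#' concatenated, fused back to nominal width by a 1x1 convolution, then
#' pooled. Padding keeps both paths spatially aligned for any input size.
#'
#' @inheritParams encode_branch1
#' @export
encode_branch2 <- function(block, x) {
  p1 <- conv_forward(block$b2$p1b, conv_forward(block$b2$p1a, x))
  p2 <- conv_forward(block$b2$p2b, conv_forward(block$b2$p2a, x))
  skip <- conv_forward(block$b2$fuse, ag_concat(list(p1, p2)))
  list(pooled = ag_maxpool2(skip), skip = skip)
}

#' Central fusion layer
#'
#' Three paths — 1x1 -> 3x3 on the branch-1 input, 3x3 -> 3x3 and 5x5 -> 3x3
#' on the branch-2 input — concatenated in that fixed order and fused by a
#' 1x1 convolution to twice the per-path width. No pooling.
#'
#' @param central A backbone's `central` sub-module.
#' @param c4_1,c4_2 Deepest pooled outputs of the two encoder branches
#'   (spatially aligned).
#' @export
central_fuse <- function(central, c4_1, c4_2) {
  d1 <- dim(ag_value(c4_1)); d2 <- dim(ag_value(c4_2))
  if (!all(d1[1:2] == d2[1:2]))
    stop("central layer inputs are spatially misaligned: ",
         paste(d1[1:2], collapse = "x"), " vs ", paste(d2[1:2], collapse = "x"))
  p1 <- conv_forward(central$p1b, conv_forward(central$p1a, c4_1))
  p2 <- conv_forward(central$p2b, conv_forward(central$p2a, c4_2))
  p3 <- conv_forward(central$p3b, conv_forward(central$p3a, c4_2))
  conv_forward(central$fuse, ag_concat(list(p1, p2, p3)))
}

#' Decoder step with two skip connections
#'
#' Transposed-convolution upsample (x2), concatenate branch-1's skip, 3x3
#' convolution, concatenate branch-2's skip, 3x3 convolution.
#'
#' @param dec One element of a backbone's `decoders` list.
#' @param u Coarser decoder feature.
#' @param skip1,skip2 Pre-pool encoder features at 2x the spatial size of
#'   `u`.
#' @export
decode_block <- function(dec, u, skip1, skip2) {
  up <- deconv_forward(dec$up, u)
  du <- dim(ag_value(up)); ds <- dim(ag_value(skip1))
  if (!all(du[1:2] == ds[1:2]))
    stop("skip connection size mismatch: upsampled ",
         paste(du[1:2], collapse = "x"), " vs skip ",
         paste(ds[1:2], collapse = "x"))
  h <- conv_forward(dec$c1, ag_concat(list(up, skip1)))
  conv_forward(dec$c2, ag_concat(list(h, skip2)))
}

#' Full backbone forward pass
#'
#' @param net A `pancseg_backbone`.
#' @param image H x W matrix (or H x W x C array) with H, W divisible by 16.
#' @return List with `prob` (H x W foreground probability matrix from the
#'   1x1 head + logistic squashing), `logits` (same, pre-squashing) and
#'   `features`: the five decoder/central feature tensors ordered finest to
#'   coarsest (spatial sizes H, H/2, H/4, H/8, H/16).
#' @export
backbone_forward <- function(net, image) {
  x <- if (is_ag_tensor(image)) image else ag_const(image)
  v <- ag_value(x)
  if (is.matrix(v)) {
    x <- ag_node(array(v, dim = c(dim(v), 1L)), list(x),
                 list(function(g) matrix(g, dim(v)[1], dim(v)[2])))
    v <- ag_value(x)
  }
  H <- dim(v)[1]; W <- dim(v)[2]
  if (H %% 16L != 0L || W %% 16L != 0L)
    stop(sprintf("input size %dx%d must be divisible by 16", H, W))
  s <- conv_forward(net$stem, x)
  x1 <- s; x2 <- s
  skips <- vector("list", 4L)
  for (l in 1:4) {
    r1 <- encode_branch1(net$blocks[[l]], x1)
    r2 <- encode_branch2(net$blocks[[l]], x2)
    skips[[l]] <- list(s1 = r1$skip, s2 = r2$skip)
    x1 <- r1$pooled; x2 <- r2$pooled
  }
  u <- central_fuse(net$central, x1, x2)
  feats <- vector("list", 5L)
  feats[[5]] <- u
  for (k in seq_along(net$decoders)) {       # levels 4, 3, 2, 1
    l <- 5L - k
    u <- decode_block(net$decoders[[k]], u, skips[[l]]$s1, skips[[l]]$s2)
    feats[[l]] <- u
  }
  logits_t <- ag_conv2d(feats[[1]], net$head$W, net$head$b, 1L, 0L)
  prob_t <- ag_sigmoid(logits_t)
  list(prob = prob_t, logits = logits_t, features = feats)
}
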