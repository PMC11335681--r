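# ---------------------------------------------------------------------------
# Non-local localization module: channel self-attention followed by spatial
# self-attention on the deepest decoder feature, then a 7x7 prediction head.
# The channel branch uses no learned projections (queries, keys and values
# are the reshaped features themselves); the spatial branch projects with
# three 1x1 convolutions, reducing Q and K to C/8 channels. Both branches
# add their attended output back to the input through a learnable scale
# initialized at 1, so setting the scales to zero makes the whole module
# collapse exactly onto its 7x7 head.
# ---------------------------------------------------------------------------

#' Construct a non-local localization module
#'
#' @param channels Channel count C of the input feature map. The reduced
#'   width for the spatial branch is `max(1, floor(C/8))` so slim test
#'   configurations remain valid.
#' @return A `pancseg_nonlocal` module.
#' @export
nonlocal_new <- function(channels) {
  C <- as.integer(channels)
  if (C < 1L) stop("channels must be >= 1")
  C1 <- max(1L, C %/% 8L)
  structure(list(
    channels = C, reduced = C1,
    gamma_c = new_param(1),
    gamma_s = new_param(1),
    q_conv = list(type = "conv", k = 1L, pad = 0L, dil = 1L, bn = FALSE,
                  act = "none", W = new_param(he_init(C1, C)),
                  b = new_param(rep(0, C1))),
    k_conv = list(type = "conv", k = 1L, pad = 0L, dil = 1L, bn = FALSE,
                  act = "none", W = new_param(he_init(C1, C)),
                  b = new_param(rep(0, C1))),
    v_conv = list(type = "conv", k = 1L, pad = 0L, dil = 1L, bn = FALSE,
                  act = "none", W = new_param(he_init(C, C)),
                  b = new_param(rep(0, C))),
    head = list(type = "conv", k = 7L, pad = 3L, dil = 1L, bn = FALSE,
                act = "none", W = new_param(he_init(1L, C * 49L)),
                b = new_param(rep(0, 1)))
  ), class = "pancseg_nonlocal")
}

#' Channel attention
#'
#' Reshape F to C x N; the attention map is the row-wise softmax of
#' `F F^T` (each row i weights the influence of every channel j on channel
#' i and sums to 1); the output is `gamma_c * (X V) + F`.
#'
#' @param mod A `pancseg_nonlocal`.
#' @param f Feature tensor (H, W, C).
#' @return Channel-attended feature tensor, same shape.
#' @export
channel_attention <- function(mod, f) {
  if (!is_ag_tensor(f)) f <- ag_const(f)
  dm <- dim(ag_value(f))
  q <- ag_to_cn(f)                                   # C x N; Q = K = V
  x <- ag_softmax_rows(ag_matmul(q, ag_transpose(q)))
  att <- ag_from_cn(ag_matmul(x, q), dm[1], dm[2])
  ag_add(ag_scale(att, mod$gamma_c), f)
}

#' Spatial attention
#'
#' Three 1x1 convolutions produce Q', K' (C/8 x N) and V' (C x N). For each
#' output position i the weights over source positions j are the softmax of
#' `Q'_i . K'_j`, so they sum to 1; the output is
#' `gamma_s * (V' X'^T) + F'`.
#'
#' @param mod A `pancseg_nonlocal`.
#' @param f_prime Channel-attended feature tensor (H, W, C).
#' @export
spatial_attention <- function(mod, f_prime) {
  if (!is_ag_tensor(f_prime)) f_prime <- ag_const(f_prime)
  dm <- dim(ag_value(f_prime))
  q <- ag_to_cn(conv_forward(mod$q_conv, f_prime))   # C1 x N
  k <- ag_to_cn(conv_forward(mod$k_conv, f_prime))
  v <- ag_to_cn(conv_forward(mod$v_conv, f_prime))   # C x N
  aff <- ag_matmul(ag_transpose(q), k)               # N x N, [i,j] = Q'_i.K'_j
  xprime <- ag_softmax_rows(aff)                     # rows sum to 1 over j
  att <- ag_from_cn(ag_matmul(v, ag_transpose(xprime)), dm[1], dm[2])
  ag_add(ag_scale(att, mod$gamma_s), f_prime)
}

#' Localize: attention stack plus 7x7 head
#'
#' Channel attention, spatial attention, then a 7x7 convolution (padding 3)
#' producing single-channel logits at the input's spatial size.
#'
#' @param mod A `pancseg_nonlocal`.
#' @param f_top Deepest decoder feature tensor (H, W, C).
#' @return List with `features` (the attended map F'') and `logits`
#'   ((H, W, 1) tensor).
#' @export
nonlocal_localize <- function(mod, f_top) {
  f2 <- spatial_attention(mod, channel_attention(mod, f_top))
  list(features = f2, logits = conv_forward(mod$head, f2))
}
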