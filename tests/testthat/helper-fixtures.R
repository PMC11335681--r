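# Shared test fixtures and small numeric utilities. Everything is generated
# in code under fixed seeds; nothing is read from disk.

slim_cascade_config <- function(stage2_input_size = 32L) {
  cascade_config(base_channels = 8L, stage2_input_size = stage2_input_size,
                 reduce_channels = 16L)
}

slim_phantom_config <- function(image_size = 32L, ...) {
  phantom_config(image_size = image_size, ...)
}

rand_feat <- function(H, W, C, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(H * W * C), dim = c(H, W, C))
}

# Central-difference gradient of scalar-valued f at x0 (numeric array).
numeric_grad <- function(f, x0, eps = 1e-5) {
  g <- array(0, dim = dim(x0) %||% length(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ag_tensor <- pancseg:::ag_tensor
ag_const <- pancseg:::ag_const
ag_value <- pancseg:::ag_value
ag_backward <- pancseg:::ag_backward
ag_sum <- pancseg:::ag_sum
ag_mul <- pancseg:::ag_mul
ag_add <- pancseg:::ag_add
ag_conv2d <- pancseg:::ag_conv2d
ag_deconv2x2 <- pancseg:::ag_deconv2x2
ag_maxpool2 <- pancseg:::ag_maxpool2
ag_bilinear <- pancseg:::ag_bilinear
ag_batchnorm <- pancseg:::ag_batchnorm
ag_softmax_rows <- pancseg:::ag_softmax_rows
ag_matmul <- pancseg:::ag_matmul
ag_transpose <- pancseg:::ag_transpose
ag_sigmoid <- pancseg:::ag_sigmoid
new_param <- pancseg:::new_param
he_init <- pancseg:::he_init
collect_params <- pancseg:::collect_params
n_params <- pancseg:::n_params
sgd_new <- pancseg:::sgd_new
sgd_step <- pancseg:::sgd_step
conv_forward <- pancseg:::conv_forward
conv_block <- pancseg:::conv_block
resize_nearest <- pancseg:::resize_nearest
resize_bilinear <- pancseg:::resize_bilinear

# Sum of a masked product: a convenient scalar head for gradient checks.
masked_sum <- function(t, mask) ag_sum(ag_mul(t, mask))
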