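# ---------------------------------------------------------------------------
# Neural-network building blocks on top of the autodiff engine: 2D
# convolution (via im2col + GEMM), 2x2 transposed convolution, 2x2 max
# pooling, bilinear resizing, per-channel batch normalization, and an SGD
# optimizer with momentum and weight decay. Layers are plain lists holding
# parameter tensors plus metadata; `collect_params()` walks any nested
# structure and returns every leaf tensor that requires gradients.
# ---------------------------------------------------------------------------

# `value + 0` forces a freshly allocated array: parameter storage must never
# alias a shared object (e.g. a bytecode literal like `1`), because the
# optimizer updates it in place.
new_param <- function(value) ag_tensor(value + 0, requires_grad = TRUE)

# He-normal initialization, the standard for ReLU networks.
he_init <- function(cout, fan_in_cols) {
  matrix(stats::rnorm(cout * fan_in_cols, sd = sqrt(2 / fan_in_cols)),
         nrow = cout, ncol = fan_in_cols)
}

# --- convolution ------------------------------------------------------------

# Weight layout: Cout x (Cin*kh*kw); column r = c*kh*kw + i*kw + j matches the
# row ordering produced by im2col_cpp.
ag_conv2d <- function(x, W, b, k, pad, dil = 1L) {
  xv <- x$value
  dm <- dim(xv)
  H <- dm[1]; Wd <- dm[2]; C <- dm[3]
  cols <- im2colT_cpp(xv, H, Wd, C, k, k, pad, dil)   # L x (C*k*k)
  Wv <- W$value
  Cout <- nrow(Wv)
  Hout <- H + 2L * pad - dil * (k - 1L)
  Wout <- Wd + 2L * pad - dil * (k - 1L)
  L <- Hout * Wout
  Y <- tcrossprod(cols, Wv)                           # L x Cout
  if (!is.null(b)) Y <- Y + rep(b$value, each = L)
  out <- array(Y, dim = c(Hout, Wout, Cout))
  parents <- list(x, W)
  vjps <- list(
    function(g) {
      dY <- matrix(g, L, Cout)
      col2imT_cpp(dY %*% Wv, H, Wd, C, k, k, pad, dil)
    },
    function(g) crossprod(matrix(g, L, Cout), cols)
  )
  if (!is.null(b)) {
    parents <- c(parents, list(b))
    vjps <- c(vjps, list(function(g) colSums(matrix(g, L, Cout))))
  }
  ag_node(out, parents, vjps)
}

# Transposed convolution, kernel 2, stride 2: each input pixel expands into a
# 2x2 output block. Weight layout: (Cout*4) x Cin with rows grouped by
# quadrant q = 1..4 for offsets (dy, dx) = (0,0), (1,0), (0,1), (1,1).
ag_deconv2x2 <- function(x, W, b) {
  xv <- x$value
  dm <- dim(xv)
  H <- dm[1]; Wd <- dm[2]; Cin <- dm[3]
  N <- H * Wd
  Xmat <- t(matrix(xv, N, Cin))
  Wv <- W$value
  Cout <- nrow(Wv) %/% 4L
  Y4 <- Wv %*% Xmat
  out <- array(0, dim = c(2L * H, 2L * Wd, Cout))
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (q in 1:4) {
    rows <- (q - 1L) * Cout + seq_len(Cout)
    blk <- array(t(Y4[rows, , drop = FALSE]), dim = c(H, Wd, Cout))
    out[seq(1L + offs[[q]][1], 2L * H, 2L), seq(1L + offs[[q]][2], 2L * Wd, 2L), ] <- blk
  }
  if (!is.null(b)) out <- out + rep(b$value, each = 4L * N)
  parents <- list(x, W)
  gather_dY4 <- function(g) {
    dY4 <- matrix(0, nrow(Wv), N)
    for (q in 1:4) {
      rows <- (q - 1L) * Cout + seq_len(Cout)
      blk <- g[seq(1L + offs[[q]][1], 2L * H, 2L), seq(1L + offs[[q]][2], 2L * Wd, 2L), , drop = FALSE]
      dY4[rows, ] <- t(matrix(blk, N, Cout))
    }
    dY4
  }
  vjps <- list(
    function(g) {
      dX <- crossprod(Wv, gather_dY4(g))
      array(t(dX), dim = c(H, Wd, Cin))
    },
    function(g) tcrossprod(gather_dY4(g), Xmat)
  )
  if (!is.null(b)) {
    parents <- c(parents, list(b))
    vjps <- c(vjps, list(function(g) colSums(matrix(g, 4L * N, Cout))))
  }
  ag_node(out, parents, vjps)
}

# 2x2 max pooling, stride 2. Ties are routed to the first maximal position in
# the order top-left, bottom-left, top-right, bottom-right (deterministic).
ag_maxpool2 <- function(x) {
  xv <- x$value
  dm <- dim(xv)
  H <- dm[1]; W <- dm[2]; C <- dm[3]
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop(sprintf("max pooling requires even spatial dims, got %d x %d", H, W))
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  x11 <- xv[ro, co, , drop = FALSE]; x21 <- xv[re, co, , drop = FALSE]
  x12 <- xv[ro, ce, , drop = FALSE]; x22 <- xv[re, ce, , drop = FALSE]
  y <- pmax(x11, x21, x12, x22)
  m11 <- x11 == y
  m21 <- (x21 == y) & !m11
  m12 <- (x12 == y) & !m11 & !m21
  m22 <- (x22 == y) & !m11 & !m21 & !m12
  ag_node(y, list(x), list(function(g) {
    dx <- array(0, dm)
    dx[ro, co, ] <- g * m11
    dx[re, co, ] <- dx[re, co, ] + g * m21
    dx[ro, ce, ] <- dx[ro, ce, ] + g * m12
    dx[re, ce, ] <- dx[re, ce, ] + g * m22
    dx
  }))
}

# Interpolation weight matrix (Hout x Hin) for bilinear resizing with the
# half-pixel-centres convention (align_corners = FALSE).
bilinear_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5
    src <- min(max(src, 0), n_in - 1)
    i0 <- floor(src)
    w1 <- src - i0
    i0 <- as.integer(i0) + 1L
    i1 <- min(i0 + 1L, n_in)
    M[i, i0] <- M[i, i0] + (1 - w1)
    M[i, i1] <- M[i, i1] + w1
  }
  M
}

# Bilinear resize of a (H, W, C) tensor to (Hout, Wout); linear, so the
# adjoint is the transposed interpolation.
ag_bilinear <- function(x, Hout, Wout) {
  xv <- x$value
  dm <- dim(xv)
  H <- dm[1]; W <- dm[2]; C <- dm[3]
  if (H == Hout && W == Wout) return(x)
  Rw <- bilinear_matrix(H, Hout)
  Cw <- bilinear_matrix(W, Wout)
  fwd <- function(v, Rm, Cm, h_in, w_in, h_out, w_out, ch) {
    y1 <- Rm %*% matrix(v, h_in, w_in * ch)                 # rows
    y1 <- array(y1, dim = c(h_out, w_in, ch))
    y2 <- Cm %*% matrix(aperm(y1, c(2, 1, 3)), w_in, h_out * ch)  # cols
    aperm(array(y2, dim = c(w_out, h_out, ch)), c(2, 1, 3))
  }
  out <- fwd(xv, Rw, Cw, H, W, Hout, Wout, C)
  ag_node(out, list(x), list(function(g) {
    fwd(g, t(Rw), t(Cw), Hout, Wout, H, W, C)
  }))
}

# Plain-array versions for non-differentiable paths (targets, evaluation).
resize_bilinear <- function(m, Hout, Wout) {
  H <- nrow(m); W <- ncol(m)
  if (H == Hout && W == Wout) return(m)
  bilinear_matrix(H, Hout) %*% m %*% t(bilinear_matrix(W, Wout))
}

resize_nearest <- function(m, Hout, Wout) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(floor((seq_len(Hout) - 0.5) * H / Hout) + 1, 1), H)
  ci <- pmin(pmax(floor((seq_len(Wout) - 0.5) * W / Wout) + 1, 1), W)
  m[ri, ci, drop = FALSE]
}

# Batch normalization over the spatial extent of each channel (batch size is
# 1 throughout, so statistics are per-slice; biased variance, eps = 1e-5).
ag_batchnorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  dm <- dim(xv)
  N <- dm[1] * dm[2]; C <- dm[3]
  gv <- gamma$value
  fw <- batchnorm_fwd_cpp(xv, N, C, gv, beta$value, eps)
  out <- fw$y
  dim(out) <- dm
  bwd_cache <- NULL
  run_bwd <- function(g) {
    if (is.null(bwd_cache))
      bwd_cache <<- batchnorm_bwd_cpp(g, fw$xhat, fw$inv_sd, gv, N, C)
    bwd_cache
  }
  ag_node(out, list(x, gamma, beta), list(
    function(g) { dx <- run_bwd(g)$dx; dim(dx) <- dm; dx },
    function(g) run_bwd(g)$dgamma,
    function(g) run_bwd(g)$dbeta
  ))
}

# --- layer constructors -----------------------------------------------------

# Conv -> [BN] -> [ReLU]. `act` one of "relu", "none". BN carries the bias
# role, so a bias vector is only allocated when BN is off.
conv_block <- function(cin, cout, k, dil = 1L, bn = TRUE, act = "relu") {
  pad <- as.integer(dil * (k - 1L) / 2L)
  layer <- list(
    type = "conv", k = as.integer(k), pad = pad, dil = as.integer(dil),
    bn = bn, act = act,
    W = new_param(he_init(cout, cin * k * k))
  )
  if (bn) {
    layer$gamma <- new_param(rep(1, cout))
    layer$beta <- new_param(rep(0, cout))
  } else {
    layer$b <- new_param(rep(0, cout))
  }
  layer
}

conv_forward <- function(layer, x) {
  y <- ag_conv2d(x, layer$W, layer$b, layer$k, layer$pad, layer$dil)
  if (isTRUE(layer$bn)) y <- ag_batchnorm(y, layer$gamma, layer$beta)
  if (identical(layer$act, "relu")) y <- ag_relu(y)
  y
}

seq_forward <- function(layers, x) {
  for (l in layers) x <- conv_forward(l, x)
  x
}

deconv_block <- function(cin, cout) {
  list(type = "deconv",
       W = new_param(he_init(cout * 4L, cin) * 0.5),
       b = new_param(rep(0, cout)))
}

deconv_forward <- function(layer, x) ag_deconv2x2(x, layer$W, layer$b)

# Recursively harvest every parameter tensor from a nested list structure.
collect_params <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is_ag_tensor(x)) {
      if (x$requires_grad) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(module)
  out
}

n_params <- function(module) {
  sum(vapply(collect_params(module), function(p) length(p$value), numeric(1)))
}

# --- optimizer --------------------------------------------------------------

#' SGD optimizer with momentum and weight decay
#'
#' @param params List of parameter tensors (from `collect_params()`).
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 penalty coefficient added to the raw gradient.
#' @return An optimizer state object; step with [sgd_step()].
#' @keywords internal
sgd_new <- function(params, lr = 1e-5, momentum = 0.9, weight_decay = 1e-7) {
  # Re-own every parameter array: updates are in-place, so the optimizer
  # must hold the only reference (values assigned from literals or other
  # objects may be shared).
  for (p in params) p$value <- p$value + 0
  list(params = params,
       lr = lr, momentum = momentum, weight_decay = weight_decay,
       velocity = lapply(params, function(p) 0))
}

sgd_step <- function(opt) {
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    if (identical(opt$velocity[[i]], 0))
      opt$velocity[[i]] <- numeric(length(p$value))
    # In-place fused update: the engine holds no live aliases of parameter
    # or velocity arrays between steps.
    sgd_update_inplace_cpp(p$value, p$grad, opt$velocity[[i]],
                           opt$lr, opt$momentum, opt$weight_decay)
    p$grad <- NULL
  }
  opt
}

sgd_zero_grad <- function(opt) {
  for (p in opt$params) p$grad <- NULL
  invisible(opt)
}
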