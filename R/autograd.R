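#' @useDynLib pancseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# A minimal reverse-mode automatic differentiation engine.
#
# Tensors are environments holding a numeric array (`value`), an accumulated
# gradient (`grad`), and — for nodes produced by an operation — the parent
# tensors plus one vector-Jacobian-product closure per parent. Backward does a
# depth-first topological sort from the loss and pushes gradients to every
# parameter. The engine supports exactly the operations the segmentation
# pipeline needs; it is not a general framework.
#
# Feature maps are arrays with dim c(H, W, C); attention matrices are plain
# matrices; losses are length-1 arrays.
# ---------------------------------------------------------------------------

.ag_state <- new.env(parent = emptyenv())
.ag_state$next_id <- 1L

ag_next_id <- function() {
  id <- .ag_state$next_id
  .ag_state$next_id <- id + 1L
  id
}

#' Create a tensor
#'
#' Wraps a numeric array as a node of the autodiff graph. Tensors created with
#' `requires_grad = TRUE` are leaf parameters: the optimizer reads and zeroes
#' their `grad` field after each backward pass.
#'
#' @param value Numeric vector, matrix or array.
#' @param requires_grad Should gradients be accumulated into this tensor?
#' @return An object of class `ag_tensor`.
#' @keywords internal
ag_tensor <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  e$parents <- NULL
  e$vjps <- NULL
  e$id <- ag_next_id()
  class(e) <- "ag_tensor"
  e
}

is_ag_tensor <- function(x) inherits(x, "ag_tensor")

ag_const <- function(x) ag_tensor(x, requires_grad = FALSE)

ag_value <- function(x) if (is_ag_tensor(x)) x$value else x

# Internal node constructor. `parents` is a list of ag_tensors, `vjps` a list
# of functions mapping the incoming gradient to each parent's gradient
# contribution. If no parent requires grad the graph edge is dropped entirely.
ag_node <- function(value, parents, vjps) {
  need <- vapply(parents, function(p) isTRUE(p$requires_grad), logical(1))
  out <- ag_tensor(value, requires_grad = any(need))
  if (any(need)) {
    out$parents <- parents
    out$vjps <- vjps
  }
  out
}

# Topologically ordered backward pass from a scalar loss.
ag_backward <- function(root, grad = 1) {
  stopifnot(is_ag_tensor(root))
  if (length(root$value) != 1L)
    stop("ag_backward: root must be a scalar")
  order <- vector("list", 64L)
  n_ord <- 0L
  visited <- new.env(parent = emptyenv())
  # Iterative post-order DFS (graphs can be a few thousand nodes deep).
  stack <- list(list(node = root, idx = 0L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    node <- top$node
    key <- as.character(node$id)
    kids <- node$parents
    nk <- if (is.null(kids)) 0L else length(kids)
    if (top$idx < nk) {
      stack[[length(stack)]]$idx <- top$idx + 1L
      child <- kids[[top$idx + 1L]]
      if (child$requires_grad && is.null(visited[[as.character(child$id)]]) &&
          !is.null(child$parents)) {
        visited[[as.character(child$id)]] <- TRUE
        stack[[length(stack) + 1L]] <- list(node = child, idx = 0L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  root$grad <- grad
  # Reverse topological order: every node is processed after all consumers.
  for (k in seq(n_ord, 1L)) {
    node <- order[[k]]
    g <- node$grad
    if (is.null(g)) next
    parents <- node$parents
    if (is.null(parents)) next
    for (j in seq_along(parents)) {
      p <- parents[[j]]
      if (!p$requires_grad) next
      contrib <- node$vjps[[j]](g)
      p$grad <- if (is.null(p$grad)) contrib else p$grad + contrib
    }
    # Free intermediate state so long training loops don't accumulate memory.
    node$grad <- NULL
    node$vjps <- NULL
    node$parents <- NULL
  }
  invisible(root)
}

# --- elementwise arithmetic -------------------------------------------------

# Binary ops accept a tensor plus either a tensor of identical shape or a
# plain numeric (broadcast by R recycling against a scalar only).

ag_add <- function(a, b) {
  if (!is_ag_tensor(b)) return(ag_node(a$value + b, list(a), list(function(g) g)))
  if (!is_ag_tensor(a)) return(ag_node(a + b$value, list(b), list(function(g) g)))
  ag_node(a$value + b$value, list(a, b), list(function(g) g, function(g) g))
}

ag_sub <- function(a, b) {
  if (!is_ag_tensor(b)) return(ag_node(a$value - b, list(a), list(function(g) g)))
  if (!is_ag_tensor(a)) return(ag_node(a - b$value, list(b), list(function(g) -g)))
  ag_node(a$value - b$value, list(a, b), list(function(g) g, function(g) -g))
}

ag_mul <- function(a, b) {
  if (!is_ag_tensor(b)) return(ag_node(a$value * b, list(a), list(function(g) g * b)))
  if (!is_ag_tensor(a)) return(ag_node(a * b$value, list(b), list(function(g) g * a)))
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), list(function(g) g * bv, function(g) g * av))
}

ag_div <- function(a, b) {
  if (!is_ag_tensor(b)) return(ag_mul(a, 1 / b))
  av <- ag_value(a); bv <- b$value
  if (!is_ag_tensor(a)) {
    return(ag_node(av / bv, list(b), list(function(g) -g * av / (bv * bv))))
  }
  ag_node(av / bv, list(a, b),
          list(function(g) g / bv, function(g) -g * av / (bv * bv)))
}

ag_neg <- function(a) ag_node(-a$value, list(a), list(function(g) -g))

ag_relu <- function(a) {
  m <- a$value > 0
  ag_node(a$value * m, list(a), list(function(g) g * m))
}

ag_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  ag_node(y, list(a), list(function(g) g * y * (1 - y)))
}

ag_log <- function(a) {
  av <- a$value
  ag_node(log(av), list(a), list(function(g) g / av))
}

# Gradient is passed only strictly inside the interval (framework convention).
ag_clamp <- function(a, lo, hi) {
  av <- a$value
  m <- av > lo & av < hi
  ag_node(pmin(pmax(av, lo), hi), list(a), list(function(g) g * m))
}

ag_sum <- function(a) {
  dm <- dim(a$value); n <- length(a$value)
  ag_node(sum(a$value), list(a), list(function(g) {
    out <- rep(as.numeric(g), n)
    if (!is.null(dm)) dim(out) <- dm
    out
  }))
}

ag_mean <- function(a) ag_div(ag_sum(a), length(a$value))

# Multiply a (H, W, C) tensor by a scalar tensor (learnable scale).
ag_scale <- function(x, s) {
  stopifnot(length(s$value) == 1L)
  xv <- x$value; sv <- as.numeric(s$value)
  ag_node(xv * sv, list(x, s),
          list(function(g) g * sv, function(g) sum(g * xv)))
}

# Multiply a (H, W, C) tensor by a single-channel (H, W) map, broadcast over
# channels. `m` may be a tensor or a plain matrix.
ag_mul_map <- function(x, m) {
  xv <- x$value
  H <- dim(xv)[1]; W <- dim(xv)[2]; C <- dim(xv)[3]
  if (!is_ag_tensor(m)) {
    mv <- as.numeric(m)
    return(ag_node(xv * mv, list(x), list(function(g) g * mv)))
  }
  mv <- as.numeric(m$value)
  ag_node(xv * mv, list(x, m), list(
    function(g) g * mv,
    function(g) {
      dm <- rowSums(matrix(g * xv, H * W, C))
      dim(dm) <- dim(m$value)
      dm
    }
  ))
}

# --- structural ops ---------------------------------------------------------

# Concatenate along the channel (third) dimension.
ag_concat <- function(tensors) {
  vals <- lapply(tensors, ag_value)
  dims <- lapply(vals, dim)
  H <- dims[[1]][1]; W <- dims[[1]][2]
  cs <- vapply(dims, function(d) d[3], numeric(1))
  out <- array(unlist(vals, use.names = FALSE), dim = c(H, W, sum(cs)))
  offs <- cumsum(c(0, cs))
  vjps <- lapply(seq_along(tensors), function(i) {
    i0 <- offs[i]; ci <- cs[i]
    function(g) g[, , (i0 + 1):(i0 + ci), drop = FALSE]
  })
  ag_node(out, tensors, vjps)
}

# Crop rows/cols of a (H, W, C) tensor or (H, W) matrix tensor.
ag_crop <- function(x, rows, cols) {
  xv <- x$value
  dm <- dim(xv)
  if (length(dm) == 3L) {
    out <- xv[rows, cols, , drop = FALSE]
    ag_node(out, list(x), list(function(g) {
      dx <- array(0, dm)
      dx[rows, cols, ] <- g
      dx
    }))
  } else {
    out <- xv[rows, cols, drop = FALSE]
    ag_node(out, list(x), list(function(g) {
      dx <- array(0, dm)
      dx[rows, cols] <- g
      dx
    }))
  }
}

# (H, W, C) array <-> C x N matrix (N = H*W, positions column-major).
ag_to_cn <- function(x) {
  dm <- dim(x$value)
  H <- dm[1]; W <- dm[2]; C <- dm[3]
  out <- t(matrix(x$value, H * W, C))
  ag_node(out, list(x), list(function(g) array(t(g), dim = c(H, W, C))))
}

ag_from_cn <- function(m, H, W) {
  C <- nrow(m$value)
  out <- array(t(m$value), dim = c(H, W, C))
  ag_node(out, list(m), list(function(g) t(matrix(g, H * W, C))))
}

ag_matmul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  out <- av %*% bv
  if (is_ag_tensor(a) && is_ag_tensor(b)) {
    ag_node(out, list(a, b), list(
      function(g) g %*% t(bv),
      function(g) t(av) %*% g
    ))
  } else if (is_ag_tensor(a)) {
    ag_node(out, list(a), list(function(g) g %*% t(bv)))
  } else {
    ag_node(out, list(b), list(function(g) t(av) %*% g))
  }
}

ag_transpose <- function(a) ag_node(t(a$value), list(a), list(function(g) t(g)))

# Drop a trailing singleton channel: (H, W, 1) -> (H, W) matrix tensor.
ag_squeeze <- function(x) {
  dm <- dim(x$value)
  stopifnot(length(dm) == 3L, dm[3] == 1L)
  ag_node(matrix(x$value, dm[1], dm[2]), list(x),
          list(function(g) array(g, dim = dm)))
}

# Numerically stabilized row-wise softmax.
ag_softmax_rows <- function(a) {
  av <- a$value
  z <- av - apply(av, 1, max)
  e <- exp(z)
  y <- e / rowSums(e)
  ag_node(y, list(a), list(function(g) y * (g - rowSums(g * y))))
}
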