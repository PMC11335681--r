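# ---------------------------------------------------------------------------
# Training objectives.
#
# Stage 1 trains with soft Dice loss. Stage 2 is deeply supervised: the
# localization output takes BCE + IoU, the four focusing outputs take
# boundary-weighted BCE + IoU, combined with level weights 2^(4-i). An
# auxiliary inter-class shared-boundary (ISB) term penalizes, via MSE between
# shared-boundary matrices, predictions whose class-boundary structure
# deviates from the ground truth — a signal that stays large for small
# objects whose pixel-count contribution to the other losses is negligible.
#
# Every loss accepts either plain numeric arrays (returns a numeric scalar)
# or autodiff tensors (returns a scalar tensor that supports backward).
# ---------------------------------------------------------------------------

LOSS_EPS <- 1e-6
PROB_EPS <- 1e-7

as_loss_pair <- function(pred, gt) {
  tensor_in <- is_ag_tensor(pred) || is_ag_tensor(gt)
  p <- if (is_ag_tensor(pred)) pred else ag_const(pred)
  g <- ag_value(gt)
  if (!all((dim(ag_value(p)) %||% length(ag_value(p))) ==
           (dim(g) %||% length(g))))
    stop("prediction and ground truth shapes differ: ",
         paste(dim(ag_value(p)), collapse = "x"), " vs ",
         paste(dim(g), collapse = "x"))
  list(p = p, g = g, tensor_in = tensor_in)
}

finish_loss <- function(loss, tensor_in) {
  if (tensor_in) loss else as.numeric(ag_value(loss))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)` with `eps = 1e-6`.
#' On hard masks this equals one minus the Dice overlap coefficient.
#'
#' @param pred Predicted foreground probabilities in [0,1] (array or tensor).
#' @param gt Binary ground-truth mask of the same shape.
#' @return Scalar numeric, or scalar tensor if `pred` is a tensor.
#' @export
dice_loss <- function(pred, gt) {
  io <- as_loss_pair(pred, gt)
  inter <- ag_sum(ag_mul(io$p, io$g))
  denom <- ag_add(ag_sum(io$p), sum(io$g))
  loss <- ag_sub(1, ag_div(ag_add(ag_mul(inter, 2), LOSS_EPS),
                           ag_add(denom, LOSS_EPS)))
  finish_loss(loss, io$tensor_in)
}

bce_term <- function(p, g, w = NULL) {
  pc <- ag_clamp(p, PROB_EPS, 1 - PROB_EPS)
  ce <- ag_neg(ag_add(ag_mul(ag_log(pc), g),
                      ag_mul(ag_log(ag_sub(1, pc)), 1 - g)))
  if (is.null(w)) return(ag_mean(ce))
  ag_div(ag_sum(ag_mul(ce, w)), sum(w))
}

iou_term <- function(p, g, w = NULL) {
  if (is.null(w)) {
    inter <- ag_sum(ag_mul(p, g))
    union <- ag_sub(ag_add(ag_sum(p), sum(g)), inter)
  } else {
    inter <- ag_sum(ag_mul(ag_mul(p, g), w))
    pg <- ag_sub(ag_add(p, g), ag_mul(p, g))
    union <- ag_sum(ag_mul(pg, w))
  }
  ag_sub(1, ag_div(ag_add(inter, LOSS_EPS), ag_add(union, LOSS_EPS)))
}

#' Localization loss: BCE + IoU
#'
#' Supervises the coarse localization prediction with the sum of binary
#' cross-entropy and IoU loss (`1 - intersection/union`, smoothed).
#'
#' @inheritParams dice_loss
#' @export
localization_loss <- function(pred, gt) {
  io <- as_loss_pair(pred, gt)
  loss <- ag_add(bce_term(io$p, io$g), iou_term(io$p, io$g))
  finish_loss(loss, io$tensor_in)
}

#' Boundary-emphasis weight map for the focusing loss
#'
#' `w = 1 + mu * |boxmean_k(gt) - gt|`: pixels whose k x k neighbourhood mean
#' disagrees with their own label — boundaries and cavities — get up-weighted.
#'
#' @param gt Binary mask (matrix).
#' @param mu Emphasis strength (default 5).
#' @param k Box filter size in pixels (default 15).
#' @return Weight matrix of the same size.
#' @export
boundary_weight_map <- function(gt, mu = 5, k = 15L) {
  gt <- as.matrix(ag_value(gt))
  1 + mu * abs(box_mean_cpp(gt, as.integer(k)) - gt)
}

#' Focusing loss: boundary-weighted BCE + IoU
#'
#' The weighted BCE normalizes by the total weight; the weighted IoU weights
#' both intersection and union pixelwise.
#'
#' @inheritParams dice_loss
#' @param mu,k Passed to [boundary_weight_map()].
#' @export
focusing_loss <- function(pred, gt, mu = 5, k = 15L) {
  io <- as_loss_pair(pred, gt)
  w <- boundary_weight_map(io$g, mu = mu, k = k)
  loss <- ag_add(bce_term(io$p, io$g, w), iou_term(io$p, io$g, w))
  finish_loss(loss, io$tensor_in)
}

#' Deep-supervision weights for the focusing levels
#'
#' Level i in 2..5 carries weight `2^(4-i)` (4, 2, 1, 0.5): coarse levels
#' are weighted higher, following deep-supervision convention.
#' @param levels Integer vector of levels (default 2:5).
#' @export
stage2_level_weights <- function(levels = 2:5) 2^(4 - levels)

#' Total stage-2 loss
#'
#' `L_pm + sum_i w_i * L_fm^i` over the four focusing predictions ordered
#' coarse to fine (levels i = 2..5).
#'
#' @param loc_pred Localization probability map.
#' @param focus_preds List of exactly 4 focusing probability maps, coarse
#'   first.
#' @param gt Binary ground-truth mask (same shape as each prediction).
#' @param mu,k Focusing-loss weight-map parameters.
#' @param weights Level weights (default [stage2_level_weights()]).
#' @export
stage2_total <- function(loc_pred, focus_preds, gt, mu = 5, k = 15L,
                         weights = stage2_level_weights()) {
  if (length(focus_preds) != 4L)
    stop("expected 4 focusing predictions, got ", length(focus_preds))
  tensor_in <- is_ag_tensor(loc_pred) ||
    any(vapply(focus_preds, is_ag_tensor, logical(1)))
  total <- localization_loss(loc_pred, gt)
  if (!is_ag_tensor(total)) total <- ag_const(total)
  for (i in seq_along(focus_preds)) {
    li <- focusing_loss(focus_preds[[i]], gt, mu = mu, k = k)
    if (!is_ag_tensor(li)) li <- ag_const(li)
    total <- ag_add(total, ag_mul(li, weights[i]))
  }
  finish_loss(total, tensor_in)
}

#' Convert per-class probability maps to hard labels
#'
#' Per-pixel argmax with ties broken to the lowest class index. Labels are
#' 1-based.
#'
#' @param pred_probs H x W x n_c array of class scores.
#' @return H x W integer matrix of labels in 1..n_c.
#' @export
hard_labels <- function(pred_probs) {
  pred_probs <- ag_value(pred_probs)
  dm <- dim(pred_probs)
  if (length(dm) != 3L || dm[3] < 2L)
    stop("pred_probs must be H x W x n_c with n_c >= 2")
  m <- matrix(pred_probs, dm[1] * dm[2], dm[3])
  lab <- max.col(m, ties.method = "first")
  matrix(as.integer(lab), dm[1], dm[2])
}

#' Binary foreground probabilities to a two-class label map
#'
#' Class 2 (foreground) iff p > 0.5, else class 1.
#' @param p Foreground probability matrix.
#' @export
binary_labels <- function(p) {
  p <- ag_value(p)
  matrix(1L + as.integer(p > 0.5), nrow(p), ncol(p))
}

#' Inter-class shared-boundary matrix
#'
#' Entry (i, j) is the length of the boundary shared between classes i and j
#' divided by the perimeter of class i. Boundaries are counted as 4-adjacent
#' pixel-pair edges; the image border counts toward a class's perimeter
#' (`l_i`) but toward no shared boundary, so rows sum to at most 1. The
#' diagonal is zero by definition, and the matrix is generally asymmetric
#' because different classes have different perimeters.
#'
#' @param label_map H x W integer matrix with labels in 1..n_c.
#' @param n_c Number of classes.
#' @return n_c x n_c numeric matrix with entries in [0,1].
#' @export
isb_matrix <- function(label_map, n_c) {
  lab <- as.matrix(label_map)
  if (any(lab < 1L | lab > n_c))
    stop("labels must lie in 1..", n_c)
  H <- nrow(lab); W <- ncol(lab)
  shared <- matrix(0, n_c, n_c)
  # Interior 4-adjacency edges with differing labels.
  if (W > 1L) {
    a <- lab[, -W]; b <- lab[, -1]
    d <- a != b
    if (any(d)) {
      ij <- cbind(a[d], b[d])
      for (r in seq_len(nrow(ij))) {
        shared[ij[r, 1], ij[r, 2]] <- shared[ij[r, 1], ij[r, 2]] + 1
        shared[ij[r, 2], ij[r, 1]] <- shared[ij[r, 2], ij[r, 1]] + 1
      }
    }
  }
  if (H > 1L) {
    a <- lab[-H, ]; b <- lab[-1, ]
    d <- a != b
    if (any(d)) {
      ij <- cbind(a[d], b[d])
      for (r in seq_len(nrow(ij))) {
        shared[ij[r, 1], ij[r, 2]] <- shared[ij[r, 1], ij[r, 2]] + 1
        shared[ij[r, 2], ij[r, 1]] <- shared[ij[r, 2], ij[r, 1]] + 1
      }
    }
  }
  # Image-border edges: every border pixel contributes one edge per touching
  # side (corners contribute two).
  border <- numeric(n_c)
  for (cls in seq_len(n_c)) {
    border[cls] <- sum(lab[1, ] == cls) + sum(lab[H, ] == cls) +
      sum(lab[, 1] == cls) + sum(lab[, W] == cls)
  }
  perim <- rowSums(shared) + border
  m <- matrix(0, n_c, n_c)
  nz <- perim > 0
  m[nz, ] <- shared[nz, , drop = FALSE] / perim[nz]
  diag(m) <- 0
  m
}

#' Inter-class shared-boundary loss
#'
#' Mean squared difference between the shared-boundary matrices of the
#' hardened prediction and the ground truth:
#' `(1/n_c^2) * sum_ij (m_pred(i,j) - m_gt(i,j))^2`. The hardening step
#' (argmax) is non-differentiable, so this term is evaluated on hard labels
#' and contributes no gradient; it is reported (and optionally added to the
#' total) as a penalty.
#'
#' @param pred_probs H x W x n_c class-score array, or an H x W foreground
#'   probability matrix (treated as the two-class case).
#' @param gt_labels H x W integer ground-truth label map in 1..n_c.
#' @param n_c Number of classes.
#' @return Scalar in [0,1].
#' @export
isb_loss <- function(pred_probs, gt_labels, n_c = 2L) {
  pred_probs <- ag_value(pred_probs)
  lab_pred <- if (length(dim(pred_probs)) == 3L) hard_labels(pred_probs)
              else binary_labels(pred_probs)
  m_pred <- isb_matrix(lab_pred, n_c)
  m_gt <- isb_matrix(gt_labels, n_c)
  mean((m_pred - m_gt)^2)
}

#' Total training loss
#'
#' `L = L_seg1 + alpha * L_seg2 + beta * L_isb` with defaults alpha = 0.9,
#' beta = 0.4.
#'
#' @param l_seg1,l_seg2,l_isb Component losses (numeric or tensors).
#' @param alpha,beta Mixing weights.
#' @export
total_loss <- function(l_seg1, l_seg2, l_isb, alpha = 0.9, beta = 0.4) {
  tensor_in <- is_ag_tensor(l_seg1) || is_ag_tensor(l_seg2) ||
    is_ag_tensor(l_isb)
  t1 <- if (is_ag_tensor(l_seg1)) l_seg1 else ag_const(l_seg1)
  t2 <- if (is_ag_tensor(l_seg2)) l_seg2 else ag_const(l_seg2)
  t3 <- if (is_ag_tensor(l_isb)) l_isb else ag_const(l_isb)
  loss <- ag_add(ag_add(t1, ag_mul(t2, alpha)), ag_mul(t3, beta))
  finish_loss(loss, tensor_in)
}
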