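# ---------------------------------------------------------------------------
# broom-style accessors and ggplot2 visualization for fitted cascades and
# evaluation reports.
# ---------------------------------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-epoch training log of a fitted cascade
#'
#' @param x A `pancseg_fit` from [run_schedule()].
#' @param ... Unused.
#' @return Tibble with one row per epoch: step, epoch, the loss components
#'   and the reported total.
#' @method tidy pancseg_fit
#' @export
tidy.pancseg_fit <- function(x, ...) x$log

#' One-row summary of a fitted cascade
#'
#' @param x A `pancseg_fit`.
#' @param ... Unused.
#' @return Tibble with the final-epoch losses, total epoch count and the
#'   key hyperparameters.
#' @method glance pancseg_fit
#' @export
glance.pancseg_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(epochs = nrow(x$log),
                 loss_seg1 = last$loss_seg1,
                 loss_seg2 = last$loss_seg2,
                 loss_isb = last$loss_isb,
                 total = last$total,
                 lr = x$hyper$lr,
                 alpha = x$hyper$alpha,
                 beta = x$hyper$beta)
}

#' Training-curve plot
#'
#' Loss components per epoch, faceted by component, with the schedule steps
#' (S, I, J) distinguished by colour.
#'
#' @param object A `pancseg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pancseg_fit
#' @export
autoplot.pancseg_fit <- function(object, ...) {
  log <- object$log
  log$global_epoch <- seq_len(nrow(log))
  long <- tibble::tibble(
    global_epoch = rep(log$global_epoch, 4L),
    step = rep(log$step, 4L),
    component = rep(c("seg1 (Dice)", "seg2 (deep supervision)",
                      "isb", "total"), each = nrow(log)),
    loss = c(log$loss_seg1, log$loss_seg2, log$loss_isb, log$total))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$global_epoch, y = .data$loss,
                                     colour = .data$step)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ component, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "loss", colour = "schedule step") +
    ggplot2::theme_minimal()
}

#' Per-case metric plot for an evaluation report
#'
#' @param object A `pancseg_report` from [evaluate_dataset()].
#' @param ... Unused.
#' @return A ggplot object showing Dice per case with the overall slice
#'   mean as a reference line.
#' @method autoplot pancseg_report
#' @export
autoplot.pancseg_report <- function(object, ...) {
  cases <- object[object$level == "case", ]
  overall <- object[object$level == "overall_slice_mean", ]
  ggplot2::ggplot(cases, ggplot2::aes(x = .data$case_id, y = .data$dice)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = overall$dice, linetype = "dashed") +
    ggplot2::labs(x = "case", y = "Dice",
                  title = "Per-case Dice (dashed: overall slice mean)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
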