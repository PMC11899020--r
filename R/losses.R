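# Hybrid segmentation loss: Dice, Tversky and their sum.
#
# Sums run over all pixels supplied (batch-level aggregation): with lesions
# occupying a few percent of the frame, per-image ratios are noisy while the
# pooled ratio is stable.

check_loss_inputs <- function(y, yhat) {
  if (length(y) != length(yhat) ||
      (!is.null(dim(y)) && !is.null(dim(yhat)) &&
       !identical(dim(y), dim(yhat))))
    stop("y and yhat must have the same shape")
  if (any(y != 0 & y != 1)) stop("y must be binary (0/1)")
  if (min(yhat) < -1e-9 || max(yhat) > 1 + 1e-9)
    stop("yhat values must lie in [0, 1]")
  invisible(TRUE)
}

#' Dice loss
#'
#' \code{1 - (2 * sum(y * yhat) + eps) / (sum(y) + sum(yhat) + eps)}:
#' one minus the (smoothed) Dice coefficient between a binary reference and
#' a soft prediction. Zero for a perfect prediction; approaches one for
#' disjoint masks.
#'
#' @param y binary reference values in \{0, 1\}.
#' @param yhat predicted probabilities in [0, 1], same shape as \code{y}.
#' @param epsilon smoothing constant avoiding division by zero.
#' @return scalar loss in [0, 1].
#' @export
#' @examples
#' diceLoss(c(1, 1, 0, 0), c(1, 0, 1, 0))  # ~0.5
diceLoss <- function(y, yhat, epsilon = 1e-6) {
  check_loss_inputs(y, yhat)
  1 - (2 * sum(y * yhat) + epsilon) / (sum(y) + sum(yhat) + epsilon)
}

#' Tversky loss
#'
#' Generalizes Dice with asymmetric penalties: false negatives weighted by
#' \code{alpha}, false positives by \code{beta}. At alpha = beta = 0.5 the
#' loss coincides with \code{\link{diceLoss}} on binary predictions.
#'
#' @param y binary reference.
#' @param yhat predicted probabilities, same shape.
#' @param config a \linkS4class{LossConfig}; or pass \code{alpha},
#'   \code{beta}, \code{epsilon} directly.
#' @param alpha,beta,epsilon used when \code{config} is missing.
#' @return scalar loss in [0, 1].
#' @export
tverskyLoss <- function(y, yhat, config = NULL, alpha = 0.7, beta = 0.3,
                        epsilon = 1e-6) {
  if (!is.null(config)) {
    alpha <- config@alpha; beta <- config@beta; epsilon <- config@epsilon
  }
  check_loss_inputs(y, yhat)
  tp <- sum(y * yhat)
  fn <- sum(y * (1 - yhat))
  fp <- sum((1 - y) * yhat)
  1 - (tp + epsilon) / (tp + alpha * fn + beta * fp + epsilon)
}

#' Combined Dice + Tversky loss
#'
#' The exact sum of \code{\link{diceLoss}} and \code{\link{tverskyLoss}}
#' with a shared smoothing constant: the Dice term maintains region-overlap
#' accuracy while the Tversky term shifts the error balance toward
#' penalizing missed lesion pixels.
#'
#' @inheritParams tverskyLoss
#' @return scalar loss in [0, 2].
#' @export
combinedLoss <- function(y, yhat, config = lossConfig()) {
  out <- diceLoss(y, yhat, epsilon = config@epsilon) +
    tverskyLoss(y, yhat, config = config)
  if (config@includeBCE) {
    p <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
    out <- out - mean(y * log(p) + (1 - y) * log(1 - p))
  }
  out
}
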