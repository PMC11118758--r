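#' Focal loss
#'
#' Cross-entropy scaled by `(1 - p_c)^gamma`, which down-weights easy,
#' well-classified examples so that training is not dominated by the
#' abundant non-RiPP class: `FL = -(1 - p_c)^gamma * log(p_c)` where
#' `p_c` is the predicted probability of the true class. `gamma = 0`
#' recovers the standard cross-entropy exactly. For a batch the losses
#' are reduced by their arithmetic mean.
#'
#' @param probs Numeric vector of class probabilities, or a matrix with
#'   one row per example.
#' @param true_class Class label(s) (see [ripp_classes()]) or integer
#'   index/indices.
#' @param gamma Focusing parameter, `>= 0`. Default 1, the value used for
#'   classifier training.
#' @param eps Probabilities are clamped below at `eps` (default 1e-12)
#'   so the loss is never infinite or NaN.
#' @param reduce One of `"mean"` (default) or `"none"`.
#' @return Non-negative scalar (or vector when `reduce = "none"`).
#' @export
#' @examples
#' focal_loss(c(0.5, 0.5), 1, gamma = 1) # 0.5 * log(2)
focal_loss <- function(probs, true_class, gamma = 1, eps = 1e-12,
                       reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  stopifnot(gamma >= 0)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  idx <- as_class_index(true_class, n_classes = ncol(probs))
  if (length(idx) != nrow(probs)) {
    stop("length of true_class must match the number of probability rows",
      call. = FALSE
    )
  }
  p_c <- probs[cbind(seq_len(nrow(probs)), idx)]
  p_c <- pmax(p_c, eps)
  loss <- -(1 - p_c)^gamma * log(p_c)
  if (reduce == "mean") mean(loss) else loss
}

#' RiPP score
#'
#' The score used for the ROC curve of the binary RiPP vs non-RiPP view:
#' one minus the predicted probability of the non-RiPP class.
#'
#' @param probs Probability vector, or matrix with one row per example
#'   and the non-RiPP class last (the frozen enumeration order).
#' @return Scalar (or vector) in `[0, 1]`.
#' @export
ripp_score <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  unname(1 - probs[, ncol(probs)])
}
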