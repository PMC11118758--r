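#' ROC points by the trapezoidal construction
#'
#' Sweeps every distinct score threshold (ties grouped) and reports the
#' true- and false-positive rates of the rule `score >= threshold`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) truth vector.
#' @return Tibble with `threshold`, `tpr`, `fpr`, starting at (0, 0).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels)
  N <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE) # last index of each tie group
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    tpr = c(0, tp[keep] / max(P, 1L)),
    fpr = c(0, fp[keep] / max(N, 1L))
  )
}

# area under the ROC curve by the trapezoidal rule over all thresholds
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (sum(labels) == 0L || sum(!labels) == 0L) {
    return(NA_real_)
  }
  rp <- roc_points(scores, labels)
  sum(diff(rp$fpr) * (utils::head(rp$tpr, -1) + utils::tail(rp$tpr, -1)) / 2)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Evaluate classifier predictions
#'
#' Computes the full metric suite from true class labels and predicted
#' class probabilities. The binary view collapses the nine RiPP classes
#' into a single positive "RiPP" label (non-RiPP is the negative class)
#' and reports accuracy, precision, recall, F1, the Matthews correlation
#' coefficient, and AUROC of the RiPP score (1 - P(non-RiPP)), all from
#' the TP/TN/FP/FN counts. The multiclass view reports accuracy, weighted
#' F1 (per-class F1 weighted by *predicted*-class counts N_c/N; set
#' `weights = "true"` for the conventional true-count weighting) and
#' Cohen's kappa with chance agreement p_e = (1/N^2) sum_c n_c1 n_c2.
#' Ratios with a zero denominator are reported as 0 and the metric name
#' is recorded in the `flags` field rather than propagating NaN.
#'
#' @param truth Class labels (see [ripp_classes()]) or integer indices.
#' @param probs Probability matrix, one row per record, non-RiPP last.
#' @param weights Weighting for the multiclass weighted F1:
#'   `"predicted"` (default, as printed) or `"true"` (conventional).
#' @return A `ripp_metrics` object: list with `binary`, `multiclass`
#'   (one-row tibbles), `confusion` (truth x prediction counts), `roc`
#'   (tibble of ROC points), `flags`, `n`.
#' @export
evaluate_predictions <- function(truth, probs,
                                 weights = c("predicted", "true")) {
  weights <- match.arg(weights)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  n_classes <- ncol(probs)
  y <- as_class_index(truth, n_classes)
  if (length(y) != nrow(probs)) {
    stop("truth and probs must have the same number of records",
      call. = FALSE
    )
  }
  n <- length(y)
  pred <- max.col(probs, ties.method = "first")
  flags <- character(0)

  conf <- matrix(0L, n_classes, n_classes,
    dimnames = list(
      truth = ripp_classes()[seq_len(n_classes)],
      prediction = ripp_classes()[seq_len(n_classes)]
    )
  )
  tab <- table(factor(y, levels = seq_len(n_classes)),
    factor(pred, levels = seq_len(n_classes))
  )
  conf[] <- as.integer(tab)

  # binary collapse: positive = any RiPP class, negative = non-RiPP (last)
  pos_t <- y != n_classes
  pos_p <- pred != n_classes
  tp <- sum(pos_t & pos_p)
  tn <- sum(!pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p)
  fn <- sum(pos_t & !pos_p)

  sentinel <- function(x, name) {
    if (is.na(x)) {
      flags <<- c(flags, name)
      0
    } else {
      x
    }
  }
  precision <- sentinel(safe_div(tp, tp + fp), "precision")
  recall <- sentinel(safe_div(tp, tp + fn), "recall")
  f1 <- sentinel(safe_div(2 * tp, 2 * tp + fp + fn), "f1")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- sentinel(
    if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
    "mcc"
  )
  scores <- ripp_score(probs)
  au <- sentinel(auroc(scores, pos_t), "auroc")

  binary <- tibble::tibble(
    accuracy = (tp + tn) / n,
    precision = precision, recall = recall, f1 = f1, mcc = mcc, auroc = au
  )

  # multiclass view
  acc_mc <- mean(pred == y)
  tp_c <- diag(conf)
  fp_c <- colSums(conf) - tp_c
  fn_c <- rowSums(conf) - tp_c
  f1_c <- ifelse(2 * tp_c + fp_c + fn_c == 0, 0,
    2 * tp_c / (2 * tp_c + fp_c + fn_c)
  )
  w_c <- if (weights == "predicted") colSums(conf) / n else rowSums(conf) / n
  weighted_f1 <- sum(f1_c * w_c)
  p_e <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- sentinel(
    if (abs(1 - p_e) < .Machine$double.eps) NA_real_ else (acc_mc - p_e) / (1 - p_e),
    "cohens_kappa"
  )
  multiclass <- tibble::tibble(
    accuracy = acc_mc, weighted_f1 = weighted_f1, cohens_kappa = kappa
  )

  structure(
    list(
      binary = binary, multiclass = multiclass, confusion = conf,
      roc = roc_points(scores, pos_t), flags = flags, n = n
    ),
    class = "ripp_metrics"
  )
}

#' @export
print.ripp_metrics <- function(x, ...) {
  cat("<ripp_metrics> on", x$n, "records\n binary: ")
  cat(paste(names(x$binary), round(unlist(x$binary), 3),
    sep = "=", collapse = " "
  ), "\n multiclass: ")
  cat(paste(names(x$multiclass), round(unlist(x$multiclass), 3),
    sep = "=", collapse = " "
  ), "\n")
  if (length(x$flags)) {
    cat(
      " zero-denominator sentinels:",
      paste(x$flags, collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' @describeIn evaluate_predictions Long tibble of all metrics.
#' @param x,... A `ripp_metrics` object (tidy method).
#' @export
tidy.ripp_metrics <- function(x, ...) {
  dplyr::bind_rows(
    tidyr::pivot_longer(x$binary, dplyr::everything(),
      names_to = "metric", values_to = "value"
    ) |> dplyr::mutate(view = "binary", .before = 1),
    tidyr::pivot_longer(x$multiclass, dplyr::everything(),
      names_to = "metric", values_to = "value"
    ) |> dplyr::mutate(view = "multiclass", .before = 1)
  )
}

#' @describeIn evaluate_predictions One-row tibble of all metrics.
#' @export
glance.ripp_metrics <- function(x, ...) {
  dplyr::bind_cols(
    x$binary,
    dplyr::rename_with(x$multiclass, ~ paste0("mc_", .x))
  )
}

#' Plot the ROC curve of an evaluation
#' @param object A `ripp_metrics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ripp_metrics <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey") +
    ggplot2::labs(
      x = "false-positive rate", y = "true-positive rate",
      subtitle = sprintf("AUROC = %.3f", object$binary$auroc)
    ) +
    ggplot2::theme_minimal()
}
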