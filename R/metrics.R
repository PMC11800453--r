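#' Confusion-matrix metrics for a two-class prediction
#'
#' Computes the five performance measures used throughout the pipeline, with
#' conduct disorder (`"CD"`) as the positive class by convention:
#' * `tpr` (sensitivity) = TP / (TP + FN)
#' * `tnr` (specificity) = TN / (TN + FP)
#' * `ppv` = TP / (TP + FP)
#' * `npv` = TN / (TN + FN)
#' * `wacc` = (tpr + tnr) / 2, the macro-averaged weighted accuracy: the
#'   mean of the two per-class accuracies, robust to class imbalance.
#'
#' A metric whose denominator is zero (e.g. PPV when nothing was predicted
#' positive) is returned as `NA`, never coerced to 0; downstream summaries
#' exclude and count such entries.
#'
#' @param truth,predicted Character vectors of equal length with the true
#'   and predicted class labels.
#' @param positive_class Label of the positive class (default `"CD"`).
#' @return A one-row tibble with columns `wacc`, `ppv`, `npv`, `tpr`, `tnr`.
#' @examples
#' compute_metrics(c("CD", "CD", "CD", "control", "control"),
#'                 c("CD", "control", "CD", "control", "control"))
#' @export
compute_metrics <- function(truth, predicted, positive_class = "CD") {
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  labs <- unique(c(truth, predicted))
  neg <- setdiff(labs, positive_class)
  if (length(neg) > 1) {
    stop("unknown label value(s): ", paste(neg[-1], collapse = ", "),
         " (expected '", positive_class, "' and one negative label)",
         call. = FALSE)
  }

  pos_t <- truth == positive_class
  pos_p <- predicted == positive_class
  tp <- sum(pos_t & pos_p)
  fn <- sum(pos_t & !pos_p)
  tn <- sum(!pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p)

  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tpr <- ratio(tp, tp + fn)
  tnr <- ratio(tn, tn + fp)
  wacc <- if (is.na(tpr) || is.na(tnr)) NA_real_ else (tpr + tnr) / 2
  tibble::tibble(
    wacc = wacc,
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    tpr = tpr,
    tnr = tnr)
}

# Macro-averaged accuracy over the classes present in `truth`; NA if any
# class present has no observations (cannot happen) -- plain helper used for
# the in-sample retention rule.
weighted_accuracy <- function(truth, predicted) {
  classes <- unique(truth)
  accs <- vapply(classes, function(cl) {
    idx <- truth == cl
    mean(predicted[idx] == cl)
  }, numeric(1))
  mean(accs)
}
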