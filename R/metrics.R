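#' Confusion counts
#'
#' The positive class is LVDD throughout.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return a `ConfusionCounts` list.
#' @export
confusionCounts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0)) stop("counts must be non-negative")
  if (sum(v) == 0) stop("total count must be positive")
  structure(as.list(v), class = "ConfusionCounts")
}

# counts from predicted/true label vectors
.countsFromLabels <- function(predicted, truth) {
  confusionCounts(tp = sum(predicted == "lvdd" & truth == "lvdd"),
                  tn = sum(predicted == "control" & truth == "control"),
                  fp = sum(predicted == "lvdd" & truth == "control"),
                  fn = sum(predicted == "control" & truth == "lvdd"))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `Acc = (TP+TN)/(TP+TN+FP+FN)`, `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`.
#' A zero denominator raises an error naming the undefined metric.
#'
#' @param counts a [confusionCounts()] object (or tp/tn/fp/fn passed
#'   directly).
#' @param tn,fp,fn counts when `counts` is given as `tp`.
#' @return list with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusionMetrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (!inherits(counts, "ConfusionCounts"))
    counts <- confusionCounts(counts, tn, fp, fn)
  with(counts, {
    if (tp + fn == 0) stop("sensitivity undefined: TP + FN == 0")
    if (tn + fp == 0) stop("specificity undefined: TN + FP == 0")
    list(accuracy = (tp + tn) / (tp + tn + fp + fn),
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp))
  })
}
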