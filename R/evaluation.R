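# Confusion-matrix construction and one-vs-rest per-class metrics.

#' Confusion matrix over the severity grades
#'
#' Rows are true grades, columns predicted grades, in the fixed severity
#' order.
#'
#' @param truth,predicted character vectors of equal length with values in
#'   `classes`.
#' @param classes class order (default the five severity grades).
#' @return n x n integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, predicted, classes = DR_GRADES) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  if (!all(truth %in% classes) || !all(predicted %in% classes))
    stop("labels outside the class set", call. = FALSE)
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- unclass(matrix(as.integer(cm), length(classes), length(classes),
                       dimnames = list(truth = classes, predicted = classes)))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Per-class one-vs-rest metrics
#'
#' For each grade treated as the positive class: accuracy
#' \eqn{(TP+TN)/N}, precision \eqn{TP/(TP+FP)}, recall \eqn{TP/(TP+FN)} and
#' F1 (harmonic mean of precision and recall). Ratios with zero denominator
#' are reported as 0 and flagged in the `undefined` column. The overall
#' (micro) accuracy — the diagonal fraction — is attached as an attribute.
#'
#' @param cm a [confusion()] matrix (any square count matrix with
#'   dimnames works).
#' @return data.frame of class `metric_report` with columns class,
#'   accuracy, precision, recall, f1, support, undefined; attribute
#'   `overall_accuracy`.
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0)
    stop("cm must be a nonempty square count matrix", call. = FALSE)
  total <- sum(cm)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  res <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    ratio <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
    pr <- ratio(tp, tp + fp)
    rc <- ratio(tp, tp + fn)
    f1 <- if (pr[1] + rc[1] == 0) c(0, TRUE)
          else c(2 * pr[1] * rc[1] / (pr[1] + rc[1]), FALSE)
    data.frame(class = classes[i],
               accuracy = (tp + tn) / total,
               precision = pr[1], recall = rc[1], f1 = f1[1],
               support = tp + fn,
               undefined = as.logical(pr[2] | rc[2] | f1[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "overall_accuracy") <- sum(diag(cm)) / total
  class(out) <- c("metric_report", "data.frame")
  out
}
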