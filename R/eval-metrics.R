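# Classification metrics for the ROI/non-ROI classifier (per-class precision,
# recall, F1, accuracy, macro and support-weighted averages) and the counting
# accuracy/error used to compare automated against reference counts.

#' Build a two-class confusion matrix
#'
#' @param labels,predictions equal-length vectors over \{0, 1\}
#'   (0 = Non-ROI, 1 = ROI).
#' @return a \code{\link{ConfusionMatrix2-class}}; rows are truth, columns
#'   predictions, order (Non-ROI, ROI).
#' @examples
#' confusionFrom(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' @export
confusionFrom <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (length(labels) == 0) stop("empty input")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop("labels and predictions must be 0 (Non-ROI) or 1 (ROI)")
  f <- function(v) factor(v, levels = c(0, 1))
  counts <- unclass(table(truth = f(labels), predicted = f(predictions)))
  dimnames(counts) <- NULL
  new("ConfusionMatrix2", counts = counts, classes = c("Non-ROI", "ROI"))
}

#' Construct a confusion matrix from raw counts
#'
#' @param counts 2x2 matrix, rows = truth, columns = predictions, class
#'   order (Non-ROI, ROI).
#' @return a \code{\link{ConfusionMatrix2-class}}.
#' @export
confusionMatrix2 <- function(counts) {
  counts <- as.matrix(counts)
  dimnames(counts) <- NULL
  new("ConfusionMatrix2", counts = counts, classes = c("Non-ROI", "ROI"))
}

.ovr <- function(cm, i) {
  m <- cm@counts
  list(tp = m[i, i], fp = sum(m[-i, i]), fn = sum(m[i, -i]),
       tn = sum(m[-i, -i]))
}

.safeRatio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reported as 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest for each class: precision = TP / (TP + FP),
#' recall = TP / (TP + FN), F1 = 2PR / (P + R). Metrics with a zero
#' denominator are reported as 0 with a warning.
#'
#' @param cm a \code{\link{ConfusionMatrix2-class}}.
#' @return data.frame with columns class, precision, recall, f1, support.
#' @export
classMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix2"))
  validObject(cm)
  out <- lapply(1:2, function(i) {
    o <- .ovr(cm, i)
    p <- .safeRatio(o$tp, o$tp + o$fp, paste0("precision(", cm@classes[i], ")"))
    r <- .safeRatio(o$tp, o$tp + o$fn, paste0("recall(", cm@classes[i], ")"))
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(class = cm@classes[i], precision = p, recall = r, f1 = f1,
               support = o$tp + o$fn)
  })
  do.call(rbind, out)
}

#' Aggregate classification metrics
#'
#' Accuracy = (TP + TN) / total; macro averages are unweighted class means;
#' weighted averages weight each class by its support (number of true
#' instances).
#'
#' @param cm a \code{\link{ConfusionMatrix2-class}}.
#' @return a \code{\link{MetricsReport-class}}.
#' @examples
#' aggregateMetrics(confusionMatrix2(rbind(c(41, 2), c(0, 15))))
#' @export
aggregateMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix2"))
  total <- sum(cm@counts)
  if (total == 0) stop("empty confusion matrix")
  pc <- classMetrics(cm)
  wts <- pc$support / sum(pc$support)
  new("MetricsReport", perClass = pc,
      accuracy = sum(diag(cm@counts)) / total,
      macroPrecision = mean(pc$precision), macroRecall = mean(pc$recall),
      macroF1 = mean(pc$f1),
      weightedPrecision = sum(wts * pc$precision),
      weightedRecall = sum(wts * pc$recall),
      weightedF1 = sum(wts * pc$f1),
      total = as.integer(total))
}

#' Counting accuracy and error percentage
#'
#' Accuracy = measured count / actual count x 100 (per cent); the companion
#' error is |100 - accuracy|, so over- and under-counts are penalized alike.
#'
#' @param measured automated count (>= 0).
#' @param actual reference count (> 0).
#' @return named numeric vector with elements \code{accuracy} and
#'   \code{error}, both in per cent.
#' @examples
#' countingAccuracy(246, 250)  # accuracy 98.4, error 1.6
#' @export
countingAccuracy <- function(measured, actual) {
  if (!is.finite(actual) || actual <= 0)
    stop("actual count must be a positive number")
  if (!is.finite(measured) || measured < 0)
    stop("measured count must be non-negative")
  acc <- measured / actual * 100
  c(accuracy = acc, error = abs(100 - acc))
}

#' Format a metrics report as a plain-text table
#'
#' Two-decimal display; raw values remain in the report object.
#'
#' @param report a \code{\link{MetricsReport-class}}.
#' @return character vector of table lines.
#' @export
formatMetricsTable <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  f <- function(x) sprintf("%9.2f", x)
  pc <- report@perClass
  lines <- c(sprintf("%-14s%9s%9s%9s%9s", "Metric", "Precision", "Recall",
                     "F1-score", "Support"))
  for (i in seq_len(nrow(pc)))
    lines <- c(lines, sprintf("%-14s%s%s%s%9d", toupper(pc$class[i]),
                              f(pc$precision[i]), f(pc$recall[i]), f(pc$f1[i]),
                              pc$support[i]))
  lines <- c(lines,
    sprintf("%-14s%9s%9s%s%9d", "Accuracy", "-", "-", f(report@accuracy),
            report@total),
    sprintf("%-14s%s%s%s%9d", "Macro avg", f(report@macroPrecision),
            f(report@macroRecall), f(report@macroF1), report@total),
    sprintf("%-14s%s%s%s%9d", "Weighted avg", f(report@weightedPrecision),
            f(report@weightedRecall), f(report@weightedF1), report@total))
  lines
}

#' Write a metrics report as JSON
#'
#' @param report a \code{\link{MetricsReport-class}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMetricsJSON <- function(report, path) {
  stopifnot(is(report, "MetricsReport"))
  pc <- report@perClass
  jsonlite::write_json(list(
    per_class = lapply(seq_len(nrow(pc)), function(i)
      list(class = pc$class[i], precision = pc$precision[i],
           recall = pc$recall[i], f1 = pc$f1[i], support = pc$support[i])),
    accuracy = report@accuracy,
    macro_avg = list(precision = report@macroPrecision,
                     recall = report@macroRecall, f1 = report@macroF1),
    weighted_avg = list(precision = report@weightedPrecision,
                        recall = report@weightedRecall, f1 = report@weightedF1),
    total = report@total), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
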