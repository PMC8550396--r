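# Evaluation: confusion matrices (raw and row-normalized), accuracy,
# per-class and macro F1, the two accuracy variants around inconsistent
# one-vs-rest predictions, and set-membership accuracy against sets of
# acceptable labels.

#' Confusion matrix
#'
#' Counts of predictions per actual class (rows = actual, columns =
#' predicted), together with the row-normalized rates whose diagonal holds
#' the per-class true positive rates. Predictions may contain the
#' [INCONSISTENT] sentinel, which is rendered as an extra predicted-only
#' column.
#'
#' @param truths,predictions equal-length label vectors.
#' @param labels the label space; defaults to the sorted union of values
#'   seen (minus the sentinel).
#' @return object of class `confusion_matrix` with fields `labels`,
#'   `counts` and `normalized`.
#' @export
confusion <- function(truths, predictions, labels = NULL) {
  if (length(truths) != length(predictions)) {
    stop("truths and predictions must have equal length")
  }
  truths <- as.character(truths)
  predictions <- as.character(predictions)
  if (is.null(labels)) {
    labels <- sort(setdiff(unique(c(truths, predictions)), INCONSISTENT))
  }
  if (length(bad <- setdiff(truths, labels))) {
    stop("unknown truth label(s): ", paste(unique(bad), collapse = ", "))
  }
  if (length(bad <- setdiff(predictions, c(labels, INCONSISTENT)))) {
    stop("unknown predicted label(s): ", paste(unique(bad), collapse = ", "))
  }
  pred_levels <- c(labels,
                   if (INCONSISTENT %in% predictions) INCONSISTENT)
  counts <- table(factor(truths, levels = labels),
                  factor(predictions, levels = pred_levels))
  counts <- unclass(counts)
  dimnames(counts) <- list(actual = labels, predicted = pred_levels)
  totals <- rowSums(counts)
  normalized <- counts / ifelse(totals > 0, totals, 1)
  structure(list(labels = labels, counts = counts, normalized = normalized),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 3, ...) {
  cat("Confusion matrix (rows = actual, cols = predicted):\n")
  print(x$counts)
  cat("Row-normalized rates:\n")
  print(round(x$normalized, digits))
  invisible(x)
}

#' Overall accuracy from a confusion matrix
#'
#' Correct predictions over all cases: the trace over the total. In the
#' binary case this is `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param cm a [confusion()] matrix.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm$counts)
  if (total == 0) stop("empty confusion matrix")
  diag_cells <- cm$counts[cbind(cm$labels, cm$labels)]
  sum(diag_cells) / total
}

per_class_stats <- function(cm) {
  labs <- cm$labels
  tp <- cm$counts[cbind(labs, labs)]
  fn <- rowSums(cm$counts)[labs] - tp
  fp <- colSums(cm$counts)[labs] - tp
  data.frame(label = labs, tp = as.numeric(tp), fn = as.numeric(fn),
             fp = as.numeric(fp), row.names = NULL)
}

#' Per-class F1 and macro F1
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`, `F1` their
#' harmonic mean, and macro-F1 the unweighted mean of per-class F1 over the
#' label space. Degenerate classes with no true and no predicted instances
#' are dropped from the macro mean; classes with true instances but no
#' correct or predicted ones get F1 = 0.
#'
#' @param cm a [confusion()] matrix.
#' @return `f1_per_class`: named numeric vector of F1 scores (NA for
#'   classes absent from both truths and predictions); `macro_f1`: scalar.
#' @export
f1_per_class <- function(cm) {
  st <- per_class_stats(cm)
  f1 <- mapply(function(tp, fn, fp) {
    if (tp + fn + fp == 0) return(NA_real_)  # never true, never predicted
    if (tp == 0) return(0)
    r <- tp / (tp + fn)
    p <- tp / (tp + fp)
    2 * p * r / (p + r)
  }, st$tp, st$fn, st$fp)
  names(f1) <- st$label
  f1
}

#' @rdname f1_per_class
#' @export
macro_f1 <- function(cm) {
  f1 <- f1_per_class(cm)
  mean(f1, na.rm = TRUE)
}

#' Accuracy including and excluding inconsistent predictions
#'
#' The one-vs-rest merge can output the [INCONSISTENT] sentinel. The
#' "include" accuracy counts those cases as wrong over all cases; the
#' "without" accuracy drops them from both numerator and denominator, so it
#' is never smaller than the "include" one.
#'
#' @param truths,predictions equal-length label vectors; `predictions` may
#'   contain [INCONSISTENT].
#' @return named numeric vector `c(include = ..., without = ...)`.
#' @export
accuracy_with_without_inconsistent <- function(truths, predictions) {
  if (length(truths) != length(predictions)) {
    stop("truths and predictions must have equal length")
  }
  n <- length(truths)
  if (n == 0) stop("no predictions")
  cons <- predictions != INCONSISTENT
  if (!any(cons)) stop("all predictions are inconsistent")
  correct <- sum(predictions[cons] == truths[cons])
  c(include = correct / n, without = correct / sum(cons))
}

#' Set-membership accuracy
#'
#' Fraction of predictions contained in the per-image set of acceptable
#' labels (e.g. after adding the alternative colors a species is known to
#' have). With singleton sets this equals plain accuracy.
#'
#' @param predictions label vector.
#' @param acceptable_sets list of non-empty character vectors, one per
#'   prediction.
#' @return rate in `[0, 1]`.
#' @export
set_membership_accuracy <- function(predictions, acceptable_sets) {
  if (length(predictions) != length(acceptable_sets)) {
    stop("predictions and acceptable_sets must have equal length")
  }
  if (any(lengths(acceptable_sets) == 0)) {
    stop("acceptable sets must be non-empty")
  }
  mean(mapply(function(p, s) p %in% s, predictions, acceptable_sets))
}

#' Export a confusion matrix
#'
#' `write_confusion_csv` writes the raw counts as CSV;
#' `plot.confusion_matrix` draws the row-normalized rates as a heat map.
#'
#' @param cm a [confusion()] matrix.
#' @param path CSV path.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(cm$counts), path, row.names = TRUE)
  invisible(path)
}

#' @export
plot.confusion_matrix <- function(x, ...) {
  z <- t(x$normalized)[, rev(seq_len(nrow(x$normalized))), drop = FALSE]
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z,
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "actual",
                  zlim = c(0, 1), ...)
  graphics::axis(1, seq_len(nrow(z)), rownames(z), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(ncol(z)), colnames(z), las = 1, cex.axis = 0.8)
  graphics::box()
  invisible(x)
}
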