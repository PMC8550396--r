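# Fusion of classifier outputs into a single color label: multi-class
# argmax, one-vs-rest logical merge under the domain closure axiom,
# max-probability over binary heads, and the MLTC / MLCR two-classifier
# ensembles driven by per-label true positive rates.

#' Sentinel label for contradictory one-vs-rest merges
#' @export
INCONSISTENT <- "INCONSISTENT"

#' Label from a multi-class probability vector
#'
#' @param probs named numeric vector (or 1-row matrix) of class
#'   probabilities; must sum to 1 within `tol`.
#' @param labels label order used for tie-breaking; defaults to
#'   `names(probs)`.
#' @param tol tolerance on the sum-to-one check.
#' @return the label with maximum probability (ties broken by label order).
#' @export
predict_multiclass <- function(probs, labels = NULL, tol = 1e-6) {
  probs <- drop(as.matrix(probs))
  if (is.matrix(probs)) stop("predict_multiclass expects a single vector")
  if (is.null(labels)) labels <- names(probs)
  if (is.null(labels) || length(labels) != length(probs)) {
    stop("labels must accompany the probability vector")
  }
  if (length(probs) == 0) stop("empty probability vector")
  if (abs(sum(probs) - 1) > tol) {
    stop("probabilities must sum to 1 (got ", format(sum(probs)), ")")
  }
  labels[which.max(probs)]
}

#' One-vs-rest logical merge (method 1)
#'
#' Merges the hard 0/1 decisions of `m - 1` binary classifiers for an
#' m-label problem. Exactly one positive decision names the label; two or
#' more positives are contradictory and yield [INCONSISTENT]; no positives
#' imply, by the domain closure axiom (the true label is one of the m
#' allowed labels) plus mutual exclusiveness, the remaining m-th label.
#'
#' @param decisions 0/1 (or logical) vector of length `m - 1`, one per label
#'   in `full_labels[1:(m-1)]`.
#' @param full_labels all m labels; the last one is the label implied when
#'   every binary classifier says no.
#' @return a list of class `fusion_result` with fields `label` and
#'   `provenance` (`"single_positive"`, `"contradiction"` or
#'   `"domain_closure"`).
#' @export
merge_one_vs_rest <- function(decisions, full_labels) {
  m <- length(full_labels)
  decisions <- as.numeric(decisions)
  if (length(decisions) != m - 1) {
    stop("need m - 1 = ", m - 1, " decisions, got ", length(decisions))
  }
  if (!all(decisions %in% c(0, 1))) stop("decisions must be 0/1")
  npos <- sum(decisions)
  if (npos == 1) {
    res <- list(label = full_labels[which(decisions == 1)],
                provenance = "single_positive")
  } else if (npos >= 2) {
    res <- list(label = INCONSISTENT, provenance = "contradiction")
  } else {
    res <- list(label = full_labels[m], provenance = "domain_closure")
  }
  structure(res, class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("Fusion result: %s (%s)\n", x$label, x$provenance))
  invisible(x)
}

#' Max-probability merge of binary heads (method 2)
#'
#' Selects the label whose binary head reports the highest probability.
#' Unlike the one-vs-rest merge it can never produce an inconsistent
#' result.
#'
#' @param per_label_probs named numeric vector mapping every label of the
#'   m-label space to its binary-head probability in `[0, 1]`.
#' @param labels the full label space (order used for tie-breaking);
#'   defaults to `names(per_label_probs)`.
#' @return the selected label.
#' @export
merge_max_probability <- function(per_label_probs, labels = NULL) {
  if (is.null(labels)) labels <- names(per_label_probs)
  if (is.null(labels)) stop("per_label_probs must be named or labels given")
  missing <- setdiff(labels, names(per_label_probs))
  if (length(missing)) {
    stop("missing probability for label(s): ", paste(missing, collapse = ", "))
  }
  p <- as.numeric(per_label_probs[labels])
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  labels[which.max(p)]
}

#' Per-label true positive rates
#'
#' TPR (recall) per class: the diagonal of the row-normalized confusion
#' matrix, `TP / (TP + FN)`.
#'
#' @param predictions,truths equal-length label vectors.
#' @param classifier_id identifier stored in the table (e.g. `"C1"` for the
#'   multi-class classifier, `"C2"` for the combined-binary one).
#' @param labels label set; defaults to the labels present in `truths`.
#' @param source_split which split the rates were measured on.
#' @return object of class `tpr_table`: list with `classifier_id`, `tpr`
#'   (named rates) and `source_split`.
#' @export
compute_tpr_table <- function(predictions, truths, classifier_id = "C1",
                              labels = NULL,
                              source_split = c("validation", "test")) {
  source_split <- match.arg(source_split)
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length")
  }
  if (is.null(labels)) labels <- sort(unique(as.character(truths)))
  absent <- setdiff(labels, as.character(truths))
  if (length(absent)) {
    stop("TPR undefined for class(es) absent from truths: ",
         paste(absent, collapse = ", "))
  }
  tpr <- vapply(labels, function(lb) {
    sel <- truths == lb
    sum(predictions[sel] == lb) / sum(sel)
  }, numeric(1))
  structure(list(classifier_id = classifier_id, tpr = tpr,
                 source_split = source_split),
            class = "tpr_table")
}

#' Construct a TPR table from known rates
#'
#' @param tpr named numeric vector of per-label true positive rates.
#' @inheritParams compute_tpr_table
#' @export
tpr_table <- function(tpr, classifier_id = "C1",
                      source_split = c("validation", "test")) {
  source_split <- match.arg(source_split)
  if (is.null(names(tpr))) stop("tpr must be a named vector")
  if (any(tpr < 0 | tpr > 1)) stop("rates must lie in [0, 1]")
  structure(list(classifier_id = classifier_id, tpr = tpr,
                 source_split = source_split),
            class = "tpr_table")
}

#' @export
print.tpr_table <- function(x, ...) {
  cat(sprintf("TPR table for %s (%s split):\n", x$classifier_id,
              x$source_split))
  print(round(x$tpr, 4))
  invisible(x)
}

tpr_of <- function(tab, label) {
  if (!label %in% names(tab$tpr)) {
    stop("no TPR entry for label '", label, "' in table ", tab$classifier_id)
  }
  unname(tab$tpr[label])
}

#' Most Likely True Color (MLTC) ensemble
#'
#' Combines the labels of two classifiers. If they agree, that label is the
#' result; if they disagree, the label whose own classifier has the higher
#' true positive rate for it wins (ties go to the first classifier).
#'
#' @param l1,l2 labels predicted by classifiers 1 and 2.
#' @param t1,t2 [tpr_table()]s of the two classifiers.
#' @return the ensemble label.
#' @export
ensemble_mltc <- function(l1, l2, t1, t2) {
  if (l1 == l2) return(l1)
  if (tpr_of(t1, l1) >= tpr_of(t2, l2)) l1 else l2
}

#' MLCR candidate ratios
#'
#' For each disagreeing candidate label, the ratio of the predicting
#' classifier's TPR for it over the other classifier's TPR for the same
#' label: `ratio(l1) = t1[l1] / t2[l1]` and `ratio(l2) = t2[l2] / t1[l2]`.
#' A low ratio means the predicting classifier is relatively weak on that
#' label, i.e. the two classifiers' rates are wide apart.
#'
#' @inheritParams ensemble_mltc
#' @return named numeric vector of the two ratios (names `l1`, `l2`).
#' @export
mlcr_ratios <- function(l1, l2, t1, t2) {
  r <- c(tpr_of(t1, l1) / tpr_of(t2, l1),
         tpr_of(t2, l2) / tpr_of(t1, l2))
  names(r) <- c(l1, l2)
  r
}

#' Most Likely Color Ratio (MLCR) ensemble
#'
#' Like [ensemble_mltc()] when the two classifiers agree. On disagreement,
#' each candidate label's TPR ratio between the two classifiers is computed
#' (see [mlcr_ratios()]) and the label with the *lower* ratio -- the one for
#' which the two classifiers' rates are wider apart -- is returned, as in
#' the method's worked example. If a required denominator TPR is zero the
#' ensemble falls back to MLTC with a warning.
#'
#' @inheritParams ensemble_mltc
#' @return the ensemble label.
#' @examples
#' t1 <- tpr_table(c(red = 0.38, white = 0.70), "C1")
#' t2 <- tpr_table(c(red = 0.58, white = 0.59), "C2")
#' ensemble_mltc("red", "white", t1, t2)  # "white" (0.59 > 0.38)
#' ensemble_mlcr("red", "white", t1, t2)  # "red"   (0.66 < 0.84)
#' @export
ensemble_mlcr <- function(l1, l2, t1, t2) {
  if (l1 == l2) return(l1)
  if (tpr_of(t2, l1) == 0 || tpr_of(t1, l2) == 0) {
    warning("zero TPR denominator; falling back to MLTC")
    return(ensemble_mltc(l1, l2, t1, t2))
  }
  r <- mlcr_ratios(l1, l2, t1, t2)
  if (r[1] == r[2]) return(ensemble_mltc(l1, l2, t1, t2))
  if (r[1] < r[2]) l1 else l2
}

#' Write / read probability matrices as CSV
#'
#' Rows are images, columns the canonical labels.
#'
#' @param probs numeric matrix with labels as column names.
#' @param path CSV path.
#' @export
write_prob_csv <- function(probs, path) {
  utils::write.csv(as.data.frame(probs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prob_csv
#' @export
read_prob_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Write a TPR table as JSON
#'
#' @param tab a [tpr_table()].
#' @param path JSON path.
#' @export
write_tpr_json <- function(tab, path) {
  jsonlite::write_json(
    list(classifier_id = tab$classifier_id,
         source_split = tab$source_split,
         tpr = as.list(tab$tpr)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_tpr_json
#' @export
read_tpr_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tpr_table(unlist(obj$tpr), classifier_id = obj$classifier_id,
            source_split = obj$source_split)
}
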