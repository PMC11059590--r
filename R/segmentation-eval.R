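# Classification and segmentation evaluation: confusion matrices, one-vs-rest
# per-class metrics, and Dice overlap.

#' Build a confusion matrix
#'
#' @param truth,pred equal-length label vectors.
#' @param class_set ordered label universe; defaults to the sorted union of
#'   observed labels.
#' @return an object of class `confusion_matrix`: an integer matrix with rows
#'   = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, class_set = NULL) {
  if (length(truth) != length(pred)) {
    abort_glom("truth and pred must have equal length", "glomRPS_bad_input")
  }
  class_set <- class_set %||% sort(unique(c(truth, pred)))
  unknown <- setdiff(unique(c(truth, pred)), class_set)
  if (length(unknown)) {
    abort_glom(paste0("label(s) outside class_set: ", paste(unknown, collapse = ", ")),
               "glomRPS_unknown_label")
  }
  t_f <- factor(truth, levels = class_set)
  p_f <- factor(pred, levels = class_set)
  cm <- table(truth = t_f, prediction = p_f)
  out <- matrix(as.integer(cm), nrow = length(class_set),
                dimnames = list(truth = class_set, prediction = class_set))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  print(unclass(x))
  invisible(x)
}

#' One-vs-rest metrics for one class of a confusion matrix
#'
#' Accuracy, specificity, precision, recall and F1 are computed one-vs-rest:
#' TP is the diagonal cell, FN the rest of the row, FP the rest of the
#' column, TN everything else. A metric whose denominator is zero is
#' reported as `NA` ("undefined"), never silently as 0: no predictions for a
#' class is not the same thing as all predictions wrong.
#'
#' @param cm a [confusion_matrix()].
#' @param cls the class to score.
#' @return a named list with `tp`, `fn`, `fp`, `tn`, `accuracy`,
#'   `specificity`, `precision`, `recall`, `f1`.
#' @export
per_class_metrics <- function(cm, cls) {
  stopifnot(inherits(cm, "confusion_matrix"))
  classes <- rownames(cm)
  if (!cls %in% classes) {
    abort_glom(paste0("class not in class_set: ", cls), "glomRPS_unknown_label")
  }
  total <- sum(cm)
  if (total == 0) abort_glom("empty confusion matrix", "glomRPS_bad_input")
  tp <- cm[cls, cls]
  fn <- sum(cm[cls, ]) - tp
  fp <- sum(cm[, cls]) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    f1_from_pr(precision, recall)
  }
  list(
    tp = tp, fn = fn, fp = fp, tn = tn,
    accuracy = (tp + tn) / total,
    specificity = safe_div(tn, tn + fp),
    precision = precision,
    recall = recall,
    f1 = f1
  )
}

#' Metrics table for every class of a confusion matrix
#'
#' @param cm a [confusion_matrix()].
#' @return data.frame with one row per class and the five one-vs-rest metric
#'   columns.
#' @export
metrics_table <- function(cm) {
  rows <- lapply(rownames(cm), function(cl) {
    m <- per_class_metrics(cm, cl)
    data.frame(class = cl, accuracy = m$accuracy, specificity = m$specificity,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall fractions in `[0, 1]`, not both zero.
#' @return the F1 score `2PR/(P+R)`.
#' @export
f1_from_pr <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  if (any(precision + recall == 0)) {
    abort_glom("F1 undefined: precision + recall = 0", "glomRPS_undefined")
  }
  2 * precision * recall / (precision + recall)
}

#' Dice overlap of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks agree perfectly on absence, so
#' the both-empty case is defined as 1.
#'
#' @param maskA,maskB logical/0-1 matrices of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) {
    abort_glom("mask shapes differ", "glomRPS_bad_input")
  }
  a <- as.logical(maskA); b <- as.logical(maskB)
  sz <- sum(a) + sum(b)
  if (sz == 0) return(1.0)
  2 * sum(a & b) / sz
}

#' Mean Dice over mask pairs, overall and by group
#'
#' @param pairs non-empty list; each element a list/pair of two binary masks.
#' @param group_labels optional vector of group tags, one per pair.
#' @return list with `per_pair`, `overall` (the pooled mean over all pairs,
#'   i.e. count-weighted across groups) and, when groups are given,
#'   `by_group` plus `group_mean` (the unweighted mean of the per-group
#'   means — differs from `overall` when group sizes differ).
#' @export
mean_dice <- function(pairs, group_labels = NULL) {
  if (!length(pairs)) abort_glom("empty list of mask pairs", "glomRPS_bad_input")
  d <- vapply(pairs, function(p) dice_coefficient(p[[1]], p[[2]]), numeric(1))
  out <- list(per_pair = d, overall = mean(d))
  if (!is.null(group_labels)) {
    stopifnot(length(group_labels) == length(pairs))
    by_group <- tapply(d, group_labels, mean)
    out$by_group <- by_group
    out$group_mean <- mean(by_group)
  }
  out
}
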