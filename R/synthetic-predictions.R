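# Confusion-controlled label generator: a stand-in for classifier output with
# planted per-class error rates.

#' Specification of a label-confusion process
#'
#' @param class_set ordered character vector of class labels.
#' @param rate_matrix square row-stochastic matrix; entry `[i, j]` is the
#'   probability that a truth of class `class_set[i]` is predicted as
#'   `class_set[j]`. Rows must sum to 1 within 1e-9.
#' @return an object of class `confusion_spec`.
#' @export
confusion_spec <- function(class_set, rate_matrix) {
  stopifnot(is.character(class_set), length(class_set) >= 2,
            !anyDuplicated(class_set))
  rate_matrix <- as.matrix(rate_matrix)
  k <- length(class_set)
  if (!all(dim(rate_matrix) == k)) {
    abort_glom("rate_matrix must be square with one row per class", "glomRPS_bad_spec")
  }
  if (any(rate_matrix < 0)) {
    abort_glom("rate_matrix entries must be non-negative", "glomRPS_bad_spec")
  }
  if (any(abs(rowSums(rate_matrix) - 1) > 1e-9)) {
    abort_glom("every rate_matrix row must sum to 1 within 1e-9", "glomRPS_bad_spec")
  }
  dimnames(rate_matrix) <- list(class_set, class_set)
  structure(list(class_set = class_set, rate_matrix = rate_matrix),
            class = "confusion_spec")
}

#' Draw predicted labels with planted confusion rates
#'
#' Each prediction is drawn independently from the rate-matrix row of its true
#' label, so the empirical per-class recall converges to the diagonal entry.
#'
#' @param true_types character vector of true labels, all in `spec$class_set`.
#' @param spec a [confusion_spec()].
#' @param seed integer seed.
#' @return character vector of predicted labels, same length as `true_types`.
#' @export
generate_prediction_labels <- function(true_types, spec, seed = 1L) {
  stopifnot(inherits(spec, "confusion_spec"))
  unknown <- setdiff(unique(true_types), spec$class_set)
  if (length(unknown)) {
    abort_glom(paste0("unknown label(s): ", paste(unknown, collapse = ", ")),
               "glomRPS_unknown_label")
  }
  with_seed(seed, {
    pred <- character(length(true_types))
    for (cls in spec$class_set) {
      sel <- true_types == cls
      if (!any(sel)) next
      pred[sel] <- sample(spec$class_set, sum(sel), replace = TRUE,
                          prob = spec$rate_matrix[cls, ])
    }
    pred
  })
}
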