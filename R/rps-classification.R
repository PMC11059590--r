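# Rule-based RPS classification: percent GS and KW presence decide classes IV
# and III; ROC-derived cutoffs on one mesangium feature separate I / IIa / IIb.

CLASS_FEATURES <- c(
  mean_mesangial_area = "ms_mesangial_area_um2",
  mesangial_area_fraction = "ms_mesangial_area_fraction",
  mesangial_area_per_mesangial_cell = "ms_mesangial_area_per_cell"
)

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the unique score values (classifying a
#' case positive when its score is >= the threshold). The trapezoidal area
#' under the resulting curve equals the probability that a random positive
#' outscores a random negative, ties counted one half — i.e. the Mann-Whitney
#' U statistic divided by `n1 * n0`.
#'
#' @param scores numeric scores, larger = more likely positive.
#' @param labels binary labels (logical, 0/1, or two-level factor with the
#'   second level positive).
#' @return object of class `roc_result`: `thresholds` (decreasing, with a
#'   `+Inf` sentinel), parallel non-decreasing `tpr` and `fpr`, and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y), !any(is.na(scores)))
  if (length(unique(y)) < 2) {
    abort_glom("both classes must be present to build a ROC curve",
               "glomRPS_bad_input")
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yo <- y[o]
  last_of_tie <- which(diff(s) != 0)
  idx <- c(last_of_tie, length(s))
  tp <- cumsum(yo)[idx]; fp <- cumsum(1 - yo)[idx]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(thresholds = c(Inf, s[idx]), tpr = tpr, fpr = fpr, auc = auc,
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) > 2) abort_glom("labels must be binary", "glomRPS_bad_input")
    return(as.integer(labels == levels(labels)[2]))
  }
  u <- unique(labels)
  if (!all(u %in% c(0, 1))) abort_glom("labels must be binary 0/1", "glomRPS_bad_input")
  as.integer(labels)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Optimal ROC cutoff by Youden's J
#'
#' Maximises `J = tpr - fpr` over the operating points of the curve and
#' returns a threshold placed midway between the unique score values it
#' separates, so applying `score >= cutoff` reproduces the chosen operating
#' point. Ties in J are broken toward the smallest cutoff.
#'
#' @param roc a [roc_result][roc_curve()].
#' @return numeric cutoff.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$tpr - roc$fpr
  scores <- roc$thresholds[-1] # finite unique scores, decreasing
  cand <- j[-1] # J at "positive iff score >= scores[i]"
  # midpoint between the operating score and the next smaller unique score
  lower <- c(scores[-1], scores[length(scores)] - 1)
  cutoffs <- (scores + lower) / 2
  best <- max(cand)
  min(cutoffs[cand >= best - 1e-12])
}

#' Fit ordinal mesangial cutoffs for early RPS classes
#'
#' Builds two ROC splits over patients of classes I, IIa and IIb: `I` vs
#' `IIa + IIb`, and `I + IIa` vs `IIb` (one-vs-rest on the ordinal scale), or
#' adjacent-pair splits (`I` vs `IIa`, `IIa` vs `IIb`). Cutoffs come from
#' Youden's J via [optimal_cutoff()]; if the two violate the ordinal order
#' they are swapped with a warning. An AUC at or below 0.55 triggers a
#' degenerate-cutoff warning: the feature does not separate the classes.
#'
#' @param features a `patient_features` data.frame (or numeric vector of the
#'   feature itself).
#' @param classes vector of pathologist classes, values in `I`, `IIa`, `IIb`.
#' @param feature which mesangium feature to use (one of
#'   `names(CLASS_FEATURES)`); ignored when `features` is numeric.
#' @param split `"one_vs_rest"` (default) or `"adjacent"`.
#' @return object of class `early_cutoffs` with fields `feature_name`,
#'   `cutoff_I_vs_II`, `cutoff_IIa_vs_IIb`, `auc_I_vs_II`, `auc_IIa_vs_IIb`,
#'   `n`, `split`.
#' @export
fit_early_cutoffs <- function(features, classes,
                              feature = names(CLASS_FEATURES),
                              split = c("one_vs_rest", "adjacent")) {
  split <- match.arg(split)
  feature <- match.arg(feature)
  x <- if (is.numeric(features)) features else features[[CLASS_FEATURES[[feature]]]]
  stopifnot(length(x) == length(classes))
  keep <- !is.na(x) & classes %in% c("I", "IIa", "IIb")
  x <- x[keep]; classes <- as.character(classes[keep])
  missing_cls <- setdiff(c("I", "IIa", "IIb"), unique(classes))
  if (length(missing_cls)) {
    abort_glom(paste0("class(es) absent from early-cutoff fit: ",
                      paste(missing_cls, collapse = ", ")),
               "glomRPS_bad_input")
  }
  if (split == "one_vs_rest") {
    roc1 <- roc_curve(x, classes %in% c("IIa", "IIb"))
    roc2 <- roc_curve(x, classes == "IIb")
  } else {
    s1 <- classes %in% c("I", "IIa")
    s2 <- classes %in% c("IIa", "IIb")
    roc1 <- roc_curve(x[s1], classes[s1] == "IIa")
    roc2 <- roc_curve(x[s2], classes[s2] == "IIb")
  }
  c1 <- optimal_cutoff(roc1); c2 <- optimal_cutoff(roc2)
  if (c1 > c2) {
    warning("ordinal cutoffs out of order; swapping", call. = FALSE)
    tmp <- c1; c1 <- c2; c2 <- tmp
  }
  if (roc1$auc <= 0.55 || roc2$auc <= 0.55) {
    warning(sprintf(
      "degenerate cutoff: feature barely separates early classes (AUCs %.3f, %.3f)",
      roc1$auc, roc2$auc), call. = FALSE)
  }
  structure(
    list(feature_name = feature, cutoff_I_vs_II = c1, cutoff_IIa_vs_IIb = c2,
         auc_I_vs_II = roc1$auc, auc_IIa_vs_IIb = roc2$auc,
         n = length(x), split = split),
    class = "early_cutoffs"
  )
}

#' @export
print.early_cutoffs <- function(x, ...) {
  cat(sprintf(
    "<early_cutoffs> %s (%s, n=%d)\n  I|II  cutoff %.4g (AUC %.3f)\n  II|IIb cutoff %.4g (AUC %.3f)\n",
    x$feature_name, x$split, x$n, x$cutoff_I_vs_II, x$auc_I_vs_II,
    x$cutoff_IIa_vs_IIb, x$auc_IIa_vs_IIb))
  invisible(x)
}

#' Assign RPS classes from patient features
#'
#' Decision order: percent GS > 50 gives class IV; otherwise a patient with
#' any KW glomerulus is class III; otherwise the mesangium feature decides
#' between I (below the I|II cutoff), IIa (below the IIa|IIb cutoff) and IIb.
#' A patient on the early path whose midsection feature is missing (no
#' midsection KW/NOA glomerulus) is returned as NA with a warning, never
#' silently defaulted.
#'
#' @param features `patient_features` data.frame (any number of rows).
#' @param cuts fitted [early_cutoffs][fit_early_cutoffs()].
#' @return ordered factor with levels I < IIa < IIb < III < IV.
#' @export
assign_class <- function(features, cuts) {
  stopifnot(inherits(cuts, "early_cutoffs"), is.data.frame(features))
  x <- features[[CLASS_FEATURES[[cuts$feature_name]]]]
  out <- rep(NA_character_, nrow(features))
  out[features$percent_GS > 50] <- "IV"
  early <- is.na(out) & !features$has_KW
  out[is.na(out) & features$has_KW] <- "III"
  out[early & !is.na(x) & x < cuts$cutoff_I_vs_II] <- "I"
  out[early & !is.na(x) & x >= cuts$cutoff_I_vs_II &
        x < cuts$cutoff_IIa_vs_IIb] <- "IIa"
  out[early & !is.na(x) & x >= cuts$cutoff_IIa_vs_IIb] <- "IIb"
  if (any(early & is.na(x))) {
    ids <- if ("patient_id" %in% names(features)) {
      paste(features$patient_id[early & is.na(x)], collapse = ", ")
    } else {
      paste(which(early & is.na(x)), collapse = ", ")
    }
    warning(paste0("unclassifiable (missing midsection feature): ", ids),
            call. = FALSE)
  }
  factor(out, levels = RPS_CLASSES, ordered = TRUE)
}
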