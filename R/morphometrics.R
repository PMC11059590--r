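# Per-glomerulus and per-patient morphometric quantification.
#
# Conventions:
#   * glomerular area = tuft area (mask codes 2 and 3), excluding the Bowman
#     capsule ring; this is also the denominator of every cell density.
#   * areas are pixel counts times pixel_size_um^2, no sub-pixel contours.
#   * "undefined" quantities (e.g. mesangial area per mesangial cell when no
#     mesangial cell was counted) are NA, never 0.

MORPHO_COLS <- c(
  "glomerular_area_um2", "mesangial_area_um2", "mesangial_area_fraction",
  "n_mesangial", "n_endothelial", "n_podocyte",
  "mesangial_area_per_cell",
  "density_mesangial", "density_endothelial", "density_podocyte",
  "ratio_mesangial", "ratio_endothelial", "ratio_podocyte"
)

# Derived morphometric columns from the base ones; shared between the mask
# path (glomerulus_morphometrics) and the cohort simulator, so both emit
# identical schemas.
morpho_derive <- function(df) {
  tot <- df$n_mesangial + df$n_endothelial + df$n_podocyte
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(
    mesangial_area_per_cell = safe(df$mesangial_area_um2, df$n_mesangial),
    density_mesangial = safe(df$n_mesangial, df$glomerular_area_um2),
    density_endothelial = safe(df$n_endothelial, df$glomerular_area_um2),
    density_podocyte = safe(df$n_podocyte, df$glomerular_area_um2),
    ratio_mesangial = safe(df$n_mesangial, tot),
    ratio_endothelial = safe(df$n_endothelial, tot),
    ratio_podocyte = safe(df$n_podocyte, tot)
  )
}

#' Morphometrics of one labeled glomerulus
#'
#' @param g a [labeled_glomerulus()].
#' @return one-row data.frame with columns `lesion_type`,
#'   `glomerular_area_um2`, `mesangial_area_um2`, `mesangial_area_fraction`,
#'   the three cell counts, `mesangial_area_per_cell`, three densities
#'   (cells/um2 of tuft) and three ratios (fractions of all intrinsic cells).
#' @export
glomerulus_morphometrics <- function(g) {
  stopifnot(inherits(g, "labeled_glomerulus"))
  if (g$pixel_size_um <= 0) abort_glom("pixel size must be positive", "glomRPS_bad_input")
  px2 <- g$pixel_size_um^2
  n_tuft <- sum(g$mask == 2L | g$mask == 3L)
  if (n_tuft == 0) abort_glom("empty tuft region", "glomRPS_bad_input")
  n_mes_px <- sum(g$mask == 3L)
  counts <- table(factor(g$cells$cell_type, levels = CELL_TYPES))
  base <- data.frame(
    lesion_type = g$lesion_type,
    glomerular_area_um2 = n_tuft * px2,
    mesangial_area_um2 = n_mes_px * px2,
    mesangial_area_fraction = n_mes_px / n_tuft,
    n_mesangial = as.integer(counts[["mesangial"]]),
    n_endothelial = as.integer(counts[["endothelial"]]),
    n_podocyte = as.integer(counts[["podocyte"]]),
    stringsAsFactors = FALSE
  )
  cbind(base, morpho_derive(base))
}

#' Midsection filter
#'
#' A glomerular profile counts as cut near its midsection when it shows at
#' least 50 intrinsic cells in total (mesangial + endothelial + podocyte).
#'
#' @param x a [labeled_glomerulus()], a morphometrics row (data.frame with
#'   the three count columns), or a numeric vector of cell counts.
#' @return logical (vectorised over data.frame rows).
#' @export
is_midsection <- function(x) {
  total <- if (inherits(x, "labeled_glomerulus")) {
    nrow(x$cells)
  } else if (is.data.frame(x)) {
    x$n_mesangial + x$n_endothelial + x$n_podocyte
  } else {
    sum(x)
  }
  total >= 50
}

#' Flag mild mesangial expansion
#'
#' True when the mesangial area fraction is below 0.2596, the 95th-percentile
#' bound of the fraction observed in early (<= IIa) disease.
#'
#' @param Mf mesangial area fraction in `[0, 1]` (vectorised).
#' @return logical.
#' @export
flag_mild_mesangial_expansion <- function(Mf) {
  if (any(is.na(Mf)) || any(Mf < 0 | Mf > 1)) {
    abort_glom("mesangial area fraction must be in [0, 1]", "glomRPS_bad_input")
  }
  Mf < 0.2596
}

#' Aggregate glomeruli to patient-level features
#'
#' Lesion-type percentages are computed over all glomeruli of the patient.
#' The intraglomerular means (`ms_` columns) are computed only over KW and
#' NOA glomeruli in the midsection (>= 50 intrinsic cells), each glomerulus
#' weighted equally; when a patient has no such glomerulus the means are NA.
#'
#' @param glomeruli either a data.frame of morphometric rows (one per
#'   glomerulus, with `lesion_type` and the columns of
#'   [glomerulus_morphometrics()]) or a list of [labeled_glomerulus()]
#'   objects.
#' @return one-row data.frame of class `patient_features`: `n_glomeruli`,
#'   `percent_GS` ... `percent_NOA`, `has_KW`, `n_midsection`, and `ms_`
#'   prefixed means of every morphometric column.
#' @export
patient_aggregate <- function(glomeruli) {
  if (is.list(glomeruli) && !is.data.frame(glomeruli)) {
    glomeruli <- do.call(rbind, lapply(glomeruli, glomerulus_morphometrics))
  }
  if (!is.data.frame(glomeruli) || nrow(glomeruli) == 0) {
    abort_glom("patient_aggregate needs at least one glomerulus", "glomRPS_bad_input")
  }
  stopifnot(all(c("lesion_type", MORPHO_COLS) %in% names(glomeruli)))
  n <- nrow(glomeruli)
  pct <- 100 * as.vector(table(factor(glomeruli$lesion_type,
                                      levels = LESION_TYPES))) / n
  names(pct) <- paste0("percent_", LESION_TYPES)
  ms_sel <- glomeruli$lesion_type %in% c("KW", "NOA") & is_midsection(glomeruli)
  ms <- glomeruli[ms_sel, MORPHO_COLS, drop = FALSE]
  ms_means <- if (nrow(ms) > 0) {
    colMeans(ms, na.rm = TRUE)
  } else {
    stats::setNames(rep(NA_real_, length(MORPHO_COLS)), MORPHO_COLS)
  }
  ms_means[is.nan(ms_means)] <- NA_real_
  out <- data.frame(
    n_glomeruli = n, t(pct), has_KW = pct[["percent_KW"]] > 0,
    n_midsection = sum(ms_sel), t(ms_means),
    stringsAsFactors = FALSE
  )
  names(out) <- c("n_glomeruli", names(pct), "has_KW", "n_midsection",
                  paste0("ms_", MORPHO_COLS))
  class(out) <- c("patient_features", "data.frame")
  out
}

#' Patient-level feature table for a whole cohort
#'
#' @param glom_df glomerulus morphometric table with a `patient_id` column.
#' @return data.frame with one row per patient (`patient_id` first column).
#' @export
aggregate_cohort <- function(glom_df) {
  stopifnot("patient_id" %in% names(glom_df))
  ids <- unique(glom_df$patient_id)
  rows <- lapply(ids, function(id) {
    pf <- patient_aggregate(glom_df[glom_df$patient_id == id, , drop = FALSE])
    cbind(data.frame(patient_id = id, stringsAsFactors = FALSE), pf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("patient_features", "data.frame")
  out
}

#' Rank-based group comparison
#'
#' Mann-Whitney U for two groups, Kruskal-Wallis H for two or more, with
#' average-rank tie handling. For the two-group test an exact p-value is used
#' when both groups have at most 20 observations and no ties are present;
#' otherwise the normal approximation with continuity correction applies.
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @param test `"mann_whitney"` (exactly two groups) or `"kruskal_wallis"`.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(values_by_group,
                           test = c("mann_whitney", "kruskal_wallis")) {
  test <- match.arg(test)
  if (!is.list(values_by_group) || length(values_by_group) < 2) {
    abort_glom("need at least two groups", "glomRPS_bad_input")
  }
  if (any(!lengths(values_by_group))) {
    abort_glom("every group must be non-empty", "glomRPS_bad_input")
  }
  if (test == "mann_whitney") {
    if (length(values_by_group) != 2) {
      abort_glom("mann_whitney requires exactly two groups", "glomRPS_bad_input")
    }
    x <- values_by_group[[1]]; y <- values_by_group[[2]]
    exact <- max(length(x), length(y)) <= 20 && !anyDuplicated(c(x, y))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Mann-Whitney U")
  } else {
    ht <- stats::kruskal.test(values_by_group)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Kruskal-Wallis H")
  }
}
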