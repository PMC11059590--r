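# Agreement and prognostic statistics: Cohen's kappa, Spearman correlation,
# comparison of two dependent overlapping correlations, time-averaged
# proteinuria, eGFR slope, ESRD event accounting and the prognostic table.

#' Cohen's kappa between two raters
#'
#' Unweighted kappa from the joint contingency table over the union of
#' observed labels: `kappa = (po - pe) / (1 - pe)` with `po` the diagonal
#' fraction and `pe` the sum of marginal products. When both raters are
#' constant and identical (`pe = 1`) kappa is undefined and returned as NA.
#'
#' @param a,b equal-length label vectors (length >= 2).
#' @return object of class `agreement_result` with `kappa`,
#'   `observed_agreement`, `expected_agreement`, `n`, `table`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) {
    abort_glom("rater vectors must have equal length", "glomRPS_bad_input")
  }
  if (length(a) < 2) abort_glom("need at least 2 rated items", "glomRPS_bad_input")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  tab <- table(factor(as.character(a), lev), factor(as.character(b), lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) NA_real_ else (po - pe) / (1 - pe)
  structure(
    list(kappa = kappa, observed_agreement = po, expected_agreement = pe,
         n = n, table = tab),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> kappa = %s (po = %.3f, pe = %.3f, n = %d)\n",
              ifelse(is.na(x$kappa), "undefined", sprintf("%.3f", x$kappa)),
              x$observed_agreement, x$expected_agreement, x$n))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with a two-sided p-value from the
#' t approximation `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#' A constant input vector gives an undefined (NA) correlation.
#'
#' @param x,y equal-length numeric vectors, n >= 3; NA pairs are dropped.
#' @return list with `r`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort_glom("need at least 3 complete pairs", "glomRPS_bad_input")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- stats::cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) {
    0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Compare two dependent overlapping correlations
#'
#' Tests whether `cor(j, k)` differs from `cor(j, h)` when both correlations
#' are computed on the same `n` cases and share variable `j` (e.g. one
#' clinical indicator correlated with two raters' classes). The default is
#' Dunn and Clark's z computed with the backtransformed average of the two
#' Fisher-transformed correlations (the variant that method comparisons since
#' the early 2000s recommend); plain Steiger averaging and Meng's method are
#' selectable.
#'
#' @param r_jk,r_jh the two correlations sharing variable j.
#' @param r_kh correlation between the two non-shared variables.
#' @param n number of cases (>= 10).
#' @param method `"hittner"` (Dunn-Clark z, backtransformed average),
#'   `"steiger"` (Dunn-Clark z, plain average), or `"meng"`.
#' @return object of class `correlation_comparison` with `Z`, `p_value` and
#'   the inputs.
#' @export
compare_dependent_correlations <- function(r_jk, r_jh, r_kh, n,
                                           method = c("hittner", "steiger", "meng")) {
  method <- match.arg(method)
  if (n < 10) abort_glom("need n >= 10", "glomRPS_bad_input")
  rs <- c(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh)
  if (any(abs(rs) >= 1)) {
    abort_glom("correlations must satisfy |r| < 1 (Fisher transform diverges)",
               "glomRPS_bad_input")
  }
  z_jk <- atanh(r_jk); z_jh <- atanh(r_jh)
  cov_term <- function(r_m) {
    (r_kh * (1 - 2 * r_m^2) - 0.5 * r_m^2 * (1 - 2 * r_m^2 - r_kh^2)) /
      (1 - r_m^2)^2
  }
  Z <- switch(method,
    hittner = {
      r_m <- tanh((z_jk + z_jh) / 2)
      (z_jk - z_jh) * sqrt((n - 3) / (2 - 2 * cov_term(r_m)))
    },
    steiger = {
      r_m <- (r_jk + r_jh) / 2
      (z_jk - z_jh) * sqrt((n - 3) / (2 - 2 * cov_term(r_m)))
    },
    meng = {
      r_m2 <- (r_jk^2 + r_jh^2) / 2
      f <- min((1 - r_kh) / (2 * (1 - r_m2)), 1)
      h <- (1 - f * r_m2) / (1 - r_m2)
      (z_jk - z_jh) * sqrt((n - 3) / (2 * (1 - r_kh) * h))
    }
  )
  p <- 2 * stats::pnorm(-abs(Z))
  structure(
    list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n, method = method,
         Z = Z, p_value = p),
    class = "correlation_comparison"
  )
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("<correlation_comparison> %s: Z = %.3f, p = %.4g (r_jk = %.3f, r_jh = %.3f, r_kh = %.3f, n = %d)\n",
              x$method, x$Z, x$p_value, x$r_jk, x$r_jh, x$r_kh, x$n))
  invisible(x)
}

#' Time-averaged proteinuria
#'
#' Trapezoidal area under the serial proteinuria curve divided by the span
#' from first to last proteinuria measurement.
#'
#' @param time_years visit times (years).
#' @param proteinuria_g24h proteinuria at each visit (g/24h); NA visits are
#'   dropped.
#' @return TA-P in g/24h, or NA when fewer than two measurements remain.
#' @export
time_average_proteinuria <- function(time_years, proteinuria_g24h) {
  keep <- stats::complete.cases(time_years, proteinuria_g24h)
  t <- time_years[keep]; p <- proteinuria_g24h[keep]
  if (length(t) < 2) return(NA_real_)
  o <- order(t)
  t <- t[o]; p <- p[o]
  auc <- sum(diff(t) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  auc / (t[length(t)] - t[1])
}

#' eGFR slope by ordinary least squares
#'
#' @param time_years visit times (years).
#' @param egfr eGFR at each visit (ml/min/1.73m2).
#' @return OLS slope in ml/min/1.73m2/year, NA with fewer than two distinct
#'   time points.
#' @export
egfr_slope <- function(time_years, egfr) {
  keep <- stats::complete.cases(time_years, egfr)
  t <- time_years[keep]; y <- egfr[keep]
  if (length(t) < 2 || length(unique(t)) < 2) return(NA_real_)
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' ESRD event detection on one trajectory
#'
#' ESRD = eGFR < 15 ml/min/1.73m2 or dialysis, sustained over at least 3
#' months, or renal transplantation (immediate). At visit resolution
#' "sustained" means the criterion holds at a visit and at every subsequent
#' visit up to one at least 3 months (0.25 years) later — or holds at the
#' final visit, which cannot be contradicted before censoring.
#'
#' @param time_years visit times.
#' @param egfr eGFR series.
#' @param dialysis,transplant optional logical flags per visit.
#' @return list with `event` (logical) and `time` (years, NA if no event).
#' @export
esrd_event <- function(time_years, egfr, dialysis = NULL, transplant = NULL) {
  nv <- length(time_years)
  o <- order(time_years)
  t <- time_years[o]; g <- egfr[o]
  dia <- if (is.null(dialysis)) rep(FALSE, nv) else dialysis[o]
  tx <- if (is.null(transplant)) rep(FALSE, nv) else transplant[o]
  if (any(tx)) {
    return(list(event = TRUE, time = t[which(tx)[1]]))
  }
  crit <- (g < 15) | dia
  for (i in which(crit)) {
    if (i == nv) return(list(event = TRUE, time = t[i]))
    later <- seq(i + 1L, nv)
    run <- later[cumall(crit[later])]
    if (length(run) && max(t[run]) - t[i] >= 0.25) {
      return(list(event = TRUE, time = t[i]))
    }
    if (length(run) == length(later)) {
      # criterion held to the end of follow-up but < 3 months: censored event
      return(list(event = TRUE, time = t[i]))
    }
  }
  list(event = FALSE, time = NA_real_)
}

cumall <- function(x) cumprod(as.integer(x)) == 1

#' Filter a cohort for prognostic analysis
#'
#' Retains patients with follow-up of at least one month (last visit time
#' >= 1/12 year) and baseline eGFR >= 30 ml/min/1.73m2.
#'
#' @param visits longitudinal table with `patient_id`, `time_years`, `egfr`.
#' @return list with `keep` (patient ids), `n_total`,
#'   `n_excluded_followup`, `n_excluded_baseline_egfr`.
#' @export
prognosis_filter <- function(visits) {
  stopifnot(all(c("patient_id", "time_years", "egfr") %in% names(visits)))
  ids <- unique(visits$patient_id)
  last_t <- tapply(visits$time_years, visits$patient_id, max)[ids]
  base_e <- vapply(ids, function(id) {
    v <- visits[visits$patient_id == id, ]
    v$egfr[which.min(v$time_years)]
  }, numeric(1))
  ok_fu <- last_t >= 1 / 12
  ok_eg <- base_e >= 30
  list(
    keep = ids[ok_fu & ok_eg],
    n_total = length(ids),
    n_excluded_followup = sum(!ok_fu),
    n_excluded_baseline_egfr = sum(!ok_eg)
  )
}

#' Per-patient prognostic indicators
#'
#' @param visits longitudinal table (`patient_id`, `time_years`, `egfr`,
#'   `proteinuria_g24h`, optional `dialysis`, `transplant`).
#' @return data.frame with one row per patient: `baseline_proteinuria`,
#'   `tap`, `baseline_egfr`, `egfr_slope`, `esrd`.
#' @export
patient_indicators <- function(visits) {
  ids <- unique(visits$patient_id)
  rows <- lapply(ids, function(id) {
    v <- visits[visits$patient_id == id, ]
    v <- v[order(v$time_years), ]
    ev <- esrd_event(v$time_years, v$egfr, v$dialysis, v$transplant)
    data.frame(
      patient_id = id,
      baseline_proteinuria = v$proteinuria_g24h[1],
      tap = time_average_proteinuria(v$time_years, v$proteinuria_g24h),
      baseline_egfr = v$egfr[1],
      egfr_slope = egfr_slope(v$time_years, v$egfr),
      esrd = as.integer(ev$event),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Spearman correlations of RPS classes with prognostic indicators
#'
#' Correlates one (or two) sets of ordinal RPS classes with baseline
#' proteinuria, time-averaged proteinuria, baseline eGFR, eGFR slope and the
#' ESRD indicator. With two raters, each indicator additionally gets a
#' dependent-correlation Z comparison ([compare_dependent_correlations()])
#' with `r_kh` the Spearman correlation between the two class vectors.
#'
#' @param classes named vector/factor of RPS classes (names = patient ids),
#'   or data.frame with `patient_id` and `class`.
#' @param visits longitudinal visit table.
#' @param classes2 optional second rater, same format.
#' @param filter apply [prognosis_filter()] first (default TRUE).
#' @return data.frame with one row per indicator: `r`, `p` (first rater);
#'   `r2`, `p2`, `Z`, `p_Z` when a second rater is given; `n` per row.
#' @export
prognostic_table <- function(classes, visits, classes2 = NULL, filter = TRUE) {
  cls1 <- as_class_vector(classes)
  cls2 <- if (!is.null(classes2)) as_class_vector(classes2)
  if (filter) {
    keep <- prognosis_filter(visits)$keep
    visits <- visits[visits$patient_id %in% keep, ]
  }
  ind <- patient_indicators(visits)
  ord1 <- as.numeric(factor(cls1[ind$patient_id], levels = RPS_CLASSES))
  ord2 <- if (!is.null(cls2)) {
    as.numeric(factor(cls2[ind$patient_id], levels = RPS_CLASSES))
  }
  indicators <- c(baseline_proteinuria = "baseline_proteinuria", tap = "tap",
                  baseline_egfr = "baseline_egfr", egfr_slope = "egfr_slope",
                  esrd = "esrd")
  rows <- lapply(names(indicators), function(nm) {
    y <- ind[[indicators[[nm]]]]
    ok <- stats::complete.cases(ord1, y)
    if (!is.null(ord2)) ok <- ok & !is.na(ord2)
    if (sum(ok) < 3) {
      warning(paste0("indicator dropped (<3 complete values): ", nm), call. = FALSE)
      return(NULL)
    }
    s1 <- spearman_cor(ord1[ok], y[ok])
    row <- data.frame(indicator = nm, n = s1$n, r = s1$r, p = s1$p_value,
                      stringsAsFactors = FALSE)
    if (!is.null(ord2)) {
      s2 <- spearman_cor(ord2[ok], y[ok])
      r_kh <- spearman_cor(ord1[ok], ord2[ok])$r
      row$r2 <- s2$r
      row$p2 <- s2$p_value
      if (!is.na(s1$r) && !is.na(s2$r) && !is.na(r_kh) &&
          max(abs(c(s1$r, s2$r, r_kh))) < 1) {
        cc <- compare_dependent_correlations(s1$r, s2$r, r_kh, s1$n)
        row$Z <- cc$Z
        row$p_Z <- cc$p_value
      } else {
        row$Z <- if (!is.na(s1$r) && !is.na(s2$r) && s1$r == s2$r) 0 else NA_real_
        row$p_Z <- if (!is.na(row$Z) && row$Z == 0) 1 else NA_real_
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_class_vector <- function(classes) {
  if (is.data.frame(classes)) {
    stopifnot(all(c("patient_id", "class") %in% names(classes)))
    stats::setNames(as.character(classes$class), classes$patient_id)
  } else {
    if (is.null(names(classes))) {
      abort_glom("classes must be named by patient_id (or be a data.frame)",
                 "glomRPS_bad_input")
    }
    stats::setNames(as.character(classes), names(classes))
  }
}
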