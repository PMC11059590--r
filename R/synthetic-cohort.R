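# Synthetic diabetic-nephropathy cohorts. Each patient carries a planted RPS
# class; per-glomerulus morphometric rows, patient trajectories (eGFR,
# proteinuria) and ESRD events all inherit the class-dependent structure that
# real biopsy cohorts show: mesangial expansion and mesangial cell numbers
# increase with class, podocyte numbers decrease, endothelial cells stay flat,
# eGFR decline and time-averaged proteinuria worsen with class.

RPS_CLASSES <- c("I", "IIa", "IIb", "III", "IV")

#' Specification of a synthetic DN cohort
#'
#' Class-wise defaults for eGFR slope (median, spread) and time-averaged
#' proteinuria reproduce published class-wise medians and interquartile ranges
#' of a biopsy-proven DN cohort: eGFR slopes of -1.89, -1.65, -3.34, -11.60
#' and -13.75 ml/min/1.73m2/year and TA-P of 0.73, 1.41, 1.60, 3.92 and 5.08
#' g/24h for classes I..IV. Note the literature medians themselves are not
#' monotone between classes I and IIa; the defaults keep that feature.
#' Normal spreads are IQR/1.349.
#'
#' @param n_patients number of patients (>= 1).
#' @param class_probs probability vector over classes I, IIa, IIb, III, IV;
#'   must sum to 1 within 1e-9. The default is weighted towards class III,
#'   as biopsy-referred DN cohorts are.
#' @param seed integer master seed; every draw in [generate_cohort()] flows
#'   from it through [derive_seed()].
#' @param mean_glomeruli mean glomeruli sampled per biopsy (Poisson).
#' @param mf_class_mean per-class mean of the patient-level mesangial area
#'   fraction.
#' @param mf_patient_sd between-patient SD of mesangial area fraction within
#'   a class (the "separation" of planted classes).
#' @param mf_glom_sd within-patient, between-glomerulus SD of the fraction;
#'   the intra-patient correlation of glomerular features is not known from
#'   the literature, so it is exposed here rather than fixed.
#' @param egfr_slope_median,egfr_slope_sd per-class planted eGFR slope
#'   location and spread (ml/min/1.73m2/year).
#' @param tap_median per-class median TA-P (g/24h); patients draw a log-normal
#'   level around it (`tap_sdlog`), visits jitter log-normally around the
#'   patient level (`visit_sdlog`).
#' @param baseline_egfr_mean,baseline_egfr_sd per-class baseline eGFR.
#' @param egfr_noise_sd visit-level Gaussian noise on eGFR.
#' @param followup_range follow-up duration drawn uniformly from this range
#'   (years); the default has mean ~2.6 years.
#' @param visit_interval_range visit spacing drawn uniformly from this range
#'   (years), i.e. 3-6 monthly.
#' @param offcut_prob probability a glomerulus is cut away from its
#'   midsection, scaling its apparent cell counts down.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200L,
                        class_probs = c(I = 0.08, IIa = 0.12, IIb = 0.15,
                                        III = 0.45, IV = 0.20),
                        seed = 1L,
                        mean_glomeruli = 62,
                        mf_class_mean = c(0.16, 0.22, 0.30, 0.36, 0.42),
                        mf_patient_sd = 0.02,
                        mf_glom_sd = 0.04,
                        egfr_slope_median = c(-1.89, -1.65, -3.34, -11.60, -13.75),
                        egfr_slope_sd = c(2.94, 6.55, 2.76, 12.49, 11.23),
                        tap_median = c(0.73, 1.41, 1.60, 3.92, 5.08),
                        tap_sdlog = c(0.58, 0.83, 1.18, 0.78, 0.77),
                        visit_sdlog = 0.25,
                        baseline_egfr_mean = c(105, 95, 85, 70, 55),
                        baseline_egfr_sd = 12,
                        egfr_noise_sd = 4,
                        followup_range = c(0.25, 4.9),
                        visit_interval_range = c(0.25, 0.5),
                        offcut_prob = 0.17) {
  if (n_patients < 1) abort_glom("n_patients must be >= 1", "glomRPS_bad_spec")
  stopifnot(length(class_probs) == 5)
  if (abs(sum(class_probs) - 1) > 1e-9) {
    abort_glom("class_probs must sum to 1 within 1e-9", "glomRPS_bad_spec")
  }
  names(class_probs) <- RPS_CLASSES
  # planted morphometric trends must be ordinal in class
  if (is.unsorted(mf_class_mean)) {
    abort_glom("mf_class_mean must be non-decreasing in class", "glomRPS_bad_spec")
  }
  cell_mean <- list(
    mesangial   = c(45, 55, 65, 80, 90),
    endothelial = c(70, 70, 70, 70, 70),
    podocyte    = c(60, 52, 45, 35, 28)
  )
  # lesion-type mixture per planted class (GS, SS, C, KW, NOA); class IV is
  # GS-dominated, KW lesions appear from class III on
  lesion_probs <- rbind(
    I   = c(0.05, 0.010, 0.002, 0.00, 0.938),
    IIa = c(0.10, 0.020, 0.005, 0.00, 0.875),
    IIb = c(0.18, 0.030, 0.005, 0.00, 0.785),
    III = c(0.30, 0.050, 0.010, 0.20, 0.440),
    IV  = c(0.65, 0.030, 0.010, 0.12, 0.190)
  )
  colnames(lesion_probs) <- LESION_TYPES
  glom_area_mean <- c(16000, 18000, 20000, 24000, 26000) # um^2, tuft
  structure(
    list(
      n_patients = as.integer(n_patients), class_probs = class_probs,
      seed = as.integer(seed), mean_glomeruli = mean_glomeruli,
      mf_class_mean = mf_class_mean, mf_patient_sd = mf_patient_sd,
      mf_glom_sd = mf_glom_sd, cell_mean = cell_mean,
      lesion_probs = lesion_probs, glom_area_mean = glom_area_mean,
      egfr_slope_median = egfr_slope_median, egfr_slope_sd = egfr_slope_sd,
      tap_median = tap_median, tap_sdlog = tap_sdlog,
      visit_sdlog = visit_sdlog,
      baseline_egfr_mean = baseline_egfr_mean,
      baseline_egfr_sd = baseline_egfr_sd, egfr_noise_sd = egfr_noise_sd,
      followup_range = followup_range,
      visit_interval_range = visit_interval_range, offcut_prob = offcut_prob
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic DN cohort
#'
#' Produces per-glomerulus morphometric rows (so [patient_aggregate()] and the
#' classification pipeline can run on them), longitudinal visit tables, and
#' the planted truth per patient. The noiseless eGFR trend of each patient has
#' exactly the planted slope; visit values add Gaussian noise. Proteinuria is
#' log-normal around a patient-specific level. A patient whose simulated eGFR
#' crosses below 15 stays below afterwards often enough that the standard
#' ESRD persistence rule fires.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `dn_cohort`: a list with data.frames
#'   `patients` (planted truth), `glomeruli` (one morphometric row per
#'   glomerulus) and `visits` (longitudinal table with columns `patient_id`,
#'   `time_years`, `egfr`, `proteinuria_g24h`, `dialysis`, `transplant`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  cls_idx <- with_seed(derive_seed(spec$seed, 0L),
                       sample.int(5L, n, replace = TRUE, prob = spec$class_probs))
  patients <- vector("list", n)
  gloms <- vector("list", n)
  visits <- vector("list", n)
  for (i in seq_len(n)) {
    k <- cls_idx[i]
    pid <- sprintf("P%04d", i)
    with_seed(derive_seed(spec$seed, i), {
      ng <- max(10L, stats::rpois(1, spec$mean_glomeruli))
      lesions <- sample(LESION_TYPES, ng, replace = TRUE,
                        prob = spec$lesion_probs[k, ])
      mf_pat <- min(0.85, max(0.02, stats::rnorm(1, spec$mf_class_mean[k],
                                                 spec$mf_patient_sd)))
      # KW/GS glomeruli carry more mesangium than the patient's NOA glomeruli
      mf_shift <- c(GS = 0.18, SS = 0.06, C = 0.03, KW = 0.10, NOA = 0)[lesions]
      mf_glom <- pmin(0.9, pmax(0.01, stats::rnorm(ng, mf_pat + mf_shift,
                                                   spec$mf_glom_sd)))
      area <- spec$glom_area_mean[k] *
        stats::rlnorm(ng, -0.5 * 0.25^2, 0.25) *
        c(GS = 0.75, SS = 1.0, C = 1.0, KW = 1.25, NOA = 1.0)[lesions]
      pat_scale <- stats::rlnorm(1, 0, 0.08)
      lam <- function(base) {
        mult <- c(GS = 0.35, SS = 0.9, C = 0.9, KW = 1.0, NOA = 1.0)[lesions]
        base[k] * pat_scale * mult
      }
      n_mes <- stats::rpois(ng, lam(spec$cell_mean$mesangial) *
                              c(GS = 1, SS = 1, C = 1, KW = 1.35, NOA = 1)[lesions])
      n_end <- stats::rpois(ng, lam(spec$cell_mean$endothelial))
      n_pod <- stats::rpois(ng, lam(spec$cell_mean$podocyte) *
                              c(GS = 1, SS = 1, C = 1, KW = 0.55, NOA = 1)[lesions])
      offcut <- stats::runif(ng) < spec$offcut_prob
      scale <- ifelse(offcut, stats::runif(ng, 0.2, 0.6), 1)
      n_mes <- round(n_mes * scale); n_end <- round(n_end * scale)
      n_pod <- round(n_pod * scale)
      area <- area * ifelse(offcut, scale^0.8, 1)

      g <- data.frame(
        patient_id = pid, glom_id = sprintf("%s_g%03d", pid, seq_len(ng)),
        lesion_type = lesions,
        glomerular_area_um2 = area,
        mesangial_area_um2 = mf_glom * area,
        mesangial_area_fraction = mf_glom,
        n_mesangial = as.integer(n_mes), n_endothelial = as.integer(n_end),
        n_podocyte = as.integer(n_pod),
        stringsAsFactors = FALSE
      )
      g <- cbind(g, morpho_derive(g))

      slope <- stats::rnorm(1, spec$egfr_slope_median[k], spec$egfr_slope_sd[k])
      egfr0 <- max(15, stats::rnorm(1, spec$baseline_egfr_mean[k],
                                    spec$baseline_egfr_sd))
      tap_pat <- spec$tap_median[k] * stats::rlnorm(1, 0, spec$tap_sdlog[k])
      fu <- stats::runif(1, spec$followup_range[1], spec$followup_range[2])
      times <- 0
      while (max(times) < fu) {
        times <- c(times, max(times) + stats::runif(1, spec$visit_interval_range[1],
                                                    spec$visit_interval_range[2]))
      }
      times <- times[times <= fu | seq_along(times) == 1]
      egfr <- pmax(2, egfr0 + slope * times +
                     c(0, stats::rnorm(length(times) - 1, 0, spec$egfr_noise_sd)))
      prot <- tap_pat * stats::rlnorm(length(times), -0.5 * spec$visit_sdlog^2,
                                      spec$visit_sdlog)
      v <- data.frame(
        patient_id = pid, time_years = times, egfr = egfr,
        proteinuria_g24h = prot, dialysis = FALSE, transplant = FALSE,
        stringsAsFactors = FALSE
      )
      patients[[i]] <- data.frame(
        patient_id = pid, true_class = RPS_CLASSES[k], n_glomeruli = ng,
        baseline_egfr = egfr0, egfr_slope_true = slope, tap_true = tap_pat,
        stringsAsFactors = FALSE
      )
      gloms[[i]] <- g
      visits[[i]] <- v
    })
  }
  structure(
    list(
      patients = do.call(rbind, patients),
      glomeruli = do.call(rbind, gloms),
      visits = do.call(rbind, visits),
      spec = spec
    ),
    class = "dn_cohort"
  )
}

#' @export
print.dn_cohort <- function(x, ...) {
  cat(sprintf("<dn_cohort> %d patients, %d glomeruli, %d visits\n",
              nrow(x$patients), nrow(x$glomeruli), nrow(x$visits)))
  print(table(x$patients$true_class)[RPS_CLASSES])
  invisible(x)
}
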