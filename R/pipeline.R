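# End-to-end pipeline: cohort (simulated or read from disk) -> glomerulus
# features -> patient features -> early cutoffs -> RPS classes -> agreement
# and prognosis tables, with a stage-level run log.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer master seed.
#' @param n_patients cohort size when simulating.
#' @param feature mesangium feature used for early-class cutoffs.
#' @param glom_features_csv optional existing glomerulus feature table; when
#'   given, it is read instead of simulating (must then also give
#'   `classes_csv` and, for prognosis, `visits_csv`).
#' @param classes_csv optional reference (pathologist) classes CSV with
#'   columns `patient_id`, `class`.
#' @param visits_csv optional longitudinal visits CSV.
#' @param cohort_spec optional [cohort_spec()] overriding `n_patients`/`seed`
#'   for simulation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_patients = 50L,
                            feature = names(CLASS_FEATURES),
                            glom_features_csv = NULL, classes_csv = NULL,
                            visits_csv = NULL, cohort_spec = NULL) {
  feature <- match.arg(feature)
  cfg <- structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_patients = as.integer(n_patients), feature = feature,
         glom_features_csv = glom_features_csv, classes_csv = classes_csv,
         visits_csv = visits_csv, cohort_spec = cohort_spec),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!is.null(cfg$glom_features_csv)) {
    for (p in c(cfg$glom_features_csv, cfg$classes_csv)) {
      if (is.null(p)) {
        abort_glom("classes_csv is required when glom_features_csv is given",
                   "glomRPS_config")
      }
      if (!file.exists(p)) {
        abort_glom(paste0("configured input does not exist: ", p), "glomRPS_config")
      }
    }
    if (!is.null(cfg$visits_csv) && !file.exists(cfg$visits_csv)) {
      abort_glom(paste0("configured input does not exist: ", cfg$visits_csv),
                 "glomRPS_config")
    }
  }
  invisible(cfg)
}

#' Run the full classification + prognosis pipeline
#'
#' Writes `glom_features.csv`, `patient_features.csv`, `cutoffs.json`,
#' `classes.csv`, `agreement.json`, `prognosis.csv` and `run_log.txt` under
#' `config$out_dir`. Identical config + seed produces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("glomRPS %s", as.character(utils::packageVersion("glomRPS"))),
    sprintf("seed: %d", config$seed),
    sprintf("feature: %s", config$feature)
  )
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (is.null(config$glom_features_csv)) {
    spec <- config$cohort_spec %||%
      cohort_spec(n_patients = config$n_patients, seed = config$seed)
    cohort <- generate_cohort(spec)
    glom_df <- cohort$glomeruli
    ref_classes <- data.frame(patient_id = cohort$patients$patient_id,
                              class = cohort$patients$true_class,
                              stringsAsFactors = FALSE)
    visits <- cohort$visits
    note("stage simulate: %d patients, %d glomeruli, %d visits",
         nrow(cohort$patients), nrow(glom_df), nrow(visits))
  } else {
    glom_df <- utils::read.csv(config$glom_features_csv, stringsAsFactors = FALSE)
    ref_classes <- utils::read.csv(config$classes_csv, stringsAsFactors = FALSE)
    visits <- if (!is.null(config$visits_csv)) {
      utils::read.csv(config$visits_csv, stringsAsFactors = FALSE)
    }
    note("stage read: %d glomerulus rows", nrow(glom_df))
  }
  write_table_csv(glom_df, file.path(config$out_dir, "glom_features.csv"))

  pf <- aggregate_cohort(glom_df)
  write_table_csv(pf, file.path(config$out_dir, "patient_features.csv"))
  note("stage aggregate: %d patients, %d with midsection features",
       nrow(pf), sum(!is.na(pf$ms_mesangial_area_fraction)))

  ref <- as_class_vector(ref_classes)[pf$patient_id]
  early_sel <- ref %in% c("I", "IIa", "IIb")
  cuts <- fit_early_cutoffs(pf[early_sel, , drop = FALSE], ref[early_sel],
                            feature = config$feature)
  jsonlite::write_json(
    list(feature = cuts$feature_name, split = cuts$split, n = cuts$n,
         cutoff_I_vs_II = cuts$cutoff_I_vs_II,
         cutoff_IIa_vs_IIb = cuts$cutoff_IIa_vs_IIb,
         auc_I_vs_II = cuts$auc_I_vs_II, auc_IIa_vs_IIb = cuts$auc_IIa_vs_IIb),
    file.path(config$out_dir, "cutoffs.json"),
    auto_unbox = TRUE, digits = 10
  )
  note("stage fit: cutoffs %.6g / %.6g (AUC %.3f / %.3f) on %d early patients",
       cuts$cutoff_I_vs_II, cuts$cutoff_IIa_vs_IIb, cuts$auc_I_vs_II,
       cuts$auc_IIa_vs_IIb, cuts$n)

  assigned <- assign_class(pf, cuts)
  classes_df <- data.frame(patient_id = pf$patient_id,
                           class = as.character(assigned),
                           stringsAsFactors = FALSE)
  write_table_csv(classes_df, file.path(config$out_dir, "classes.csv"))
  note("stage assign: %d classified, %d unclassifiable",
       sum(!is.na(assigned)), sum(is.na(assigned)))

  ok <- !is.na(assigned)
  agr <- cohens_kappa(as.character(assigned[ok]), ref[ok])
  jsonlite::write_json(
    list(kappa = agr$kappa, observed_agreement = agr$observed_agreement,
         expected_agreement = agr$expected_agreement, n = agr$n),
    file.path(config$out_dir, "agreement.json"),
    auto_unbox = TRUE, digits = 10
  )
  note("stage agreement: kappa %.4f on %d patients", agr$kappa, agr$n)

  prog <- NULL
  if (!is.null(visits)) {
    cls1 <- stats::setNames(as.character(assigned[ok]), pf$patient_id[ok])
    cls2 <- as_class_vector(ref_classes)
    flt <- prognosis_filter(visits)
    note("stage prognosis filter: %d/%d retained (%d short follow-up, %d low baseline eGFR)",
         length(flt$keep), flt$n_total, flt$n_excluded_followup,
         flt$n_excluded_baseline_egfr)
    visits_kept <- visits[visits$patient_id %in% intersect(flt$keep, names(cls1)), ]
    prog <- prognostic_table(cls1, visits_kept, classes2 = cls2, filter = FALSE)
    write_table_csv(prog, file.path(config$out_dir, "prognosis.csv"))
    note("stage prognosis: %d indicators", nrow(prog))
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(glom_features = glom_df, patient_features = pf, cutoffs = cuts,
                 classes = classes_df, agreement = agr, prognosis = prog,
                 log = log_lines))
}
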