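## Tabular interfaces: patient TDM records (CSV), population model
## configuration (YAML), and bundled example data.

.RECORD_COLS <- c("patient_id", "dose_mg", "tau_h", "days_on", "days_off",
                  "sample_time_after_dose_h", "analyte", "conc_ng_ml",
                  "blq_flag", "toxicity_grade2plus", "clinical_benefit",
                  "empirical_new_dose_mg")

#' Path to a bundled example file
#'
#' Lists or returns the path of the plain-text data files shipped with
#' the package (population model configuration and small reference
#' tables used in examples and regression tests).
#'
#' @param file File name; if `NULL`, lists available files.
#' @return A file path, or a character vector of file names.
#' @export
sunidose_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "sunidose")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no bundled file called ", file, call. = FALSE)
  path
}

#' Read a population PK model from a YAML configuration
#'
#' The configuration carries typical values, log-scale IIV standard
#' deviations and the residual error model per analyte, all with
#' explicit units. `default_population()` loads the bundled sunitinib +
#' N-desethyl sunitinib base model.
#'
#' @param path Path to a YAML file (see the bundled
#'   `sunitinib_population.yaml` for the schema).
#' @return A [population_pk()] object.
#' @export
read_population_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  an <- function(a) analyte_pk(a$ka, a$cl, a$v1, a$q, a$v2)
  typ <- individual_pk(parent = an(cfg$parent$typical),
                       metabolite = an(cfg$metabolite$typical))
  omega <- c()
  for (side in c("parent", "metabolite")) {
    om <- cfg[[side]]$omega
    if (length(om)) {
      omega <- c(omega, stats::setNames(unlist(om),
                                        paste(side, names(om), sep = ".")))
    }
  }
  err <- function(e) residual_error(e$sigma_prop, e$sigma_add, e$loq)
  population_pk(typ, omega,
                error = list(parent = err(cfg$parent$error),
                             metabolite = err(cfg$metabolite$error)))
}

#' @rdname read_population_config
#' @export
default_population <- function() {
  read_population_config(sunidose_example("sunitinib_population.yaml"))
}

#' Write patient TDM records to CSV
#'
#' One row per measured analyte per sample, in the schema read back by
#' [read_patient_records()].
#'
#' @param cohort A `synthetic_cohort` object (see [generate_cohort()]);
#'   if [apply_empirical_rules()] has not been applied, the empirical
#'   dose column is left `NA`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_records <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  p <- cohort$patients
  o <- cohort$observations
  i <- match(o$patient_id, p$id)
  df <- data.frame(
    patient_id = o$patient_id,
    dose_mg = p$dose_mg[i], tau_h = p$tau_h[i],
    days_on = p$days_on[i], days_off = p$days_off[i],
    sample_time_after_dose_h = o$time_after_dose,
    analyte = o$analyte,
    conc_ng_ml = o$conc, blq_flag = o$blq,
    toxicity_grade2plus = p$toxicity_grade2plus[i],
    clinical_benefit = p$clinical_benefit[i],
    empirical_new_dose_mg = if ("empirical_new_dose_mg" %in% names(p)) {
      p$empirical_new_dose_mg[i]
    } else NA_real_)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read patient TDM records from CSV
#'
#' Validates the schema and returns one typed record per patient. A
#' record with only one measured analyte is accepted and flagged
#' (`single_analyte = TRUE`); a quantified concentration below the LOQ
#' without the BLQ flag raises a validation warning.
#'
#' @param path CSV path with columns `patient_id, dose_mg, tau_h,
#'   days_on, days_off, sample_time_after_dose_h, analyte, conc_ng_ml,
#'   blq_flag, toxicity_grade2plus, clinical_benefit,
#'   empirical_new_dose_mg`.
#' @param loq LOQ used for the validation warning (ng/mL).
#' @return A list of `patient_record` objects, each a list with `id`,
#'   `regimen` ([dose_regimen()]), `observations` (data.frame),
#'   `toxicity_grade2plus`, `clinical_benefit`,
#'   `empirical_new_dose_mg`, `single_analyte`.
#' @export
read_patient_records <- function(path, loq = 10) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  missing <- setdiff(.RECORD_COLS, names(df))
  if (length(missing)) {
    stop("patient record file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(df$analyte %in% c("parent", "metabolite"))) {
    bad <- which(!df$analyte %in% c("parent", "metabolite"))[1]
    stop("row ", bad, ", column 'analyte': unknown analyte '",
         df$analyte[bad], "'", call. = FALSE)
  }
  for (col in c("dose_mg", "tau_h")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad)) {
      stop("row ", bad[1], ", column '", col, "': must be positive",
           call. = FALSE)
    }
  }
  df$blq_flag <- as.logical(df$blq_flag)
  low <- !df$blq_flag & !is.na(df$conc_ng_ml) & df$conc_ng_ml < loq
  if (any(low)) {
    warning(sum(low), " quantified concentration(s) below the LOQ (",
            loq, " ng/mL) without a BLQ flag", call. = FALSE)
  }
  lapply(split(df, df$patient_id), function(d) {
    if (length(unique(d$dose_mg)) != 1) {
      stop("patient ", d$patient_id[1], ": inconsistent dose across rows",
           call. = FALSE)
    }
    structure(list(
      id = d$patient_id[1],
      regimen = dose_regimen(d$dose_mg[1], d$tau_h[1],
                             d$days_on[1], d$days_off[1]),
      observations = data.frame(analyte = d$analyte,
                                time_after_dose = d$sample_time_after_dose_h,
                                conc = d$conc_ng_ml,
                                blq = d$blq_flag,
                                at_steady_state = TRUE),
      toxicity_grade2plus = d$toxicity_grade2plus[1],
      clinical_benefit = d$clinical_benefit[1],
      empirical_new_dose_mg = d$empirical_new_dose_mg[1],
      single_analyte = length(unique(d$analyte)) < 2),
      class = "patient_record")
  })
}
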