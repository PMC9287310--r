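# Patient-level data model: one row per patient, canonical column set shared
# by the readers, the synthetic generator, and every downstream stage.

.patient_required <- c(
  "patient_id", "trial", "arm", "age", "sex", "race", "region", "ecog",
  "liver_mets", "time_from_met_dx", "ras_status",
  "pfs_time", "pfs_event", "os_time", "os_event"
)

.patient_levels <- list(
  trial      = c("current", "external"),
  arm        = c("experimental", "control"),
  sex        = c("female", "male"),
  race       = c("white", "nonwhite", "unknown"),
  region     = c("north_america", "europe", "asia_pacific"),
  ecog       = c("0", "1"),
  liver_mets = c("yes", "no"),
  ras_status = c("wild_type", "mutant", "unknown")
)

#' Validate a patient-level cohort table
#'
#' Checks the canonical cohort schema: required columns, categorical levels,
#' strictly positive survival times, binary event flags, unique patient ids,
#' the trial/arm consistency rule (external patients are control-only), and
#' `pfs_time <= os_time` per patient.
#'
#' @param cohort data frame with one row per patient.
#' @return The cohort, invisibly, when valid; otherwise an error naming the
#'   offending column or patient.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(.patient_required, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(cohort$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(cohort$patient_id[duplicated(cohort$patient_id)]),
               collapse = ", "), call. = FALSE)
  for (col in names(.patient_levels)) {
    vals <- as.character(cohort[[col]])
    bad <- !is.na(vals) & !(vals %in% .patient_levels[[col]])
    if (any(bad))
      stop(sprintf("unparseable level(s) in '%s' at row(s) %s: %s", col,
                   paste(which(bad), collapse = ", "),
                   paste(unique(vals[bad]), collapse = ", ")), call. = FALSE)
  }
  for (col in c("pfs_time", "os_time")) {
    bad <- !is.na(cohort[[col]]) & cohort[[col]] <= 0
    if (any(bad))
      stop(sprintf("non-positive %s for patient(s): %s", col,
                   paste(cohort$patient_id[bad], collapse = ", ")),
           call. = FALSE)
  }
  bad_age <- !is.na(cohort$age) & cohort$age <= 0
  if (any(bad_age))
    stop("non-positive age for patient(s): ",
         paste(cohort$patient_id[bad_age], collapse = ", "), call. = FALSE)
  bad_tfd <- !is.na(cohort$time_from_met_dx) & cohort$time_from_met_dx < 0
  if (any(bad_tfd))
    stop("negative time_from_met_dx for patient(s): ",
         paste(cohort$patient_id[bad_tfd], collapse = ", "), call. = FALSE)
  for (col in c("pfs_event", "os_event")) {
    bad <- !is.na(cohort[[col]]) & !(cohort[[col]] %in% c(0, 1))
    if (any(bad))
      stop(sprintf("%s must be 0/1; offending patient(s): %s", col,
                   paste(cohort$patient_id[bad], collapse = ", ")),
           call. = FALSE)
  }
  ext_exp <- cohort$trial == "external" & cohort$arm == "experimental"
  if (any(ext_exp, na.rm = TRUE))
    stop("external-trial patients must be control-only: ",
         paste(cohort$patient_id[which(ext_exp)], collapse = ", "),
         call. = FALSE)
  bad_ord <- !is.na(cohort$pfs_time) & !is.na(cohort$os_time) &
    cohort$pfs_time > cohort$os_time + 1e-8
  if (any(bad_ord))
    stop("pfs_time exceeds os_time for patient(s): ",
         paste(cohort$patient_id[bad_ord], collapse = ", "), call. = FALSE)
  invisible(cohort)
}

#' Read a patient-level cohort from CSV
#'
#' Expects one row per patient with the canonical columns (see
#' [validate_cohort()]).  Missing categorical values are encoded as
#' `"unknown"` where the schema has such a level, missing numerics as empty
#' fields.  A `schema` mapping renames non-canonical headers on the way in.
#'
#' @param path CSV file path.
#' @param schema optional named character vector `c(canonical = "file_column")`
#'   used to rename columns before validation.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop("schema maps '", canon, "' to missing column '", src, "'",
             call. = FALSE)
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(.patient_required, names(df))
  if (length(missing_cols) > 0L)
    stop("input lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$ecog <- as.character(df$ecog)
  validate_cohort(df)
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort validated cohort data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format tumour-assessment table
#'
#' Long CSV with columns `patient_id`, `week`, `response` where `response`
#' is a RECIST v1.1 visit-level code (CR/PR/SD/PD/NE).  Weeks must be
#' strictly increasing within a patient.
#'
#' @param path CSV file path.
#' @return Data frame of assessments ordered by patient and week.
#' @export
read_assessments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "week", "response")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("assessment table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- !df$response %in% c("CR", "PR", "SD", "PD", "NE")
  if (any(bad))
    stop("invalid response code(s) at row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(df$response[bad]), collapse = ", "), call. = FALSE)
  if (any(df$week <= 0 | df$week != round(df$week)))
    stop("weeks must be positive integers", call. = FALSE)
  df <- df[order(df$patient_id, df$week), , drop = FALSE]
  dup <- stats::ave(df$week, df$patient_id,
                    FUN = function(w) duplicated(w))
  if (any(dup == 1))
    stop("duplicate assessment week within patient(s): ",
         paste(unique(df$patient_id[dup == 1]), collapse = ", "),
         call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Combine concurrent and external control patients into a hybrid cohort
#'
#' Union of the two control cohorts with trial provenance preserved in the
#' `trial` column.  Both inputs must be control-arm only; duplicate patient
#' ids across the two sources are an error.
#'
#' @param current_control concurrent (randomized) control patients.
#' @param external_control external-control patients from the historical
#'   trial (may have zero rows).
#' @return Hybrid-control cohort data frame of
#'   `nrow(current_control) + nrow(external_control)` rows.
#' @export
assemble_hybrid <- function(current_control, external_control) {
  for (df in list(current_control, external_control)) {
    if (nrow(df) > 0 && any(df$arm != "control"))
      stop("hybrid control must be built from control-arm patients only",
           call. = FALSE)
  }
  shared <- intersect(names(current_control), names(external_control))
  hybrid <- rbind(current_control[, shared, drop = FALSE],
                  external_control[, shared, drop = FALSE])
  if (anyDuplicated(hybrid$patient_id))
    stop("duplicate patient_id across control sources: ",
         paste(unique(hybrid$patient_id[duplicated(hybrid$patient_id)]),
               collapse = ", "), call. = FALSE)
  rownames(hybrid) <- NULL
  hybrid
}

#' Truncate external-control survival times at the current trial's maximum
#'
#' External-control follow-up typically extends past the small concurrent
#' trial's; times beyond the current trial's maximum observed time for the
#' endpoint are administratively censored at that maximum so both sources
#' share a common support.
#'
#' @param external external-control cohort.
#' @param current current-trial cohort (both arms).
#' @param endpoint `"pfs"` or `"os"`.
#' @return The external cohort with `<endpoint>_time` capped and
#'   `<endpoint>_event` set to 0 for capped patients.
#' @export
truncate_survival <- function(external, current, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  if (nrow(external) == 0L || nrow(current) == 0L)
    stop("both cohorts must be non-empty", call. = FALSE)
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  cap <- max(current[[tcol]], na.rm = TRUE)
  over <- !is.na(external[[tcol]]) & external[[tcol]] > cap
  external[[tcol]][over] <- cap
  external[[ecol]][over] <- 0
  external
}
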