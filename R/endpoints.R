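# Endpoint harmonization: 12-week disease control derived from visit-level
# RECIST codes under two different assessment schedules.
#
# The current trial assesses every 6 weeks, so disease control (CR/PR at any
# time, or stable disease sustained to >= 12 weeks) is read off directly.
# The historical trial assesses every 8 weeks, so 12-week status must be
# inferred from the week-8 and week-16 visits: PD at week 8 implies PD at 12
# weeks; SD at both 8 and 16 implies SD at 12 weeks; anything else is
# unknown.  CR/PR at any time counts as disease control under both
# schedules.

#' Derive the 12-week disease-control outcome for one patient
#'
#' @param weeks integer vector of assessment weeks (strictly increasing).
#' @param responses character vector of RECIST codes (CR/PR/SD/PD/NE), same
#'   length as `weeks`.
#' @param trial `"current"` (6-weekly schedule, direct rule) or
#'   `"external"` (8-weekly schedule, week-8/16 inference rule).
#' @param empty_series outcome assigned when a patient has no post-baseline
#'   assessment: the default (`"conservative"`) scores such patients as
#'   `no_disease_control` in the current trial (responder-type endpoint) and
#'   `unknown` in the external trial; `"unknown"` scores both as unknown.
#' @return List with `dcr12` (one of `disease_control`,
#'   `no_disease_control`, `unknown`) and `basis`, a short provenance string
#'   such as `"PD@8"` or `"SD@8&16"`.
#' @export
derive_dcr12 <- function(weeks, responses, trial = c("current", "external"),
                         empty_series = c("conservative", "unknown")) {
  trial <- match.arg(trial)
  empty_series <- match.arg(empty_series)
  stopifnot(length(weeks) == length(responses))
  if (length(weeks) > 1 && any(diff(weeks) <= 0))
    stop("assessment weeks must be strictly increasing", call. = FALSE)
  bad <- !responses %in% c("CR", "PR", "SD", "PD", "NE")
  if (any(bad))
    stop("invalid response code(s): ",
         paste(unique(responses[bad]), collapse = ", "), call. = FALSE)

  if (length(weeks) == 0L) {
    dcr <- if (empty_series == "unknown" || trial == "external")
      "unknown" else "no_disease_control"
    return(list(dcr12 = dcr, basis = "no_postbaseline_assessment"))
  }

  if (any(responses %in% c("CR", "PR"))) {
    w <- weeks[match(TRUE, responses %in% c("CR", "PR"))]
    return(list(dcr12 = "disease_control",
                basis = sprintf("response_any_time@%d", w)))
  }

  if (trial == "external") {
    r8 <- responses[match(8L, weeks)]
    r16 <- responses[match(16L, weeks)]
    if (!is.na(r8) && r8 == "PD")
      return(list(dcr12 = "no_disease_control", basis = "PD@8"))
    if (!is.na(r8) && r8 == "SD" && !is.na(r16) && r16 == "SD")
      return(list(dcr12 = "disease_control", basis = "SD@8&16"))
    return(list(dcr12 = "unknown", basis = "indeterminate_8_16"))
  }

  # current trial: SD sustained to >= 12 weeks, NE visits skipped when
  # scanning; PD before week 12 breaks the scan
  informative <- responses != "NE"
  w <- weeks[informative]
  r <- responses[informative]
  if (length(w) == 0L)
    return(list(dcr12 = "no_disease_control", basis = "all_NE"))
  first_pd <- match("PD", r)
  sd_late <- which(r == "SD" & w >= 12)
  for (i in sd_late) {
    if (is.na(first_pd) || first_pd > i)
      return(list(dcr12 = "disease_control",
                  basis = sprintf("SD_sustained@%d", w[i])))
  }
  basis <- if (!is.na(first_pd)) sprintf("PD@%d", w[first_pd])
           else "SD_not_sustained_12"
  list(dcr12 = "no_disease_control", basis = basis)
}

#' Derive 12-week disease control for a whole cohort
#'
#' Applies [derive_dcr12()] per patient to a long-format assessment table.
#' Patients present in `cohort` but absent from the assessment table are
#' scored via the empty-series rule.
#'
#' @param cohort validated cohort data frame (supplies patient ids and the
#'   per-patient trial label).
#' @param assessments long data frame (`patient_id`, `week`, `response`).
#' @param empty_series see [derive_dcr12()].
#' @return Data frame with `patient_id`, `dcr12`, `basis`.
#' @export
derive_dcr_cohort <- function(cohort, assessments,
                              empty_series = c("conservative", "unknown")) {
  empty_series <- match.arg(empty_series)
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    a <- assessments[assessments$patient_id == pid, , drop = FALSE]
    a <- a[order(a$week), , drop = FALSE]
    res <- derive_dcr12(a$week, a$response, trial = cohort$trial[i],
                        empty_series = empty_series)
    data.frame(patient_id = pid, dcr12 = res$dcr12, basis = res$basis,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
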