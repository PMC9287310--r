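# Declarative eligibility filtering with step-by-step attrition reporting,
# the standard way an external-control cohort is carved out of a completed
# trial's control arm.

#' Construct an eligibility rule
#'
#' A rule is a declarative predicate over cohort columns: `field op value`.
#' Records for which the field is missing are "not assessable" and are kept
#' or dropped according to the `na_action` passed to [apply_eligibility()].
#'
#' @param name short step label (appears in the attrition report).
#' @param field cohort column the predicate reads.
#' @param op one of `"eq"`, `"ne"`, `"ge"`, `"le"`, `"in"`.
#' @param value comparison value (a vector for `"in"`).
#' @param rationale optional free-text justification.
#' @return An `eligibility_rule` object.
#' @export
eligibility_rule <- function(name, field, op, value, rationale = "") {
  op <- match.arg(op, c("eq", "ne", "ge", "le", "in"))
  structure(list(name = name, field = field, op = op, value = value,
                 rationale = rationale),
            class = "eligibility_rule")
}

#' Read eligibility rules from a YAML file
#'
#' The file is a YAML list of `{name, field, op, value}` mappings (plus an
#' optional `rationale`), mirroring the attrition steps of a trial's
#' inclusion/exclusion flow chart.
#'
#' @param path YAML file path.
#' @return List of [eligibility_rule()] objects.
#' @export
read_eligibility_rules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    need <- c("name", "field", "op", "value")
    if (!all(need %in% names(r)))
      stop("eligibility rule needs fields ", paste(need, collapse = ", "),
           call. = FALSE)
    eligibility_rule(r$name, r$field, r$op, r$value,
                     if (is.null(r$rationale)) "" else r$rationale)
  })
}

#' Default eligibility configuration shipped with the package
#'
#' Encodes the usual third-line refractory selection steps (treatment-line
#' setting, required prior chemotherapy exposure, biomarker exclusions) as
#' placeholders over the synthetic generator's eligibility fields.
#'
#' @return List of eligibility rules.
#' @export
default_eligibility_rules <- function() {
  read_eligibility_rules(
    system.file("extdata", "eligibility_default.yaml",
                package = "hybridctrl", mustWork = TRUE))
}

.rule_keep <- function(rule, cohort, na_action) {
  if (!rule$field %in% names(cohort))
    stop("eligibility rule '", rule$name, "' references unknown field '",
         rule$field, "'", call. = FALSE)
  x <- cohort[[rule$field]]
  keep <- switch(rule$op,
    eq = x == rule$value,
    ne = x != rule$value,
    ge = x >= rule$value,
    le = x <= rule$value,
    `in` = x %in% rule$value)
  keep[is.na(keep)] <- identical(na_action, "keep")
  keep
}

#' Apply eligibility rules sequentially with an attrition report
#'
#' Each rule removes the records failing its predicate; the report records
#' one step per rule with before/excluded/after counts, mirroring a trial
#' attrition (CONSORT-style) diagram.  Counts always telescope:
#' `n_before - n_excluded = n_after`, and the next step's `n_before` equals
#' the previous step's `n_after`.
#'
#' @param cohort cohort data frame.
#' @param rules list of [eligibility_rule()] objects (possibly empty, in
#'   which case the cohort passes through and the report has zero rows).
#' @param na_action `"drop"` (default) or `"keep"` for records where a
#'   rule's field is missing.
#' @return List with `cohort` (filtered) and `attrition` (data frame of
#'   class `attrition_report`).
#' @export
apply_eligibility <- function(cohort, rules, na_action = c("drop", "keep")) {
  na_action <- match.arg(na_action)
  steps <- data.frame(step = integer(0), rule = character(0),
                      n_before = integer(0), n_excluded = integer(0),
                      n_after = integer(0), stringsAsFactors = FALSE)
  out <- cohort
  for (i in seq_along(rules)) {
    rule <- rules[[i]]
    keep <- .rule_keep(rule, out, na_action)
    steps <- rbind(steps, data.frame(
      step = i, rule = rule$name, n_before = nrow(out),
      n_excluded = sum(!keep), n_after = sum(keep),
      stringsAsFactors = FALSE))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(steps) <- c("attrition_report", "data.frame")
  list(cohort = out, attrition = steps)
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("Cohort attrition (", nrow(x), " step",
      if (nrow(x) != 1) "s", "):\n", sep = "")
  if (nrow(x) > 0) print.data.frame(x, row.names = FALSE)
  final <- if (nrow(x) > 0) x$n_after[nrow(x)] else NA_integer_
  cat("Final cohort size:", final, "\n")
  invisible(x)
}

#' Write an attrition report to CSV
#'
#' @param attrition an `attrition_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_attrition <- function(attrition, path) {
  utils::write.csv(as.data.frame(attrition), path, row.names = FALSE)
  invisible(path)
}
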