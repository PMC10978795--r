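#' Spontaneous-report sets
#'
#' A `report_set` is the package's tidy relational container for a batch of
#' spontaneous adverse-event reports. It mirrors the FAERS quarterly table
#' layout: one row per report version in `$cases`, and child tables for drug
#' mentions, reaction preferred terms (PTs), and outcome codes, all keyed by
#' `record_id` (the raw record identifier; in FAERS terms, the primaryid).
#' A single case (`case_id`) may be present in several versions until
#' [deduplicate()] is applied.
#'
#' @param cases Tibble with columns `record_id`, `case_id`, `version_key`
#'   (integer report version used for deduplication), `country` (code or
#'   `NA`), `therapy_start` and `event_date` (`Date` or `NA`).
#' @param drugs Tibble with columns `record_id`, `drug`, `role`; `role` is one
#'   of `"PS"` (primary suspect), `"SS"`, `"C"`, `"I"`.
#' @param events Tibble with columns `record_id`, `pt`; one row per reaction,
#'   each PT at most once per record.
#' @param outcomes Tibble with columns `record_id`, `outcome`; codes from
#'   `DE, LT, HO, DS, CA, RI, OT`.
#' @param provenance Optional list describing where the set came from (a
#'   [sim_config()] or ingestion file paths).
#'
#' @return An object of class `report_set`.
#' @examples
#' rs <- report_set(
#'   cases = tibble::tibble(
#'     record_id = "1001-1", case_id = "1001", version_key = 1L,
#'     country = "US", therapy_start = as.Date("2021-01-01"),
#'     event_date = as.Date("2021-01-15")
#'   ),
#'   drugs = tibble::tibble(record_id = "1001-1", drug = "XCOPRI", role = "PS"),
#'   events = tibble::tibble(record_id = "1001-1", pt = "Somnolence"),
#'   outcomes = tibble::tibble(record_id = "1001-1", outcome = "HO")
#' )
#' n_reports(rs)
#' @export
report_set <- function(cases, drugs, events, outcomes, provenance = NULL) {
  out <- new_report_set(
    cases = tibble::as_tibble(cases),
    drugs = tibble::as_tibble(drugs),
    events = tibble::as_tibble(events),
    outcomes = tibble::as_tibble(outcomes),
    provenance = provenance
  )
  validate_report_set(out)
}

new_report_set <- function(cases, drugs, events, outcomes, provenance = NULL) {
  structure(
    list(cases = cases, drugs = drugs, events = events, outcomes = outcomes,
         provenance = provenance),
    class = "report_set"
  )
}

drug_roles <- c("PS", "SS", "C", "I")
outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

validate_report_set <- function(x) {
  need <- list(
    cases = c("record_id", "case_id", "version_key", "country",
              "therapy_start", "event_date"),
    drugs = c("record_id", "drug", "role"),
    events = c("record_id", "pt"),
    outcomes = c("record_id", "outcome")
  )
  for (tab in names(need)) {
    missing <- setdiff(need[[tab]], names(x[[tab]]))
    if (length(missing) > 0) {
      stop(sprintf("report_set$%s is missing column(s): %s",
                   tab, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  if (anyDuplicated(x$cases$record_id)) {
    stop("report_set: record_id values must be unique", call. = FALSE)
  }
  if (nrow(x$events) > 0 &&
      (any(is.na(x$events$pt)) || any(!nzchar(x$events$pt)))) {
    stop("report_set: every event PT must be a non-empty string", call. = FALSE)
  }
  if (nrow(x$drugs) > 0 && !all(x$drugs$role %in% drug_roles)) {
    stop(sprintf("report_set: drug roles must be one of {%s}",
                 paste(drug_roles, collapse = ", ")), call. = FALSE)
  }
  if (nrow(x$outcomes) > 0 && !all(x$outcomes$outcome %in% outcome_codes)) {
    stop(sprintf("report_set: outcome codes must be one of {%s}",
                 paste(outcome_codes, collapse = ", ")), call. = FALSE)
  }
  orphan <- function(tab) setdiff(unique(tab$record_id), x$cases$record_id)
  for (tab in c("drugs", "events", "outcomes")) {
    bad <- orphan(x[[tab]])
    if (length(bad) > 0) {
      stop(sprintf("report_set$%s refers to unknown record_id(s): %s",
                   tab, paste(utils::head(bad, 3), collapse = ", ")),
           call. = FALSE)
    }
  }
  x
}

#' Number of reports in a report set
#'
#' @param x A [report_set()].
#' @return Integer count of report records (report versions before
#'   deduplication, unique cases after).
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "report_set"))
  nrow(x$cases)
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf(
    "<report_set> %d report record(s), %d case(s)\n",
    nrow(x$cases), dplyr::n_distinct(x$cases$case_id)
  ))
  cat(sprintf("  drug mentions: %d | reactions: %d | outcomes: %d\n",
              nrow(x$drugs), nrow(x$events), nrow(x$outcomes)))
  if (!is.null(x$provenance$kind)) {
    cat(sprintf("  provenance: %s\n", x$provenance$kind))
  }
  invisible(x)
}

# Restrict every table of a report_set to the given record ids,
# preserving case-table row order.
filter_records <- function(x, record_ids) {
  new_report_set(
    cases = dplyr::filter(x$cases, .data$record_id %in% record_ids),
    drugs = dplyr::filter(x$drugs, .data$record_id %in% record_ids),
    events = dplyr::filter(x$events, .data$record_id %in% record_ids),
    outcomes = dplyr::filter(x$outcomes, .data$record_id %in% record_ids),
    provenance = x$provenance
  )
}
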