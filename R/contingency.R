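#' 2x2 contingency table for one drug-event pair
#'
#' The fourfold table underlying every disproportionality statistic:
#' `a` focal-drug reports with the target event, `b` focal-drug reports
#' without it, `c` non-focal reports with it, `d` non-focal reports without
#' it, `n = a + b + c + d`.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return An object of class `contingency_table`.
#' @examples
#' contingency_table(20, 80, 100, 9800)
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency_table: all cells must be non-negative counts",
         call. = FALSE)
  }
  n <- a + b + c + d
  if (n < 1) {
    stop("contingency_table: table must contain at least one report",
         call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d, n = n),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%g b=%g c=%g d=%g (N=%g)\n",
              x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

# Accepts a contingency_table or a data frame with columns a, b, c, d and
# returns aligned numeric cell vectors (vectorised over data-frame rows).
as_cells <- function(table) {
  # doubles throughout: cell products like (a+b)(c+d)(a+c)(b+d) overflow
  # 32-bit integers at realistic database sizes
  if (inherits(table, "contingency_table")) {
    return(list(a = as.numeric(table$a), b = as.numeric(table$b),
                c = as.numeric(table$c), d = as.numeric(table$d)))
  }
  if (is.data.frame(table)) {
    missing <- setdiff(c("a", "b", "c", "d"), names(table))
    if (length(missing) > 0) {
      stop(sprintf("table is missing cell column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    return(list(a = as.numeric(table$a), b = as.numeric(table$b),
                c = as.numeric(table$c), d = as.numeric(table$d)))
  }
  stop("table must be a contingency_table or a data frame with a,b,c,d",
       call. = FALSE)
}

#' Build the 2x2 table for one preferred term
#'
#' Counts are per report: a report contributes at most once to the focal-drug
#' row (regardless of how many matching mentions it carries) and at most once
#' to the event column (regardless of repeated PT rows), so the four cells
#' always sum to the number of reports. The set should be deduplicated first,
#' otherwise case versions are counted as distinct reports.
#'
#' @param reports A deduplicated [report_set()].
#' @param drug_names Focal drug query names, as in [select_drug_reports()].
#' @param pt Target preferred term (exact match).
#' @param role Drug role defining the focal row (default `"PS"`).
#' @return A [contingency_table()].
#' @export
build_table <- function(reports, drug_names = c("XCOPRI", "CENOBAMATE"),
                        pt, role = "PS") {
  stopifnot(inherits(reports, "report_set"))
  if (nrow(reports$cases) == 0) {
    stop("build_table: no reports", call. = FALSE)
  }
  focal_ids <- matching_record_ids(reports, drug_names, role)
  event_ids <- unique(reports$events$record_id[reports$events$pt == pt])
  all_ids <- reports$cases$record_id
  is_focal <- all_ids %in% focal_ids
  has_event <- all_ids %in% event_ids
  contingency_table(
    a = sum(is_focal & has_event),
    b = sum(is_focal & !has_event),
    c = sum(!is_focal & has_event),
    d = sum(!is_focal & !has_event)
  )
}

#' Build 2x2 tables for every PT co-reported with the focal drug
#'
#' One table per distinct PT observed in at least one focal-drug report
#' (`a > 0`); PTs never co-reported with the focal drug are omitted since
#' they cannot generate a drug signal. The focal-row margin `a + b` is the
#' same for every PT.
#'
#' @inheritParams build_table
#' @return Tibble with columns `pt, a, b, c, d, n`, sorted by descending `a`
#'   then PT name.
#' @export
build_all_tables <- function(reports, drug_names = c("XCOPRI", "CENOBAMATE"),
                             role = "PS") {
  stopifnot(inherits(reports, "report_set"))
  if (nrow(reports$cases) == 0) {
    stop("build_all_tables: no reports", call. = FALSE)
  }
  n_total <- nrow(reports$cases)
  focal_ids <- matching_record_ids(reports, drug_names, role)
  n_focal <- length(focal_ids)
  ev <- dplyr::distinct(reports$events, .data$record_id, .data$pt)
  counts <- ev |>
    dplyr::mutate(focal = .data$record_id %in% focal_ids) |>
    dplyr::summarise(
      a = sum(.data$focal), with_pt = dplyr::n(), .by = "pt"
    ) |>
    dplyr::filter(.data$a > 0) |>
    dplyr::mutate(
      b = n_focal - .data$a,
      c = .data$with_pt - .data$a,
      d = n_total - n_focal - .data$c,
      n = n_total
    ) |>
    dplyr::select("pt", "a", "b", "c", "d", "n") |>
    dplyr::arrange(dplyr::desc(.data$a), .data$pt)
  counts
}

#' Read a PT-to-SOC mapping file
#'
#' A MedDRA-style map assigning each preferred term to exactly one system
#' organ class (the primary-SOC convention, so SOC rollups never double
#' count). CSV with header `pt,soc,soc_code`; `soc_code` may be empty.
#' MedDRA itself is licensed and not distributed here — real analyses must
#' supply their own map. A small bundled toy map covering the default
#' synthetic PTs is available via [toy_meddra_map()].
#'
#' @param path CSV file path.
#' @return Tibble with columns `pt, soc, soc_code`, one row per PT.
#' @export
read_meddra_map <- function(path) {
  map <- readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(c("pt", "soc"), names(map))
  if (length(missing) > 0) {
    stop(sprintf("read_meddra_map: '%s' is missing column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (!"soc_code" %in% names(map)) map$soc_code <- NA_character_
  if (anyDuplicated(map$pt)) {
    stop("read_meddra_map: each PT must map to exactly one SOC",
         call. = FALSE)
  }
  dplyr::select(map, "pt", "soc", "soc_code")
}

#' Bundled toy PT-to-SOC map
#'
#' Covers the default synthetic background PTs plus the filler PT; intended
#' for examples and tests, not for real MedDRA coding.
#'
#' @return Tibble with columns `pt, soc, soc_code`.
#' @export
toy_meddra_map <- function() {
  read_meddra_map(
    system.file("extdata", "meddra_toy_map.csv", package = "pvsignal",
                mustWork = TRUE)
  )
}

#' Roll PT-level case counts up to system organ classes
#'
#' Sums per-PT case counts within each SOC under the primary-SOC convention,
#' so the SOC totals conserve the PT totals. PTs absent from the map are
#' collected under `"UNMAPPED"` with a warning.
#'
#' @param pt_counts Data frame with columns `pt` and `count` (e.g. the
#'   `a` cells of strong-signal PTs, renamed).
#' @param map A PT-to-SOC map as returned by [read_meddra_map()].
#' @return Tibble with columns `soc, soc_code, count`, sorted by descending
#'   count then SOC name.
#' @export
aggregate_soc <- function(pt_counts, map = toy_meddra_map()) {
  stopifnot(is.data.frame(pt_counts))
  if (!all(c("pt", "count") %in% names(pt_counts))) {
    stop("aggregate_soc: pt_counts needs columns 'pt' and 'count'",
         call. = FALSE)
  }
  if (nrow(pt_counts) == 0) {
    return(tibble::tibble(soc = character(), soc_code = character(),
                          count = numeric()))
  }
  joined <- dplyr::left_join(pt_counts, map, by = "pt")
  unmapped <- is.na(joined$soc)
  if (any(unmapped)) {
    warning(sprintf("aggregate_soc: %d PT(s) not in map, collected under UNMAPPED: %s",
                    sum(unmapped),
                    paste(utils::head(joined$pt[unmapped], 5), collapse = ", ")),
            call. = FALSE)
    joined$soc[unmapped] <- "UNMAPPED"
  }
  joined |>
    dplyr::summarise(
      soc_code = dplyr::first(.data$soc_code),
      count = sum(.data$count),
      .by = "soc"
    ) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$soc) |>
    dplyr::select("soc", "soc_code", "count")
}
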