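#' Read a quarter of FAERS-dialect ASCII tables
#'
#' Parses the five `$`-delimited quarterly tables (DEMO, DRUG, REAC, OUTC,
#' THER) into a [report_set()]. Records are joined across tables on the raw
#' record identifier (`primaryid`); rows in a child table whose record id does
#' not appear in DEMO (orphans, which occur in real quarterly files) are
#' dropped with a warning. Dates are `YYYYMMDD` integers; unparseable or
#' empty dates become missing, never an error. Therapy start is taken as the
#' earliest THER start date per record.
#'
#' @param paths Either a directory containing the five files, or a character
#'   vector of file paths. Tables are recognised by the base file name
#'   containing `demo`, `drug`, `reac`, `outc` or `ther` (case-insensitive).
#'   OUTC and THER files are optional; DEMO, DRUG and REAC are required.
#' @return A [report_set()]; header-only files yield an empty set.
#' @examples
#' dir <- tempfile()
#' rs <- generate_reports(sim_config(n_reports = 50, seed = 3))
#' write_faers_dialect(rs, dir)
#' read_quarter(dir)
#' @export
read_quarter <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, full.names = TRUE)
  }
  paths <- paths[file.exists(paths)]
  find_table <- function(key) {
    hit <- grep(key, tolower(basename(paths)))
    if (length(hit) == 0) return(NA_character_)
    paths[hit[1]]
  }
  files <- vapply(c("demo", "drug", "reac", "outc", "ther"), find_table, "")
  for (req in c("demo", "drug", "reac")) {
    if (is.na(files[[req]])) {
      stop(sprintf("read_quarter: no %s table found among supplied paths",
                   toupper(req)), call. = FALSE)
    }
  }

  demo <- read_faers_table(files[["demo"]],
                           c("primaryid", "caseid", "caseversion"))
  drug <- read_faers_table(files[["drug"]],
                           c("primaryid", "role_cod", "drugname"))
  reac <- read_faers_table(files[["reac"]], c("primaryid", "pt"))
  outc <- if (!is.na(files[["outc"]])) {
    read_faers_table(files[["outc"]], c("primaryid", "outc_cod"))
  }
  ther <- if (!is.na(files[["ther"]])) {
    read_faers_table(files[["ther"]], c("primaryid", "start_dt"))
  }

  cases <- tibble::tibble(
    record_id = demo$primaryid,
    case_id = demo$caseid,
    version_key = parse_int(demo$caseversion),
    country = if ("occr_country" %in% names(demo)) {
      dplyr::na_if(demo$occr_country, "")
    } else {
      rep(NA_character_, nrow(demo))
    },
    therapy_start = as.Date(rep(NA, nrow(demo))),
    event_date = if ("event_dt" %in% names(demo)) {
      parse_faers_date(demo$event_dt)
    } else {
      as.Date(rep(NA, nrow(demo)))
    }
  )
  if (!is.null(ther) && nrow(ther) > 0) {
    starts <- ther |>
      dplyr::mutate(start = parse_faers_date(.data$start_dt)) |>
      dplyr::filter(!is.na(.data$start)) |>
      dplyr::summarise(start = min(.data$start), .by = "primaryid")
    cases <- cases |>
      dplyr::left_join(starts, by = c(record_id = "primaryid")) |>
      dplyr::mutate(therapy_start = .data$start) |>
      dplyr::select(-"start")
  }

  drop_orphans <- function(tab, name) {
    if (is.null(tab) || nrow(tab) == 0) return(tab)
    orphan <- !tab$primaryid %in% cases$record_id
    if (any(orphan)) {
      warning(sprintf(
        "read_quarter: dropping %d %s row(s) with no matching DEMO case",
        sum(orphan), name
      ), call. = FALSE)
    }
    tab[!orphan, , drop = FALSE]
  }
  drug <- drop_orphans(drug, "DRUG")
  reac <- drop_orphans(reac, "REAC")
  outc <- drop_orphans(outc, "OUTC")

  drugs <- tibble::tibble(
    record_id = drug$primaryid,
    role = drug$role_cod,
    drug = drug$drugname
  )[, c("record_id", "drug", "role")]
  events <- tibble::tibble(record_id = reac$primaryid, pt = reac$pt) |>
    dplyr::distinct()
  outcomes <- if (is.null(outc)) {
    tibble::tibble(record_id = character(), outcome = character())
  } else {
    tibble::tibble(record_id = outc$primaryid, outcome = outc$outc_cod)
  }

  report_set(cases, drugs, events, outcomes,
             provenance = list(kind = "faers_quarter",
                               files = unname(files[!is.na(files)])))
}

read_faers_table <- function(path, required) {
  tab <- readr::read_delim(
    path, delim = "$", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop(sprintf("read_quarter: file '%s' is missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  tab
}

parse_int <- function(x) {
  out <- suppressWarnings(as.integer(x))
  out[is.na(out)] <- 1L  # absent version defaults to the first
  out
}

parse_faers_date <- function(x) {
  x <- trimws(x)
  x[!grepl("^[0-9]{8}$", x)] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

#' Deduplicate case reports
#'
#' Spontaneous-report databases carry multiple versions of the same case;
#' keeping several would inflate disproportionality cells. For each
#' `case_id`, the record with the largest `version_key` is retained (the
#' standard latest-version convention); ties are broken by the
#' lexicographically larger raw `record_id`. The operation is idempotent.
#'
#' @param reports A [report_set()].
#' @return A [report_set()] with exactly one record per `case_id`.
#' @export
deduplicate <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  keep <- reports$cases |>
    dplyr::arrange(
      .data$case_id, dplyr::desc(.data$version_key), dplyr::desc(.data$record_id)
    ) |>
    dplyr::distinct(.data$case_id, .keep_all = TRUE)
  filter_records(reports, keep$record_id)
}

normalise_drug_name <- function(x) toupper(trimws(x))

#' Select reports mentioning a focal drug in a given role
#'
#' Keeps reports carrying at least one drug mention whose name matches any of
#' the query names — case-insensitively, after trimming surrounding
#' whitespace — with the required role code. Matching is exact by default;
#' set `substring = TRUE` to match the query as a substring of the reported
#' drug name (useful for verbatim names with salt suffixes).
#'
#' @param reports A [report_set()].
#' @param drug_names Character vector of query names; defaults to the focal
#'   drug's trade and generic names.
#' @param role Required drug role code (default `"PS"`, primary suspect).
#' @param substring Match query names as substrings instead of exactly.
#' @return The filtered [report_set()].
#' @export
select_drug_reports <- function(reports,
                                drug_names = c("XCOPRI", "CENOBAMATE"),
                                role = "PS",
                                substring = FALSE) {
  stopifnot(inherits(reports, "report_set"))
  if (length(drug_names) == 0) {
    stop("select_drug_reports: drug_names must be non-empty", call. = FALSE)
  }
  keep <- matching_record_ids(reports, drug_names, role, substring)
  filter_records(reports, keep)
}

matching_record_ids <- function(reports, drug_names, role, substring = FALSE) {
  q <- normalise_drug_name(drug_names)
  d <- reports$drugs |> dplyr::filter(.data$role %in% .env$role)
  name <- normalise_drug_name(d$drug)
  hit <- if (substring) {
    Reduce(`|`, lapply(q, function(s) grepl(s, name, fixed = TRUE)))
  } else {
    name %in% q
  }
  if (nrow(d) == 0) character() else unique(d$record_id[hit])
}
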