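#' Descriptive summary of a report set
#'
#' Report counts overall, by reporter country and by outcome code, plus the
#' serious-outcome proportion. A report is serious when it carries at least
#' one outcome code in `serious_codes` (by default every FAERS outcome code:
#' death, life-threatening, hospitalisation, disability, congenital anomaly,
#' required intervention, other serious).
#'
#' @param reports A deduplicated [report_set()].
#' @param serious_codes Outcome codes that mark a report as serious.
#' @return An object of class `descriptive_summary`: a list with
#'   `n_reports`, `by_country` (tibble, descending), `by_outcome` (tibble),
#'   `n_serious`, `serious_fraction`, and `serious_pct` (percentage rounded
#'   to one decimal).
#' @examples
#' rs <- generate_reports(sim_config(n_reports = 300, seed = 2))
#' descriptive_summary(rs)
#' @export
descriptive_summary <- function(reports,
                                serious_codes = c("DE", "LT", "HO", "DS",
                                                  "CA", "RI", "OT")) {
  stopifnot(inherits(reports, "report_set"))
  n <- nrow(reports$cases)
  if (n == 0) {
    stop("descriptive_summary: empty report set", call. = FALSE)
  }
  by_country <- reports$cases |>
    dplyr::filter(!is.na(.data$country)) |>
    dplyr::count(.data$country, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$country)
  by_outcome <- reports$outcomes |>
    dplyr::distinct(.data$record_id, .data$outcome) |>
    dplyr::count(.data$outcome, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$outcome)
  serious_ids <- unique(
    reports$outcomes$record_id[reports$outcomes$outcome %in% serious_codes]
  )
  n_serious <- sum(reports$cases$record_id %in% serious_ids)
  structure(
    list(
      n_reports = n,
      by_country = by_country,
      by_outcome = by_outcome,
      n_serious = n_serious,
      serious_fraction = n_serious / n,
      serious_pct = round(100 * n_serious / n, 1)
    ),
    class = "descriptive_summary"
  )
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat(sprintf("<descriptive_summary> %d reports, %d serious (%.1f%%)\n",
              x$n_reports, x$n_serious, x$serious_pct))
  top <- utils::head(x$by_country, 3)
  if (nrow(top) > 0) {
    cat("  top countries:",
        paste(sprintf("%s=%d", top$country, top$n), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Onset-time distribution in monthly buckets
#'
#' Onset is `event_date - therapy_start` in days; bucket `k` covers the
#' half-open interval `[30(k-1), 30k)` days, so day 0 falls in bucket 1 and
#' day 30 opens bucket 2. Reports with a missing date or a negative onset
#' are excluded from the buckets and counted separately.
#'
#' @param reports A [report_set()].
#' @param bucket_days Bucket width in days (default 30, a nominal month).
#' @return Tibble with columns `bucket, days_min, days_max, n`, with
#'   attributes `n_with_dates`, `n_missing`, `n_negative`.
#' @export
onset_time_distribution <- function(reports, bucket_days = 30) {
  stopifnot(inherits(reports, "report_set"))
  if (bucket_days < 1) {
    stop("onset_time_distribution: bucket_days must be >= 1", call. = FALSE)
  }
  days <- as.numeric(reports$cases$event_date - reports$cases$therapy_start)
  n_missing <- sum(is.na(days))
  n_negative <- sum(days < 0, na.rm = TRUE)
  ok <- !is.na(days) & days >= 0
  bucket <- floor(days[ok] / bucket_days) + 1
  out <- if (length(bucket) == 0) {
    tibble::tibble(bucket = integer(), n = integer())
  } else {
    tibble::tibble(bucket = as.integer(bucket)) |>
      dplyr::count(.data$bucket, name = "n") |>
      dplyr::arrange(.data$bucket)
  }
  out <- out |>
    dplyr::mutate(
      days_min = (.data$bucket - 1) * bucket_days,
      days_max = .data$bucket * bucket_days - 1
    ) |>
    dplyr::select("bucket", "days_min", "days_max", "n")
  attr(out, "n_with_dates") <- sum(ok)
  attr(out, "n_missing") <- n_missing
  attr(out, "n_negative") <- n_negative
  out
}

#' Top strong-association signals
#'
#' The headline table of a disproportionality screen: strong-tier PTs (all
#' four algorithms positive) sorted by descending case count `a`, ties broken
#' by descending ROR then PT name, truncated to the top `n` rows.
#'
#' @param results Decision table from [evaluate_criteria()] (must contain
#'   `pt`, `a`, `ror`, `tier`).
#' @param n Maximum number of rows (default 30).
#' @param tier Which tier to tabulate (default `"strong"`).
#' @return Tibble of at most `n` rows.
#' @export
top_signals_table <- function(results, n = 30, tier = "strong") {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) {
    stop("top_signals_table: empty results", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("top_signals_table: n must be >= 1", call. = FALSE)
  }
  results |>
    dplyr::filter(.data$tier %in% .env$tier) |>
    dplyr::arrange(dplyr::desc(.data$a), dplyr::desc(.data$ror), .data$pt) |>
    utils::head(n)
}

#' Run the full signal-detection pipeline
#'
#' End-to-end composition: ingest (or simulate) -> deduplicate -> select
#' focal-drug reports -> per-PT 2x2 tables -> four disproportionality
#' statistics -> threshold decisions and consensus tiers -> SOC rollup of
#' strong signals -> onset-time distribution and descriptive summary.
#' Optionally writes every output table as CSV plus a machine-readable JSON
#' run log (parameters, seed and report counts at each stage); identical
#' inputs and configuration produce byte-identical outputs.
#'
#' @param quarter_dir Directory of FAERS-dialect files, or `NULL`.
#' @param sim A [sim_config()] used when `quarter_dir` is `NULL`.
#' @param reports A ready-made [report_set()] overriding both sources.
#' @param drug_names,role Focal-drug selection, as in [select_drug_reports()].
#' @param meddra_map PT-to-SOC map tibble (default [toy_meddra_map()]).
#' @param criteria A [signal_criteria()] object.
#' @param priors A [bcpnn_priors()] object.
#' @param correction Continuity correction for zero cells, see [ror()].
#' @param top_n Rows in the top-signal table.
#' @param out_dir Output directory for CSVs and the run log, or `NULL` to
#'   skip writing.
#' @return An object of class `pv_run`: list with `reports` (the selected
#'   focal set), `tables`, `signals` (metrics + decisions), `venn`, `soc`,
#'   `top`, `onset`, `summary`, and `log`.
#' @examples
#' run <- run_pipeline(sim = sim_config(n_reports = 2000, seed = 11))
#' run$venn
#' @export
run_pipeline <- function(quarter_dir = NULL, sim = NULL, reports = NULL,
                         drug_names = c("XCOPRI", "CENOBAMATE"), role = "PS",
                         meddra_map = toy_meddra_map(),
                         criteria = signal_criteria(),
                         priors = bcpnn_priors(),
                         correction = FALSE,
                         top_n = 30,
                         out_dir = NULL) {
  stage <- "ingest"
  result <- tryCatch({
    raw <- if (!is.null(reports)) {
      reports
    } else if (!is.null(quarter_dir)) {
      read_quarter(quarter_dir)
    } else if (!is.null(sim)) {
      generate_reports(sim)
    } else {
      stop("supply one of quarter_dir, sim or reports", call. = FALSE)
    }
    n_raw <- nrow(raw$cases)

    stage <- "deduplicate"
    dedup <- deduplicate(raw)

    stage <- "select"
    focal <- select_drug_reports(dedup, drug_names = drug_names, role = role)
    if (nrow(focal$cases) == 0) {
      stop(sprintf("no reports with %s as %s after deduplication",
                   paste(drug_names, collapse = "/"), role), call. = FALSE)
    }

    stage <- "contingency"
    tables <- build_all_tables(dedup, drug_names = drug_names, role = role)

    stage <- "statistics"
    signals <- signal_metrics(tables, priors = priors, correction = correction)

    stage <- "decisions"
    signals <- evaluate_criteria(signals, criteria = criteria)
    venn <- venn_counts(signals)

    stage <- "soc"
    strong <- dplyr::filter(signals, .data$tier == "strong")
    soc <- aggregate_soc(
      dplyr::transmute(strong, pt = .data$pt, count = .data$a),
      map = meddra_map
    )

    stage <- "reporting"
    top <- if (nrow(signals) > 0) {
      top_signals_table(signals, n = top_n)
    } else {
      signals
    }
    onset <- onset_time_distribution(focal)
    summary <- descriptive_summary(focal)

    log <- list(
      parameters = list(
        drug_names = drug_names, role = role,
        criteria = unclass(criteria), priors = unclass(priors),
        correction = correction, top_n = top_n,
        seed = if (!is.null(sim)) as.integer(sim$seed) else NULL,
        source = if (!is.null(reports)) "report_set"
                 else if (!is.null(quarter_dir)) quarter_dir
                 else "simulated"
      ),
      counts = list(
        raw_records = n_raw,
        deduplicated = nrow(dedup$cases),
        focal_reports = nrow(focal$cases),
        pts_tested = nrow(tables),
        positive_pts = sum(signals$tier != "none"),
        strong_pts = sum(signals$tier == "strong"),
        venn = as.list(venn)
      )
    )
    structure(
      list(reports = focal, tables = tables, signals = signals, venn = venn,
           soc = soc, top = top, onset = onset, summary = summary, log = log),
      class = "pv_run"
    )
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(out_dir)) {
    write_run(result, out_dir)
  }
  result
}

#' @export
print.pv_run <- function(x, ...) {
  cat(sprintf(
    "<pv_run> %d focal report(s), %d PT(s) tested, %d positive, %d strong\n",
    x$log$counts$focal_reports, x$log$counts$pts_tested,
    x$log$counts$positive_pts, x$log$counts$strong_pts
  ))
  invisible(x)
}

# Rounded presentation copy of the signal table: two decimals for statistics,
# full precision retained in the pv_run object.
format_signal_table <- function(signals) {
  num <- c("ror", "se_ln_ror", "ror_ci_low", "ror_ci_high", "prr", "chi2",
           "ic", "e_ic", "ic_sd", "ic025", "ebgm", "ebgm05", "ebgm95")
  dplyr::mutate(
    signals,
    dplyr::across(dplyr::any_of(num), \(x) round(x, 2))
  )
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(format_signal_table(run$signals), p("signals.csv"), na = "")
  readr::write_csv(format_signal_table(run$top), p("top_signals.csv"), na = "")
  readr::write_csv(run$tables, p("tables.csv"), na = "")
  readr::write_csv(run$soc, p("soc.csv"), na = "")
  readr::write_csv(run$onset, p("onset.csv"), na = "")
  readr::write_csv(run$summary$by_country, p("by_country.csv"), na = "")
  readr::write_csv(run$summary$by_outcome, p("by_outcome.csv"), na = "")
  log <- run$log
  log$summary <- list(
    n_reports = run$summary$n_reports,
    n_serious = run$summary$n_serious,
    serious_pct = run$summary$serious_pct
  )
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}
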