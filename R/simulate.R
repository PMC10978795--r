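#' Configure a synthetic spontaneous-reporting database
#'
#' Parameterises the generative model behind [generate_reports()]: a database
#' of `n_reports` spontaneous reports in which a focal drug appears as primary
#' suspect in a fraction of reports, every report carries one or more MedDRA
#' preferred terms (PTs) drawn per-PT from independent Bernoulli background
#' rates, and selected PTs have their reporting rate multiplied by a known
#' ratio in focal-drug reports (the injected signals that ground-truth tests
#' recover).
#'
#' Defaults emulate the reporting profile of a recently approved antiseizure
#' drug in a spontaneous-report database: about 30% of reports carry a serious
#' outcome, the large majority originate from the United States, and onset
#' times cluster in the first month of therapy (geometric onset-day
#' distribution with mean 30 days).
#'
#' @param n_reports Number of reports to generate (>= 1).
#' @param focal_drug Name the focal drug carries in its mentions.
#' @param focal_drug_fraction Probability in (0, 1) that a report lists the
#'   focal drug as primary suspect.
#' @param background_pts Named numeric vector: per-report probability of each
#'   PT among non-focal reports. Names must be unique non-empty PT strings.
#' @param injected_signals Named numeric vector of reporting-rate ratios
#'   (>= 0) applied to the background rate in focal-drug reports; every name
#'   must be a `background_pts` PT. PTs not listed keep ratio 1.
#' @param serious_fraction Probability in \[0, 1\] that a report carries a
#'   serious outcome code.
#' @param outcome_weights Named relative weights over outcome codes
#'   `DE, LT, HO, DS, OT` used for serious reports.
#' @param country_weights Named relative weights over reporter country codes.
#' @param onset_mean_days Mean of the geometric onset-day distribution
#'   (days from therapy start to event onset).
#' @param background_drugs Pool of non-focal drug names; guarantees the
#'   `b` and `d` cells of downstream 2x2 tables are populated.
#' @param concomitant_prob Probability that a report carries one additional
#'   concomitant drug from the background pool.
#' @param filler_pt PT assigned to a report whose Bernoulli draws produced no
#'   event (spontaneous reports always list at least one reaction). Kept
#'   outside `background_pts` so the analytic cell expectations of
#'   [expected_cells()] hold exactly for every background PT.
#' @param seed Integer seed; all randomness flows from this single seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_reports()], [expected_cells()], [write_faers_dialect()]
#' @examples
#' cfg <- sim_config(n_reports = 500, seed = 7)
#' cfg$focal_drug_fraction
#' @export
sim_config <- function(n_reports = 10000,
                       focal_drug = "XCOPRI",
                       focal_drug_fraction = 0.05,
                       background_pts = default_background_pts(),
                       injected_signals = c(
                         "Seizure" = 10, "Somnolence" = 10, "Dizziness" = 10,
                         "Balance disorder" = 10, "Diplopia" = 10
                       ),
                       serious_fraction = 0.304,
                       outcome_weights = c(DE = 36, LT = 22, HO = 315,
                                           DS = 22, OT = 375),
                       country_weights = c(US = 2378, GB = 29, OT = 128),
                       onset_mean_days = 30,
                       background_drugs = sprintf("BACKGROUND_DRUG_%02d", 1:20),
                       concomitant_prob = 0.3,
                       filler_pt = "Adverse event",
                       seed = 20200701) {
  cfg <- structure(
    list(
      n_reports = n_reports,
      focal_drug = focal_drug,
      focal_drug_fraction = focal_drug_fraction,
      background_pts = background_pts,
      injected_signals = injected_signals,
      serious_fraction = serious_fraction,
      outcome_weights = outcome_weights,
      country_weights = country_weights,
      onset_mean_days = onset_mean_days,
      background_drugs = background_drugs,
      concomitant_prob = concomitant_prob,
      filler_pt = filler_pt,
      seed = seed
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' Default background PT reporting rates
#'
#' Thirty PTs named after common antiseizure-drug adverse events, with
#' per-report background probabilities spanning roughly 0.1%-2% — the range
#' within which the downstream 2x2 cells of a 10,000-report database take
#' values comparable to published disproportionality tables.
#'
#' @return Named numeric vector of per-report event probabilities.
#' @export
default_background_pts <- function() {
  pts <- c(
    "Seizure", "Product dose omission issue", "Fatigue", "Somnolence",
    "Dizziness", "Fall", "Feeling abnormal", "Gait disturbance",
    "Wrong technique in product usage process", "Balance disorder",
    "Memory impairment", "Hypersomnia", "Product use issue", "Vision blurred",
    "Diplopia", "Lethargy", "Generalised tonic-clonic seizure",
    "Product availability issue", "Dysarthria", "Therapy interrupted",
    "Aura", "Disturbance in attention", "Feeling drunk", "Irritability",
    "Amnesia", "Speech disorder", "Anger", "Abnormal behaviour",
    "Partial seizures", "Headache"
  )
  rates <- round(exp(seq(log(0.02), log(0.001), length.out = length(pts))), 5)
  stats::setNames(rates, pts)
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("sim_config$%s: %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(cfg$n_reports) || length(cfg$n_reports) != 1 ||
      is.na(cfg$n_reports) || cfg$n_reports < 1 ||
      cfg$n_reports != floor(cfg$n_reports)) {
    fail("n_reports", "must be a single integer >= 1")
  }
  if (!is.character(cfg$focal_drug) || length(cfg$focal_drug) != 1 ||
      !nzchar(cfg$focal_drug)) {
    fail("focal_drug", "must be a non-empty string")
  }
  f <- cfg$focal_drug_fraction
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f <= 0 || f >= 1) {
    fail("focal_drug_fraction", "must be a probability strictly in (0, 1)")
  }
  bp <- cfg$background_pts
  if (!is.numeric(bp) || length(bp) < 1 || is.null(names(bp)) ||
      any(!nzchar(names(bp)))) {
    fail("background_pts", "must be a named numeric vector of PT rates")
  }
  if (anyDuplicated(names(bp))) {
    fail("background_pts", "PT names must be unique")
  }
  if (any(is.na(bp)) || any(bp < 0) || any(bp > 1)) {
    fail("background_pts", "rates must lie in [0, 1]")
  }
  sig <- cfg$injected_signals
  if (length(sig) > 0) {
    if (!is.numeric(sig) || is.null(names(sig))) {
      fail("injected_signals", "must be a named numeric vector of ratios")
    }
    if (any(is.na(sig)) || any(sig < 0)) {
      fail("injected_signals", "reporting ratios must be >= 0")
    }
    unknown <- setdiff(names(sig), names(bp))
    if (length(unknown) > 0) {
      fail("injected_signals",
           paste("every injected signal must name a background PT; unknown:",
                 paste(unknown, collapse = ", ")))
    }
  }
  s <- cfg$serious_fraction
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0 || s > 1) {
    fail("serious_fraction", "must be a probability in [0, 1]")
  }
  check_weights <- function(w, field, allowed = NULL) {
    if (!is.numeric(w) || length(w) < 1 || is.null(names(w)) ||
        any(is.na(w)) || any(w < 0) || sum(w) <= 0) {
      fail(field, "must be named non-negative weights with positive sum")
    }
    if (!is.null(allowed) && !all(names(w) %in% allowed)) {
      fail(field, sprintf("codes must be among {%s}",
                          paste(allowed, collapse = ", ")))
    }
  }
  check_weights(cfg$outcome_weights, "outcome_weights",
                c("DE", "LT", "HO", "DS", "OT"))
  check_weights(cfg$country_weights, "country_weights")
  if (!is.numeric(cfg$onset_mean_days) || length(cfg$onset_mean_days) != 1 ||
      is.na(cfg$onset_mean_days) || cfg$onset_mean_days <= 0) {
    fail("onset_mean_days", "must be a positive number of days")
  }
  if (!is.character(cfg$background_drugs) || length(cfg$background_drugs) < 1) {
    fail("background_drugs", "must supply at least one non-focal drug name")
  }
  p <- cfg$concomitant_prob
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    fail("concomitant_prob", "must be a probability in [0, 1]")
  }
  if (!is.character(cfg$filler_pt) || length(cfg$filler_pt) != 1 ||
      !nzchar(cfg$filler_pt) || cfg$filler_pt %in% names(bp)) {
    fail("filler_pt", "must be a non-empty PT name outside background_pts")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed) ||
      cfg$seed != floor(cfg$seed)) {
    fail("seed", "must be a single integer")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d reports | focal drug %s (PS fraction %.3f) | %d background PTs | %d injected signal(s) | seed %d\n",
    x$n_reports, x$focal_drug, x$focal_drug_fraction,
    length(x$background_pts), length(x$injected_signals), as.integer(x$seed)
  ))
  invisible(x)
}

# Per-PT event probability for focal-drug reports: background rate times the
# injected reporting ratio (1 when the PT carries no signal), capped at 1.
focal_pt_rates <- function(cfg) {
  rates <- cfg$background_pts
  ratio <- stats::setNames(rep(1, length(rates)), names(rates))
  ratio[names(cfg$injected_signals)] <- cfg$injected_signals
  pmin(rates * ratio, 1)  # named first argument keeps PT names
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws a [report_set()] from the generative model of a [sim_config()]:
#' focal-drug membership is Bernoulli(`focal_drug_fraction`); given membership,
#' each background PT is an independent Bernoulli with its (possibly
#' signal-multiplied, capped at 1) rate; a report whose draws produced no
#' event receives the filler PT, so every report carries at least one
#' reaction while the background-PT cell expectations of [expected_cells()]
#' remain exact. Focal reports carry exactly one focal-drug mention with role
#' `"PS"`; all reports draw their remaining drugs from the background pool.
#' Serious reports receive one outcome code; onset days are geometric with
#' mean `onset_mean_days` and therapy-start dates are uniform over a
#' three-year reporting window.
#'
#' The same configuration (including seed) always yields a bit-identical
#' report set.
#'
#' @param config A [sim_config()].
#' @return A [report_set()] whose `provenance` records the config.
#' @examples
#' rs <- generate_reports(sim_config(n_reports = 200, seed = 1))
#' rs
#' @export
generate_reports <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(as.integer(config$seed), generate_reports_impl(config))
}

generate_reports_impl <- function(cfg) {
  n <- cfg$n_reports
  case_id <- sprintf("%07d", seq_len(n))
  record_id <- paste0(case_id, "-1")

  focal <- stats::runif(n) < cfg$focal_drug_fraction
  bg <- cfg$background_pts
  fr <- focal_pt_rates(cfg)

  # Event draws: per-PT independent Bernoulli given drug status.
  ev <- vector("list", length(bg))
  for (j in seq_along(bg)) {
    p <- ifelse(focal, fr[j], bg[j])
    hit <- stats::runif(n) < p
    ev[[j]] <- which(hit)
  }
  events <- tibble::tibble(
    record_id = record_id[unlist(ev, use.names = FALSE)],
    pt = rep(names(bg), lengths(ev))
  )
  no_event <- setdiff(record_id, events$record_id)
  if (length(no_event) > 0) {
    events <- dplyr::bind_rows(
      events, tibble::tibble(record_id = no_event, pt = cfg$filler_pt)
    )
  }
  events <- dplyr::arrange(events, .data$record_id, .data$pt)

  # Drug mentions: focal reports get the focal drug as primary suspect,
  # non-focal reports a primary suspect from the background pool; either may
  # add one concomitant background drug.
  ps_drug <- ifelse(
    focal, cfg$focal_drug,
    sample(cfg$background_drugs, n, replace = TRUE)
  )
  conc <- stats::runif(n) < cfg$concomitant_prob
  conc_drug <- sample(cfg$background_drugs, n, replace = TRUE)
  drugs <- dplyr::bind_rows(
    tibble::tibble(record_id = record_id, drug = ps_drug, role = "PS"),
    tibble::tibble(record_id = record_id[conc], drug = conc_drug[conc],
                   role = "C")
  )
  drugs <- dplyr::arrange(drugs, .data$record_id, .data$role, .data$drug)

  serious <- stats::runif(n) < cfg$serious_fraction
  out_code <- sample(names(cfg$outcome_weights), n, replace = TRUE,
                     prob = cfg$outcome_weights)
  outcomes <- tibble::tibble(
    record_id = record_id[serious], outcome = out_code[serious]
  )

  country <- sample(names(cfg$country_weights), n, replace = TRUE,
                    prob = cfg$country_weights)
  window_start <- as.Date("2020-07-01")
  window_days <- as.integer(as.Date("2023-06-30") - window_start)
  therapy_start <- window_start +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L
  onset_days <- stats::rgeom(n, prob = 1 / (cfg$onset_mean_days + 1))
  event_date <- therapy_start + onset_days

  cases <- tibble::tibble(
    record_id = record_id, case_id = case_id, version_key = 1L,
    country = country, therapy_start = therapy_start, event_date = event_date
  )
  new_report_set(cases, drugs, events, outcomes,
                 provenance = list(kind = "simulated", config = cfg))
}

#' Analytic cell expectations under the generative model
#'
#' Closed-form expectations of the 2x2 contingency cells that
#' [build_table()] produces for one background PT of a synthetic database:
#' with `n` reports, focal fraction `f`, background rate `r` and reporting
#' ratio `rho` (1 if not injected),
#' `E[a] = n * f * min(1, r * rho)`, `E[b] = n * f * (1 - min(1, r * rho))`,
#' `E[c] = n * (1 - f) * r`, `E[d] = n * (1 - f) * (1 - r)`.
#' These match [generate_reports()] exactly because zero-event reports are
#' completed with a filler PT outside the background set rather than redrawn.
#'
#' @param config A [sim_config()].
#' @param pt A background PT name from `config$background_pts`.
#' @return Named numeric vector with components `a`, `b`, `c`, `d`.
#' @examples
#' cfg <- sim_config(n_reports = 10000, focal_drug_fraction = 0.01,
#'                   background_pts = c("Somnolence" = 0.012),
#'                   injected_signals = c("Somnolence" = 1))
#' expected_cells(cfg, "Somnolence") # E[a] = 1.2, E[c] = 118.8
#' @export
expected_cells <- function(config, pt) {
  config <- validate_sim_config(config)
  if (!pt %in% names(config$background_pts)) {
    stop(sprintf("expected_cells: unknown PT '%s' (not in background_pts)", pt),
         call. = FALSE)
  }
  n <- config$n_reports
  f <- config$focal_drug_fraction
  r <- unname(config$background_pts[pt])
  p_focal <- unname(focal_pt_rates(config)[pt])
  c(a = n * f * p_focal,
    b = n * f * (1 - p_focal),
    c = n * (1 - f) * r,
    d = n * (1 - f) * (1 - r))
}

#' Write a report set in the FAERS quarterly ASCII dialect
#'
#' Emits the five `$`-delimited tables (DEMO, DRUG, REAC, OUTC, THER) with
#' header rows, dates as `YYYYMMDD` integers and missing values as empty
#' fields, such that [read_quarter()] round-trips to an equivalent
#' [report_set()].
#'
#' @param reports A [report_set()].
#' @param directory Output directory (created if absent).
#' @return Named character vector of the five file paths
#'   (`DEMO`, `DRUG`, `REAC`, `OUTC`, `THER`), invisibly.
#' @export
write_faers_dialect <- function(reports, directory) {
  stopifnot(inherits(reports, "report_set"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop(sprintf("write_faers_dialect: cannot create directory '%s'",
                 directory), call. = FALSE)
  }
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y%m%d"))

  demo <- tibble::tibble(
    primaryid = reports$cases$record_id,
    caseid = reports$cases$case_id,
    caseversion = reports$cases$version_key,
    event_dt = fmt_date(reports$cases$event_date),
    occr_country = dplyr::coalesce(reports$cases$country, "")
  )
  drug <- reports$drugs |>
    dplyr::group_by(.data$record_id) |>
    dplyr::mutate(drug_seq = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      primaryid = .data$record_id,
      caseid = sub("-[0-9]+$", "", .data$record_id),
      drug_seq = .data$drug_seq,
      role_cod = .data$role,
      drugname = .data$drug
    )
  reac <- tibble::tibble(
    primaryid = reports$events$record_id,
    caseid = sub("-[0-9]+$", "", reports$events$record_id),
    pt = reports$events$pt
  )
  outc <- tibble::tibble(
    primaryid = reports$outcomes$record_id,
    caseid = sub("-[0-9]+$", "", reports$outcomes$record_id),
    outc_cod = reports$outcomes$outcome
  )
  ther <- reports$cases |>
    dplyr::filter(!is.na(.data$therapy_start)) |>
    dplyr::transmute(
      primaryid = .data$record_id,
      caseid = .data$case_id,
      dsg_drug_seq = 1L,
      start_dt = fmt_date(.data$therapy_start)
    )

  tables <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc,
                 THER = ther)
  paths <- stats::setNames(
    file.path(directory, paste0(names(tables), ".txt")), names(tables)
  )
  for (nm in names(tables)) {
    readr::write_delim(tables[[nm]], paths[[nm]], delim = "$", na = "")
  }
  invisible(paths)
}
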