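test_that("sim_config validation names the offending field", {
  expect_error(sim_config(n_reports = 0), "n_reports")
  expect_error(sim_config(focal_drug_fraction = 0), "focal_drug_fraction")
  expect_error(sim_config(focal_drug_fraction = 1.2), "focal_drug_fraction")
  expect_error(sim_config(background_pts = c(0.1, 0.2)), "background_pts")
  expect_error(
    sim_config(background_pts = c(Seizure = 0.1, Seizure = 0.2)),
    "background_pts"
  )
  expect_error(sim_config(background_pts = c(Seizure = 1.5)), "background_pts")
  expect_error(
    sim_config(injected_signals = c("Not a background PT" = 2)),
    "injected_signals"
  )
  expect_error(sim_config(injected_signals = c(Seizure = -1)),
               "injected_signals")
  expect_error(sim_config(serious_fraction = 2), "serious_fraction")
  expect_error(sim_config(outcome_weights = c(XX = 1)), "outcome_weights")
  expect_error(sim_config(onset_mean_days = 0), "onset_mean_days")
  expect_error(sim_config(filler_pt = "Seizure"), "filler_pt")
  expect_error(sim_config(seed = 1.5), "seed")
})

test_that("identical seed gives a bit-identical report set", {
  cfg <- sim_config(n_reports = 800, seed = 42)
  expect_identical(generate_reports(cfg), generate_reports(cfg))
  other <- generate_reports(sim_config(n_reports = 800, seed = 43))
  expect_false(identical(generate_reports(cfg)$events, other$events))
})

test_that("generated reports respect the configured structure", {
  cfg <- sim_config(n_reports = 1000, seed = 9)
  rs <- generate_reports(cfg)
  expect_s3_class(rs, "report_set")
  expect_equal(n_reports(rs), 1000)
  expect_false(anyDuplicated(rs$cases$record_id) > 0)
  # every report carries at least one reaction, each PT at most once
  expect_setequal(unique(rs$events$record_id), rs$cases$record_id)
  expect_equal(anyDuplicated(rs$events[, c("record_id", "pt")]), 0L)
  # focal reports carry exactly one primary-suspect focal-drug mention
  ps <- dplyr::filter(rs$drugs, role == "PS")
  expect_equal(nrow(ps), 1000)
  focal_ps <- dplyr::filter(ps, drug == cfg$focal_drug)
  expect_equal(anyDuplicated(focal_ps$record_id), 0L)
  # non-serious reports carry no outcome codes
  expect_lte(dplyr::n_distinct(rs$outcomes$record_id), 1000)
  expect_true(all(rs$outcomes$outcome %in% c("DE", "LT", "HO", "DS", "OT")))
  expect_true(all(rs$cases$event_date >= rs$cases$therapy_start))
})

test_that("expected_cells matches the documented closed form", {
  base <- function(ratio) {
    sim_config(
      n_reports = 10000, focal_drug_fraction = 0.01,
      background_pts = c(Somnolence = 0.012),
      injected_signals = c(Somnolence = ratio), seed = 1
    )
  }
  e1 <- expected_cells(base(1), "Somnolence")
  expect_equal(unname(e1["a"]), 1.2)
  expect_equal(unname(e1["c"]), 118.8)
  expect_equal(sum(e1), 10000)

  expect_equal(unname(expected_cells(base(0), "Somnolence")["a"]), 0)

  e2 <- expected_cells(base(16.667), "Somnolence")
  expect_equal(unname(e2["a"]), 10000 * 0.01 * 0.012 * 16.667)
  expect_equal(unname(e2["a"]), 20.0004, tolerance = 1e-12)
  expect_equal(unname(e2["c"]), 118.8)

  # rate * ratio capped at one
  capped <- sim_config(
    n_reports = 100, focal_drug_fraction = 0.5,
    background_pts = c(Somnolence = 0.2),
    injected_signals = c(Somnolence = 50), seed = 1
  )
  expect_equal(unname(expected_cells(capped, "Somnolence")["a"]), 50)

  expect_error(expected_cells(base(1), "Seizure"), "unknown PT")
})

test_that("empirical a-cell means converge to the analytic expectation", {
  cfg <- sim_config(
    n_reports = 10000, focal_drug_fraction = 0.01,
    background_pts = c(Somnolence = 0.012),
    injected_signals = c(Somnolence = 16.7), seed = 0
  )
  exp_cells <- expected_cells(cfg, "Somnolence")
  n_rep <- 200
  a_obs <- vapply(seq_len(n_rep), function(i) {
    cfg$seed <- 1000 + i
    rs <- generate_reports(cfg)
    tab <- build_table(rs, drug_names = cfg$focal_drug, pt = "Somnolence")
    tab$a
  }, numeric(1))
  # a ~ Binomial(n, f * p); SE of the replicate mean follows
  p <- cfg$focal_drug_fraction * min(1, 0.012 * 16.7)
  se_mean <- sqrt(10000 * p * (1 - p) / n_rep)
  expect_lt(abs(mean(a_obs) - exp_cells["a"]), 3 * se_mean)
})

test_that("with all reporting ratios at one, ROR centres on unity", {
  pts <- stats::setNames(rep(0.05, 4),
                         c("Seizure", "Somnolence", "Dizziness", "Fatigue"))
  log_rors <- unlist(lapply(1:40, function(i) {
    cfg <- sim_config(
      n_reports = 5000, focal_drug_fraction = 0.1, background_pts = pts,
      injected_signals = stats::setNames(rep(1, 4), names(pts)), seed = 500 + i
    )
    tabs <- build_all_tables(generate_reports(cfg), drug_names = cfg$focal_drug)
    log(ror(tabs)$ror)
  }))
  expect_equal(mean(log_rors, na.rm = TRUE), 0, tolerance = 0.05)
})

test_that("the FAERS dialect writer emits five header-bearing files", {
  empty <- report_set(
    cases = tibble::tibble(record_id = character(), case_id = character(),
                           version_key = integer(), country = character(),
                           therapy_start = as.Date(character()),
                           event_date = as.Date(character())),
    drugs = tibble::tibble(record_id = character(), drug = character(),
                           role = character()),
    events = tibble::tibble(record_id = character(), pt = character()),
    outcomes = tibble::tibble(record_id = character(), outcome = character())
  )
  dir <- withr::local_tempdir()
  paths <- write_faers_dialect(empty, dir)
  expect_named(paths, c("DEMO", "DRUG", "REAC", "OUTC", "THER"))
  for (p in paths) {
    lines <- readLines(p)
    expect_length(lines, 1)  # header only
    expect_match(lines[1], "\\$")
  }
})

test_that("a report with two PTs writes two REAC rows sharing one id", {
  rs <- tiny_report_set()
  dir <- withr::local_tempdir()
  paths <- write_faers_dialect(rs, dir)
  reac <- readr::read_delim(paths[["REAC"]], delim = "$", col_types = "ccc",
                            progress = FALSE)
  rows01 <- dplyr::filter(reac, primaryid == "01-1")
  expect_equal(nrow(rows01), 2)
  expect_setequal(rows01$pt, c("Somnolence", "Dizziness"))
})

test_that("write then read round-trips all analysed fields", {
  rs <- generate_reports(sim_config(n_reports = 300, seed = 77))
  dir <- withr::local_tempdir()
  write_faers_dialect(rs, dir)
  back <- read_quarter(dir)
  expect_equal(report_set_fields(back), report_set_fields(rs))
})
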