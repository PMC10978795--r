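# Shared fixtures: all built in code at test time.

ref_table <- function() contingency_table(20, 80, 100, 9800)

# Random 2x2 tables with cells in [lo, hi]; margins guaranteed non-empty.
random_tables <- function(n, seed, lo = 0, hi = 500) {
  withr::with_seed(seed, {
    tab <- tibble::tibble(
      a = sample(lo:hi, n, replace = TRUE),
      b = sample(lo:hi, n, replace = TRUE),
      c = sample(lo:hi, n, replace = TRUE),
      d = sample(lo:hi, n, replace = TRUE)
    )
    dplyr::filter(tab, a + b > 0, c + d > 0, a + c > 0, b + d > 0)
  })
}

# A small hand-built report set: 4 cases, one with two versions.
# case 01: XCOPRI/PS + Somnolence + Dizziness, serious (HO), US, dated.
# case 02: XCOPRI/PS (two versions; v2 keeps pt Fall), GB.
# case 03: OTHERDRUG/PS + Somnolence, XCOPRI as concomitant only.
# case 04: OTHERDRUG/PS + Headache, no outcome, missing dates.
tiny_report_set <- function() {
  report_set(
    cases = tibble::tibble(
      record_id = c("01-1", "02-1", "02-2", "03-1", "04-1"),
      case_id = c("01", "02", "02", "03", "04"),
      version_key = c(1L, 1L, 2L, 1L, 1L),
      country = c("US", "GB", "GB", "US", NA),
      therapy_start = as.Date(c("2021-01-01", "2021-02-01", "2021-02-01",
                                "2021-03-01", NA)),
      event_date = as.Date(c("2021-01-10", "2021-02-05", "2021-02-20",
                             "2021-03-31", NA))
    ),
    drugs = tibble::tibble(
      record_id = c("01-1", "02-1", "02-2", "03-1", "03-1", "04-1"),
      drug = c("XCOPRI", "xcopri ", "XCOPRI", "OTHERDRUG", "XCOPRI",
               "OTHERDRUG"),
      role = c("PS", "PS", "PS", "PS", "C", "PS")
    ),
    events = tibble::tibble(
      record_id = c("01-1", "01-1", "02-1", "02-2", "03-1", "04-1"),
      pt = c("Somnolence", "Dizziness", "Seizure", "Fall", "Somnolence",
             "Headache")
    ),
    outcomes = tibble::tibble(
      record_id = c("01-1", "02-2"),
      outcome = c("HO", "DE")
    )
  )
}

# Write a hand-built FAERS-dialect quarter: 3 cases, one orphan REAC row.
write_fixture_quarter <- function(dir, orphan = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(name, lines) {
    writeLines(lines, file.path(dir, paste0(name, ".txt")))
  }
  w("DEMO", c(
    "primaryid$caseid$caseversion$event_dt$occr_country",
    "101-1$101$1$20210510$US",
    "102-1$102$1$20210601$GB",
    "103-1$103$1$$US"
  ))
  w("DRUG", c(
    "primaryid$caseid$drug_seq$role_cod$drugname",
    "101-1$101$1$PS$XCOPRI",
    "101-1$101$2$C$LEVETIRACETAM",
    "102-1$102$1$PS$CENOBAMATE",
    "103-1$103$1$PS$LAMOTRIGINE"
  ))
  reac <- c(
    "primaryid$caseid$pt",
    "101-1$101$Somnolence",
    "101-1$101$Dizziness",
    "102-1$102$Seizure",
    "103-1$103$Somnolence"
  )
  if (orphan) reac <- c(reac, "999-1$999$Fatigue")
  w("REAC", reac)
  w("OUTC", c(
    "primaryid$caseid$outc_cod",
    "101-1$101$HO"
  ))
  w("THER", c(
    "primaryid$caseid$dsg_drug_seq$start_dt",
    "101-1$101$1$20210501",
    "102-1$102$1$20210520",
    "103-1$103$1$notadate"
  ))
  dir
}

# Canonical, order-independent view of the fields the pipeline analyses,
# for round-trip comparisons.
report_set_fields <- function(rs) {
  list(
    cases = dplyr::arrange(
      dplyr::select(rs$cases, "record_id", "case_id", "version_key",
                    "country", "therapy_start", "event_date"),
      record_id
    ),
    drugs = dplyr::arrange(rs$drugs, record_id, drug, role),
    events = dplyr::arrange(rs$events, record_id, pt),
    outcomes = dplyr::arrange(rs$outcomes, record_id, outcome)
  )
}

# Simulation configuration used by signal-recovery checks: five PTs carry an
# injected reporting ratio of 10 on a background rate of 0.005, so with
# 10,000 reports and a 5% focal fraction the expected a-cell is 25.
recovery_config <- function(seed, ratio = 10) {
  pts <- stats::setNames(
    c(rep(0.005, 5), rep(0.01, 10), rep(0.02, 5)),
    c("Seizure", "Somnolence", "Dizziness", "Balance disorder", "Diplopia",
      paste0("Background PT ", sprintf("%02d", 1:10)),
      paste0("Common PT ", 1:5))
  )
  sim_config(
    n_reports = 10000,
    focal_drug_fraction = 0.05,
    background_pts = pts,
    injected_signals = stats::setNames(
      rep(ratio, 5),
      c("Seizure", "Somnolence", "Dizziness", "Balance disorder", "Diplopia")
    ),
    seed = seed
  )
}

null_config <- function(seed, n_reports = 10000) {
  sim_config(n_reports = n_reports, injected_signals = numeric(), seed = seed)
}

# Exact evaluation of the four point statistics via big-rational arithmetic
# (Python fractions); returns a tibble with NA where a statistic is
# undefined under the package's zero-cell policy.
bigrational_oracle <- function(tables) {
  src <- file.path(tempdir(), "bigrational_oracle.py")
  writeLines(c(
    "import sys, csv",
    "from fractions import Fraction as F",
    "rows = list(csv.DictReader(open(sys.argv[1])))",
    "out = csv.writer(open(sys.argv[2], 'w', newline=''))",
    "out.writerow(['ror', 'prr', 'chi2', 'ebgm'])",
    "for r in rows:",
    "    a, b, c, d = (F(int(r[k])) for k in 'abcd')",
    "    n = a + b + c + d",
    "    ror = a * d / (b * c) if a*b*c*d != 0 else None",
    "    prr = (a / (a + b)) / (c / (c + d)) if c != 0 else None",
    "    num = abs(a * d - b * c) - n / 2",
    "    num = num if num > 0 else F(0)",
    "    den = (a + b) * (c + d) * (a + c) * (b + d)",
    "    chi2 = n * num * num / den if den != 0 else None",
    "    ebgm = a * n / ((a + c) * (a + b))",
    "    out.writerow(['' if x is None else repr(float(x))",
    "                  for x in (ror, prr, chi2, ebgm)])"
  ), src)
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  readr::write_csv(tables[, c("a", "b", "c", "d")], fin)
  status <- system2("python", c(src, fin, fout))
  stopifnot(status == 0)
  readr::read_csv(fout, col_types = "dddd", progress = FALSE)
}

# Monte-Carlo oracle for the BCPNN bound: draws from the independent Beta
# posteriors of the joint and marginal reporting probabilities, computes the
# information component for each draw, and returns mean - 2 sd.
mc_ic025 <- function(a, b, c, d, priors = bcpnn_priors(), draws = 1e6) {
  n <- a + b + c + d
  row1 <- a + b
  col1 <- a + c
  gamma <- priors$gamma11 * (n + priors$alpha) * (n + priors$beta) /
    ((row1 + priors$alpha1) * (col1 + priors$beta1))
  p_xy <- stats::rbeta(draws, a + priors$gamma11, n - a + gamma - priors$gamma11)
  p_x <- stats::rbeta(draws, row1 + priors$alpha1,
                      n - row1 + priors$alpha - priors$alpha1)
  p_y <- stats::rbeta(draws, col1 + priors$beta1,
                      n - col1 + priors$beta - priors$beta1)
  ic <- log2(p_xy / (p_x * p_y))
  mean(ic) - 2 * stats::sd(ic)
}
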