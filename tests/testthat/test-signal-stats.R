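# Reference values below were derived by independent hand evaluation of the
# printed formulas on the table (a, b, c, d) = (20, 80, 100, 9800).

test_that("ROR matches the hand-derived reference and flags zero cells", {
  r <- ror(ref_table())
  expect_equal(r$ror, 24.5)
  expect_equal(r$se_ln_ror, sqrt(1 / 20 + 1 / 80 + 1 / 100 + 1 / 9800))
  expect_equal(r$ror_ci_low, 14.448, tolerance = 1e-4)
  expect_equal(r$ror_ci_high, 41.5456, tolerance = 1e-4)

  sym <- ror(contingency_table(10, 10, 10, 10))
  expect_equal(sym$ror, 1)
  expect_true(sym$ror_ci_low < 1 && sym$ror_ci_high > 1)

  z <- ror(contingency_table(1, 0, 5, 5))
  expect_false(z$ror_defined)
  expect_true(is.na(z$ror))
  zc <- ror(contingency_table(1, 0, 5, 5), correction = TRUE)
  expect_true(zc$ror_defined)
  expect_equal(zc$ror, (1.5 * 5.5) / (0.5 * 5.5))

  expect_error(ror(data.frame(a = 0, b = 0, c = 0, d = 0)), "no reports")
})

test_that("PRR and Yates chi-squared match the reference", {
  p <- prr_chi2(ref_table())
  expect_equal(p$prr, 19.8)
  expect_equal(p$chi2, 285.3178, tolerance = 1e-4)

  sym <- prr_chi2(contingency_table(10, 10, 10, 10))
  expect_equal(sym$prr, 1)
  expect_lt(sym$chi2, 1)  # continuity-corrected null

  # scale invariance of a ratio of proportions
  scaled <- prr_chi2(contingency_table(200, 800, 1000, 98000))
  expect_equal(scaled$prr, 19.8)

  # continuity term floored at zero
  expect_equal(prr_chi2(contingency_table(1, 1, 1, 1))$chi2, 0)
  expect_error(prr_chi2(data.frame(a = 0, b = 0, c = 5, d = 5)),
               "zero row margin")
})

test_that("BCPNN shrinkage matches the reference and handles zero cells", {
  b <- bcpnn_ic(ref_table())
  expect_equal(b$ic, log2(20 * 10000 / (100 * 120)))
  expect_equal(b$e_ic, 3.240711, tolerance = 1e-5)
  expect_equal(b$ic025, 2.502112, tolerance = 1e-5)
  expect_lte(b$ic025, b$e_ic)

  # no co-reporting: prior keeps the estimate finite and negative
  z <- bcpnn_ic(contingency_table(0, 50, 50, 900))
  expect_true(is.finite(z$e_ic))
  expect_lt(z$e_ic, 0)
  expect_equal(z$ic, -Inf)

  # independence limit: shrunk IC tends to the raw IC of 0 as N grows
  small <- bcpnn_ic(contingency_table(5, 45, 30, 270))
  big <- bcpnn_ic(contingency_table(5e3, 45e3, 30e3, 270e3))
  expect_lte(small$e_ic, 0)
  expect_lte(big$e_ic, 0)
  expect_lt(abs(big$e_ic), abs(small$e_ic))
  expect_equal(big$e_ic, 0, tolerance = 1e-3)

  expect_error(bcpnn_ic(ref_table(), priors = list(gamma11 = 1)),
               "bcpnn_priors")
  expect_error(bcpnn_priors(gamma11 = 0), "positive")
  expect_error(bcpnn_priors(alpha = 0.5, alpha1 = 1), "alpha")
})

test_that("EBGM (relative reporting ratio) matches the reference", {
  e <- ebgm(ref_table())
  expect_equal(e$ebgm, 20 * 10000 / (120 * 100))
  expect_equal(e$ebgm, 16.6667, tolerance = 1e-4)
  expect_equal(e$ebgm05, 9.8286, tolerance = 1e-4)
  expect_false(attr(e, "shrunk"))

  expect_equal(ebgm(contingency_table(10, 10, 10, 10))$ebgm, 1)
  expect_error(ebgm(data.frame(a = 0, b = 0, c = 5, d = 5)), "zero margin")

  z <- ebgm(contingency_table(3, 0, 2, 5))
  expect_true(is.na(z$ebgm05))
  expect_true(ebgm(contingency_table(3, 0, 2, 5), correction = TRUE)$ebgm_defined)
})

test_that("EBGM never exceeds N / (a + b)", {
  tabs <- random_tables(300, seed = 88, lo = 1)
  e <- ebgm(tabs)
  n <- tabs$a + tabs$b + tabs$c + tabs$d
  expect_true(all(e$ebgm <= n / (tabs$a + tabs$b) + 1e-12))
})

test_that("each statistic is nondecreasing in a in the rare-event regime", {
  # ROR and PRR are monotone in a unconditionally; the observed-to-expected
  # ratios (EBGM, E(IC)) are monotone while the pair stays rare relative to
  # both margins, the regime where signal detection operates
  tabs <- data.frame(a = 1:60, b = 400, c = 250, d = 8000)
  expect_true(all(diff(ror(tabs)$ror) >= 0))
  expect_true(all(diff(prr_chi2(tabs)$prr) >= 0))
  expect_true(all(diff(ebgm(tabs)$ebgm) >= 0))
  expect_true(all(diff(bcpnn_ic(tabs)$e_ic) >= 0))
  # unconditional monotonicity for the odds/proportion ratios
  wide <- data.frame(a = seq(1, 2000, by = 50), b = 40, c = 25, d = 800)
  expect_true(all(diff(ror(wide)$ror) >= 0))
  expect_true(all(diff(prr_chi2(wide)$prr) >= 0))
})

test_that("exact independence gives unit ratios and non-positive shrunk IC", {
  # a/(a+b) = c/(c+d) by construction
  tabs <- data.frame(a = c(5, 20, 9), b = c(45, 180, 81),
                     c = c(30, 5, 90), d = c(270, 45, 810))
  expect_equal(ror(tabs)$ror, c(1, 1, 1))
  expect_equal(prr_chi2(tabs)$prr, c(1, 1, 1))
  expect_equal(ebgm(tabs)$ebgm, c(1, 1, 1))
  expect_true(all(bcpnn_ic(tabs)$e_ic <= 0))
})

test_that("criteria are strict and undefined metrics fail", {
  m <- tibble::tibble(
    pt = letters[1:6],
    a = c(4, 3, 4, 4, 4, 4),
    ror_ci_low = c(1.2, 100, 1.2, 1.2, NA, 1.2),
    prr = c(2.5, 100, 2.5, 2.5, 2.5, 2.5),
    chi2 = c(5, 100, 5, 5, 5, 5),
    ic025 = c(0.1, 100, 0, 0.1, 0.1, 0.1),
    ebgm05 = c(2.1, 100, 2.1, 2, 2.1, NA)
  )
  d <- evaluate_criteria(m)
  expect_equal(d$tier[1], "strong")
  # a = 3 fails the strict a > 3 even with huge statistics
  expect_false(d$ror_pos[2] || d$mhra_pos[2])
  expect_equal(d$tier[2], "positive")  # BCPNN/MGPS have no case threshold
  # boundary values fail strict thresholds
  expect_false(d$bcpnn_pos[3])
  expect_false(d$mgps_pos[4])
  # undefined metrics fail their criterion
  expect_false(d$ror_pos[5])
  expect_false(d$mgps_pos[6])
})

test_that("tiers are consistent with the per-algorithm flags", {
  tabs <- random_tables(400, seed = 3, lo = 0)
  d <- evaluate_criteria(signal_metrics(tabs))
  n_pos <- d$ror_pos + d$mhra_pos + d$bcpnn_pos + d$mgps_pos
  expect_true(all(d$tier[n_pos == 4] == "strong"))
  expect_true(all(d$tier[n_pos >= 1 & n_pos < 4] == "positive"))
  expect_true(all(d$tier[n_pos == 0] == "none"))
})

test_that("venn counts: marginals, intersection and edge cases", {
  all_pass <- tibble::tibble(ror_pos = rep(TRUE, 4), mhra_pos = TRUE,
                             bcpnn_pos = TRUE, mgps_pos = TRUE)
  v <- venn_counts(all_pass)
  expect_equal(unname(v), rep(4L, 5))

  disjoint <- tibble::tibble(
    ror_pos = c(TRUE, FALSE, FALSE, FALSE),
    mhra_pos = c(FALSE, TRUE, FALSE, FALSE),
    bcpnn_pos = c(FALSE, FALSE, TRUE, FALSE),
    mgps_pos = c(FALSE, FALSE, FALSE, TRUE)
  )
  v2 <- venn_counts(disjoint)
  expect_equal(unname(v2), c(1L, 1L, 1L, 1L, 0L))

  tabs <- random_tables(200, seed = 5)
  v3 <- venn_counts(evaluate_criteria(signal_metrics(tabs)))
  expect_true(all(v3["all_four"] <= v3[c("ror", "mhra", "bcpnn", "mgps")]))
})
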