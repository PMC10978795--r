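#' Reporting odds ratio with log-normal confidence interval
#'
#' `ROR = ad / bc`, with `SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)` and the
#' 95% interval `exp(ln ROR +/- 1.96 SE)`. With any zero cell the estimate is
#' flagged undefined (`defined = FALSE`, values `NA`) unless the
#' Haldane-Anscombe continuity correction is enabled, which adds 0.5 to every
#' cell before computing.
#'
#' @param table A [contingency_table()] or a data frame with columns
#'   `a, b, c, d` (vectorised over rows).
#' @param correction Apply the +0.5 continuity correction to zero-cell
#'   tables (default `FALSE`).
#' @return Tibble with columns `ror, se_ln_ror, ror_ci_low, ror_ci_high,
#'   ror_defined`.
#' @examples
#' ror(contingency_table(20, 80, 100, 9800))
#' @export
ror <- function(table, correction = FALSE) {
  cl <- as_cells(table)
  n <- cl$a + cl$b + cl$c + cl$d
  if (any(n == 0)) {
    stop("ror: table has no reports", call. = FALSE)
  }
  has_zero <- cl$a == 0 | cl$b == 0 | cl$c == 0 | cl$d == 0
  defined <- !has_zero | correction
  adj <- if (correction) ifelse(has_zero, 0.5, 0) else 0
  a <- cl$a + adj; b <- cl$b + adj; c <- cl$c + adj; d <- cl$d + adj
  est <- ifelse(defined, a * d / (b * c), NA_real_)
  se <- ifelse(defined, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(
    ror = est,
    se_ln_ror = se,
    ror_ci_low = exp(log(est) - 1.96 * se),
    ror_ci_high = exp(log(est) + 1.96 * se),
    ror_defined = defined
  )
}

#' Proportional reporting ratio and Yates-corrected chi-squared
#'
#' The MHRA criteria pair: `PRR = [a/(a+b)] / [c/(c+d)]` and the
#' continuity-corrected chi-squared
#' `chi2 = N (|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`,
#' with the continuity term `|ad - bc| - N/2` floored at zero.
#'
#' @inheritParams ror
#' @return Tibble with columns `prr, chi2`. `prr` is `Inf` when `c = 0` with
#'   `a > 0`, `NA` when `a = c = 0`; `chi2` is `NA` when an event-column
#'   margin is empty.
#' @examples
#' prr_chi2(contingency_table(20, 80, 100, 9800))
#' @export
prr_chi2 <- function(table) {
  cl <- as_cells(table)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  n <- a + b + c + d
  if (any(a + b == 0) || any(c + d == 0)) {
    stop("prr_chi2: zero row margin (a+b or c+d is empty)", call. = FALSE)
  }
  prr <- (a / (a + b)) / (c / (c + d))
  prr[a == 0 & c == 0] <- NA_real_
  num <- pmax(abs(a * d - b * c) - n / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, n * num^2 / denom, NA_real_)
  tibble::tibble(prr = prr, chi2 = chi2)
}

#' Priors for the BCPNN information component
#'
#' The Bayesian confidence propagation neural network places a Dirichlet
#' prior on the joint drug-event probability and Beta priors on the margins.
#' The classical defaults (`gamma11 = 1`, `alpha1 = beta1 = 1`,
#' `alpha = beta = 2`) make the prior expectation of the information
#' component zero for an empty database.
#'
#' @param gamma11 Prior count added to cell `a` (joint probability prior).
#' @param alpha1,beta1 Prior counts for the drug-row and event-column margins.
#' @param alpha,beta Prior totals for the two margins; must be at least
#'   `alpha1` and `beta1`.
#' @return An object of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(gamma11 = 1, alpha1 = 1, beta1 = 1,
                         alpha = 2, beta = 2) {
  vals <- c(gamma11 = gamma11, alpha1 = alpha1, beta1 = beta1,
            alpha = alpha, beta = beta)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("bcpnn_priors: all prior parameters must be strictly positive",
         call. = FALSE)
  }
  if (alpha < alpha1 || beta < beta1) {
    stop("bcpnn_priors: totals must satisfy alpha >= alpha1 and beta >= beta1",
         call. = FALSE)
  }
  structure(as.list(vals), class = "bcpnn_priors")
}

#' BCPNN information component with shrinkage
#'
#' The raw information component is
#' `IC = log2[ aN / ((a+b)(a+c)) ]`, the log2 observed-to-expected
#' co-reporting ratio under independence. Its Bayesian posterior expectation
#' under the BCPNN prior is
#' `E(IC) = log2[ (a + g11)(N + alpha)(N + beta) /
#'                ((N + gamma)(a + b + alpha1)(a + c + beta1)) ]`
#' with the derived Dirichlet total
#' `gamma = g11 (N + alpha)(N + beta) / ((a + b + alpha1)(a + c + beta1))`,
#' and the signal bound is `IC025 = E(IC) - 2 sqrt(V(IC))` using the
#' first-order posterior variance
#' `V(IC) = (1/ln 2)^2 [ (N - a + gamma - g11) / ((a + g11)(1 + N + gamma))
#'   + (N - (a+b) + alpha - alpha1) / ((a + b + alpha1)(1 + N + alpha))
#'   + (N - (a+c) + beta - beta1) / ((a + c + beta1)(1 + N + beta)) ]`.
#' Zero cells are permitted: the prior keeps every logarithm finite. The raw
#' `ic` (which is `-Inf` when `a = 0`) is reported for reference only; the
#' decision criterion uses `ic025`.
#'
#' @inheritParams ror
#' @param priors A [bcpnn_priors()] object.
#' @return Tibble with columns `ic, e_ic, ic_sd, ic025` (all in bits).
#' @examples
#' bcpnn_ic(contingency_table(20, 80, 100, 9800))
#' @export
bcpnn_ic <- function(table, priors = bcpnn_priors()) {
  if (!inherits(priors, "bcpnn_priors")) {
    stop("bcpnn_ic: priors must be a bcpnn_priors object", call. = FALSE)
  }
  cl <- as_cells(table)
  a <- cl$a
  n <- cl$a + cl$b + cl$c + cl$d
  row1 <- cl$a + cl$b
  col1 <- cl$a + cl$c
  g11 <- priors$gamma11; a1 <- priors$alpha1; b1 <- priors$beta1
  al <- priors$alpha; be <- priors$beta

  ic <- log2(a * n / (row1 * col1))
  gamma <- g11 * (n + al) * (n + be) / ((row1 + a1) * (col1 + b1))
  e_ic <- log2((a + g11) * (n + al) * (n + be) /
                 ((n + gamma) * (row1 + a1) * (col1 + b1)))
  v_ic <- (1 / log(2))^2 * (
    (n - a + gamma - g11) / ((a + g11) * (1 + n + gamma)) +
      (n - row1 + al - a1) / ((row1 + a1) * (1 + n + al)) +
      (n - col1 + be - b1) / ((col1 + b1) * (1 + n + be))
  )
  ic_sd <- sqrt(v_ic)
  tibble::tibble(ic = ic, e_ic = e_ic, ic_sd = ic_sd,
                 ic025 = e_ic - 2 * ic_sd)
}

#' Relative reporting ratio (unshrunk EBGM) with lower bound
#'
#' `EBGM = aN / ((a+c)(a+b))`, the observed-to-expected co-reporting ratio,
#' with a log-normal 95% interval using the same standard error as the ROR:
#' `exp(ln EBGM +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. This is the
#' unshrunk relative reporting ratio, not the DuMouchel gamma-Poisson
#' shrinkage estimate; the `shrunk` attribute on the result records that.
#' Zero cells make the interval undefined unless `correction` adds 0.5 to
#' every cell, as in [ror()].
#'
#' @inheritParams ror
#' @return Tibble with columns `ebgm, ebgm05, ebgm95, ebgm_defined`, with
#'   attribute `shrunk = FALSE`.
#' @examples
#' ebgm(contingency_table(20, 80, 100, 9800))
#' @export
ebgm <- function(table, correction = FALSE) {
  cl <- as_cells(table)
  if (any(cl$a + cl$b == 0) || any(cl$a + cl$c == 0)) {
    stop("ebgm: zero margin (a+b or a+c is empty)", call. = FALSE)
  }
  has_zero <- cl$a == 0 | cl$b == 0 | cl$c == 0 | cl$d == 0
  defined <- !has_zero | correction
  adj <- if (correction) ifelse(has_zero, 0.5, 0) else 0
  a <- cl$a + adj; b <- cl$b + adj; c <- cl$c + adj; d <- cl$d + adj
  n <- a + b + c + d
  est <- ifelse(defined, a * n / ((a + c) * (a + b)), NA_real_)
  se <- ifelse(defined, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  out <- tibble::tibble(
    ebgm = est,
    ebgm05 = exp(log(est) - 1.96 * se),
    ebgm95 = exp(log(est) + 1.96 * se),
    ebgm_defined = defined
  )
  attr(out, "shrunk") <- FALSE
  out
}

#' Compute all four disproportionality statistics
#'
#' Convenience wrapper running [ror()], [prr_chi2()], [bcpnn_ic()] and
#' [ebgm()] over a table of per-PT cells (as from [build_all_tables()]),
#' returning one tidy row per PT.
#'
#' @param tables Data frame with columns `a, b, c, d` and optionally `pt`.
#' @param priors A [bcpnn_priors()] object.
#' @param correction Continuity correction for zero cells in [ror()]/[ebgm()].
#' @return Tibble binding the input columns with all metric columns.
#' @export
signal_metrics <- function(tables, priors = bcpnn_priors(),
                           correction = FALSE) {
  stopifnot(is.data.frame(tables))
  dplyr::bind_cols(
    tibble::as_tibble(tables),
    ror(tables, correction = correction),
    prr_chi2(tables),
    bcpnn_ic(tables, priors = priors),
    ebgm(tables, correction = correction)
  )
}

#' Signal detection thresholds
#'
#' The printed decision rules of the four algorithms, all strict
#' inequalities: ROR requires `a > 3` and a 95% CI lower bound `> 1`; MHRA
#' requires `a > 3`, `PRR > 2` and `chi2 > 4`; BCPNN requires `IC025 > 0`;
#' MGPS requires `EBGM05 > 2`.
#'
#' @param min_a Case-count threshold; a PT passes only with `a > min_a`.
#' @param ror_lower_gt Threshold for the ROR CI lower bound.
#' @param prr_gt,chi2_gt Thresholds for the MHRA pair.
#' @param ic025_gt Threshold for the BCPNN lower bound (bits).
#' @param ebgm05_gt Threshold for the EBGM lower bound.
#' @return An object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_a = 3, ror_lower_gt = 1, prr_gt = 2,
                            chi2_gt = 4, ic025_gt = 0, ebgm05_gt = 2) {
  vals <- c(min_a = min_a, ror_lower_gt = ror_lower_gt, prr_gt = prr_gt,
            chi2_gt = chi2_gt, ic025_gt = ic025_gt, ebgm05_gt = ebgm05_gt)
  if (any(!is.finite(vals))) {
    stop("signal_criteria: all thresholds must be finite", call. = FALSE)
  }
  structure(as.list(vals), class = "signal_criteria")
}

#' Apply the four algorithms' thresholds and assign consensus tiers
#'
#' Evaluates every threshold as a strict inequality; an undefined (missing)
#' metric fails its criterion. The consensus tier is `"strong"` when all
#' four algorithms flag the PT, `"positive"` when at least one (but not all)
#' does, and `"none"` otherwise — consensus across algorithms, rather than a
#' multiplicity adjustment, is the false-positive control.
#'
#' @param metrics Data frame containing columns `a, ror_ci_low, prr, chi2,
#'   ic025, ebgm05` (as produced by [signal_metrics()]).
#' @param criteria A [signal_criteria()] object.
#' @return The input tibble with logical columns `ror_pos, mhra_pos,
#'   bcpnn_pos, mgps_pos` and a character column `tier` appended.
#' @export
evaluate_criteria <- function(metrics, criteria = signal_criteria()) {
  stopifnot(is.data.frame(metrics))
  if (!inherits(criteria, "signal_criteria")) {
    stop("evaluate_criteria: criteria must be a signal_criteria object",
         call. = FALSE)
  }
  need <- c("a", "ror_ci_low", "prr", "chi2", "ic025", "ebgm05")
  missing <- setdiff(need, names(metrics))
  if (length(missing) > 0) {
    stop(sprintf("evaluate_criteria: metrics missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  gt <- function(x, thr) !is.na(x) & x > thr  # undefined fails
  out <- tibble::as_tibble(metrics)
  out$ror_pos <- gt(out$a, criteria$min_a) &
    gt(out$ror_ci_low, criteria$ror_lower_gt)
  out$mhra_pos <- gt(out$a, criteria$min_a) &
    gt(out$prr, criteria$prr_gt) & gt(out$chi2, criteria$chi2_gt)
  out$bcpnn_pos <- gt(out$ic025, criteria$ic025_gt)
  out$mgps_pos <- gt(out$ebgm05, criteria$ebgm05_gt)
  n_pos <- out$ror_pos + out$mhra_pos + out$bcpnn_pos + out$mgps_pos
  out$tier <- dplyr::case_when(
    n_pos == 4 ~ "strong",
    n_pos >= 1 ~ "positive",
    .default = "none"
  )
  out
}

#' Per-algorithm signal counts and four-way intersection
#'
#' Summarises a decision table: how many PTs each algorithm flags, and how
#' many are flagged by all four (the "effective" strong-association set).
#' The intersection can never exceed any marginal count.
#'
#' @param decisions Data frame with logical columns `ror_pos, mhra_pos,
#'   bcpnn_pos, mgps_pos` (as from [evaluate_criteria()]).
#' @return Named integer vector with elements `ror, mhra, bcpnn, mgps,
#'   all_four`.
#' @export
venn_counts <- function(decisions) {
  stopifnot(is.data.frame(decisions))
  need <- c("ror_pos", "mhra_pos", "bcpnn_pos", "mgps_pos")
  missing <- setdiff(need, names(decisions))
  if (length(missing) > 0) {
    stop(sprintf("venn_counts: decisions missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  c(
    ror = sum(decisions$ror_pos),
    mhra = sum(decisions$mhra_pos),
    bcpnn = sum(decisions$bcpnn_pos),
    mgps = sum(decisions$mgps_pos),
    all_four = sum(decisions$ror_pos & decisions$mhra_pos &
                     decisions$bcpnn_pos & decisions$mgps_pos)
  )
}
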