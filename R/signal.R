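# The four disproportionality estimators and the combined signal rule.
#
# All four compare observed to expected reporting under row/column
# independence of the 2x2 table:
#   ROR  = (a/c)/(b/d) = ad/bc           (odds scale)
#   PRR  = [a/(a+b)] / [c/(c+d)]         (rate scale), paired with Pearson chi2
#   IC   = log2( a*N / ((a+c)(a+b)) )    (information component, base-2 log)
#   EBGM = a*N / ((a+c)(a+b))            (observed/expected ratio)
# EBGM here is the plain observed-to-expected ratio with Wald bounds on the
# log scale, not the gamma-Poisson shrinkage estimator of the full MGPS
# machinery; consequently IC == log2(EBGM) identically. Intervals are
# exp(ln x +/- 1.96 se) with se = sqrt(1/a + 1/b + 1/c + 1/d), except the
# PRR's se which drops the within-row terms: sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)).
#
# A table with a zero in a required cell yields NA estimates ("undefined,
# flagged") rather than a continuity correction; the signal rule already
# requires a >= 3, so corrected small-cell estimates are never needed.

#' Reporting odds ratio with 95% Wald interval
#'
#' @param a,b,c,d Cell counts (vectorized). Any zero cell gives `NA`s.
#' @return A tibble with `ror`, `ror_lower`, `ror_upper`.
#' @export
ror_estimate <- function(a, b, c, d) {
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  point <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble(ror = point,
         ror_lower = exp(log(point) - 1.96 * se),
         ror_upper = exp(log(point) + 1.96 * se))
}

#' Proportional reporting ratio with 95% interval and Pearson chi-squared
#'
#' The chi-squared statistic is the uncorrected Pearson statistic of the 2x2
#' table; it is computed whenever all margins are positive, even when the PRR
#' point itself is undefined.
#'
#' @param a,b,c,d Cell counts (vectorized). `a = 0` or `c = 0` gives `NA`
#'   point/bounds.
#' @return A tibble with `prr`, `prr_lower`, `prr_upper`, `chi2`.
#' @export
prr_estimate <- function(a, b, c, d) {
  ok <- a > 0 & c > 0 & (a + b) > 0 & (c + d) > 0
  point <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
  se <- ifelse(ok, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  margins_ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  tibble(prr = point,
         prr_lower = exp(log(point) - 1.96 * se),
         prr_upper = exp(log(point) + 1.96 * se),
         chi2 = ifelse(margins_ok, pearson_chi2(a, b, c, d), NA_real_))
}

#' Information component (BCPNN) with a 95% interval
#'
#' The point estimate is the base-2 log of the observed-to-expected reporting
#' ratio, `log2(a * N / ((a + c) * (a + b)))`. Two interval methods are
#' offered:
#'
#' * `"se"` (default): Wald bounds `point +/- 1.96 * se / ln 2` with
#'   `se = sqrt(1/a + 1/b + 1/c + 1/d)`, i.e. the log-scale standard error of
#'   the observed/expected ratio converted to base 2.
#' * `"bcpnn-bayes"`: the closed-form credible-interval approximation of
#'   Noren et al. (2006, Stat Med) used by the WHO UMC:
#'   `IC* = log2((a + 0.5)/(E + 0.5))` with `E = (a + b)(a + c)/N`, and
#'   `IC025 = IC* - 3.3 (a + 0.5)^(-1/2) - 2 (a + 0.5)^(-3/2)` (the upper
#'   bound adds `2.4 (a + 0.5)^(-1/2) + 0.5 (a + 0.5)^(-3/2)`). Useful when
#'   `a` is small and the Wald bound is anti-conservative.
#'
#' @param a,b,c,d Cell counts (vectorized). `a = 0` gives `NA`.
#' @param method `"se"` or `"bcpnn-bayes"`.
#' @return A tibble with `ic`, `ic_lower`, `ic_upper`.
#' @export
ic_estimate <- function(a, b, c, d, method = c("se", "bcpnn-bayes")) {
  method <- match.arg(method)
  n <- a + b + c + d
  ok <- a > 0 & (a + c) > 0 & (a + b) > 0 & n > 0
  point <- ifelse(ok, log2(a * n / ((a + c) * (a + b))), NA_real_)
  if (method == "se") {
    se_ok <- ok & b > 0 & c > 0 & d > 0
    se <- ifelse(se_ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d) / log(2), NA_real_)
    lower <- point - 1.96 * se
    upper <- point + 1.96 * se
  } else {
    e <- (a + b) * (a + c) / n
    star <- ifelse(ok, log2((a + 0.5) / (e + 0.5)), NA_real_)
    lower <- star - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
    upper <- star + 2.4 * (a + 0.5)^(-0.5) + 0.5 * (a + 0.5)^(-1.5)
    lower <- ifelse(ok, lower, NA_real_)
    upper <- ifelse(ok, upper, NA_real_)
  }
  tibble(ic = point, ic_lower = lower, ic_upper = upper)
}

#' Observed-to-expected reporting ratio (EBGM as printed) with 95% interval
#'
#' `EBGM = a * N / ((a + c) * (a + b))` with Wald bounds
#' `exp(ln EBGM +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. This is the unshrunk
#' observed/expected ratio; no empirical-Bayes prior is fitted.
#'
#' @param a,b,c,d Cell counts (vectorized). `a = 0` gives `NA`.
#' @return A tibble with `ebgm`, `ebgm_lower` (the EBGM05 bound), `ebgm_upper`.
#' @export
ebgm_estimate <- function(a, b, c, d) {
  n <- a + b + c + d
  ok <- a > 0 & (a + c) > 0 & (a + b) > 0 & n > 0
  point <- ifelse(ok, a * n / ((a + c) * (a + b)), NA_real_)
  se_ok <- ok & b > 0 & c > 0 & d > 0
  se <- ifelse(se_ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble(ebgm = point,
         ebgm_lower = exp(log(point) - 1.96 * se),
         ebgm_upper = exp(log(point) + 1.96 * se))
}

#' Signal-detection thresholds
#'
#' Defaults encode the conventional four-algorithm rule: at least 3 reports
#' of the event with the drug; ROR 95% lower bound above 1; PRR at least 2
#' with chi-squared at least 4; IC025 above 0; EBGM05 above 2.
#'
#' @param min_a,prr_min,chi2_min,ror_lower_min,ic025_min,ebgm05_min Numeric
#'   thresholds.
#' @return A named list of class `pv_thresholds`.
#' @export
signal_thresholds <- function(min_a = 3, prr_min = 2, chi2_min = 4,
                              ror_lower_min = 1, ic025_min = 0,
                              ebgm05_min = 2) {
  th <- list(min_a = min_a, prr_min = prr_min, chi2_min = chi2_min,
             ror_lower_min = ror_lower_min, ic025_min = ic025_min,
             ebgm05_min = ebgm05_min)
  if (!all(vapply(th, function(x) is.numeric(x) && is.finite(x), logical(1)))) {
    abort("all thresholds must be finite numbers")
  }
  structure(th, class = "pv_thresholds")
}

#' Compute all four estimators and the combined significance flag
#'
#' Takes a data frame of contingency cells (one term per row, as produced by
#' [build_contingency()] or [counts_to_cells()]) and appends the four point
#' estimates with 95% bounds, the chi-squared value, the per-criterion pass
#' flags and the combined `significant` flag. A signal is significant only if
#' it passes the count criterion AND all four algorithm criteria; an
#' undefined (NA) estimate fails its criterion.
#'
#' @param cells A data frame with numeric columns `a`, `b`, `c`, `d`.
#' @param thresholds A [signal_thresholds()] object.
#' @param ic_method Interval method passed to [ic_estimate()].
#' @return The input tibble with estimate, bound, flag and `significant`
#'   columns appended.
#' @export
disproportionality <- function(cells, thresholds = signal_thresholds(),
                               ic_method = c("se", "bcpnn-bayes")) {
  stopifnot(inherits(thresholds, "pv_thresholds"),
            all(c("a", "b", "c", "d") %in% names(cells)))
  ic_method <- match.arg(ic_method)
  cells <- as_tibble(cells)
  a <- cells$a; b <- cells$b; c <- cells$c; d <- cells$d
  out <- dplyr::bind_cols(
    cells,
    ror_estimate(a, b, c, d),
    prr_estimate(a, b, c, d),
    ic_estimate(a, b, c, d, method = ic_method),
    ebgm_estimate(a, b, c, d)
  )
  pass <- function(x) !is.na(x) & x
  out %>%
    mutate(
      count_pass = .data$a >= thresholds$min_a,
      ror_pass = pass(.data$ror_lower > thresholds$ror_lower_min),
      prr_pass = pass(.data$prr >= thresholds$prr_min &
                        .data$chi2 >= thresholds$chi2_min),
      ic_pass = pass(.data$ic_lower > thresholds$ic025_min),
      ebgm_pass = pass(.data$ebgm_lower > thresholds$ebgm05_min),
      significant = .data$count_pass & .data$ror_pass & .data$prr_pass &
        .data$ic_pass & .data$ebgm_pass
    )
}

#' Evaluate a single 2x2 table against the signal rule
#'
#' Scalar convenience wrapper around [disproportionality()].
#'
#' @param a,b,c,d Cell counts.
#' @inheritParams disproportionality
#' @return A one-row tibble.
#' @export
evaluate_signal <- function(a, b, c, d, thresholds = signal_thresholds(),
                            ic_method = "se") {
  disproportionality(tibble(a = a, b = b, c = c, d = d),
                     thresholds = thresholds, ic_method = ic_method)
}

#' Reconstruct 2x2 cells from externally aggregated counts
#'
#' Public dashboards (e.g. WHO VigiAccess) publish only the marginal counts:
#' events for the drug with the term (`a`), the drug's event total (`a + b`),
#' the term's event total (`a + c`) and the database total (`N`). The
#' remaining cells follow by subtraction, after which the same estimators
#' apply.
#'
#' @param a Drug-and-term event count.
#' @param drug_total Drug event total `a + b`.
#' @param term_total Term event total `a + c`.
#' @param n Database event total `N`.
#' @return A tibble with columns `a`, `b`, `c`, `d`.
#' @export
counts_to_cells <- function(a, drug_total, term_total, n) {
  b <- drug_total - a
  c <- term_total - a
  d <- n - a - b - c
  if (any(c(b, c, d) < 0)) abort("aggregated counts imply a negative cell")
  tibble(a = a, b = b, c = c, d = d)
}

#' Signal table for every term in a universe
#'
#' Convenience composition of [build_contingency()] and
#' [disproportionality()].
#'
#' @inheritParams build_contingency
#' @inheritParams disproportionality
#' @return A tibble, one row per term, sorted by `a` descending.
#' @export
signal_table <- function(universe, level = c("pt", "soc"), dict = NULL,
                         thresholds = signal_thresholds(),
                         ic_method = "se") {
  cells <- build_contingency(universe, level = level, dict = dict)
  disproportionality(cells, thresholds = thresholds, ic_method = ic_method)
}
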