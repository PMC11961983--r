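# Two-by-two disproportionality tables. For each term the cells are
#   a: target-drug events with the term      b: target-drug events without it
#   c: other-drug events with the term       d: other-drug events without it
# Counts are at EVENT level (unique report x PT pairs), so a+b is the target
# drug's event total, not its report total.

#' Build 2x2 contingency tables from an event universe
#'
#' At PT level a term is a normalized preferred term; at SOC level events are
#' first mapped through the dictionary (unknown terms fall into the
#' `"UNMAPPED"` pseudo-SOC) and a term is a system organ class. One row per
#' term is returned; restrict with `terms` to select particular ones.
#'
#' @param universe A `pv_universe` from [assemble_event_universe()].
#' @param level `"pt"` or `"soc"`.
#' @param dict A `pv_dictionary`; required at SOC level.
#' @param terms Optional character vector restricting the output.
#' @return A tibble with columns `level`, `term`, `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(universe, level = c("pt", "soc"), dict = NULL,
                              terms = NULL) {
  stopifnot(inherits(universe, "pv_universe"))
  level <- match.arg(level)
  ev <- universe$events
  if (level == "soc") {
    if (is.null(dict) || nrow(dict) == 0) {
      abort("a non-empty term dictionary is required at SOC level")
    }
    ev$term <- soc_of(dict, ev$pt, quiet = TRUE)$soc
  } else {
    ev$term <- ev$pt
  }
  tot_target <- sum(ev$target)
  tot_other <- nrow(ev) - tot_target

  out <- ev %>%
    group_by(.data$term) %>%
    summarise(a = sum(.data$target), c = sum(!.data$target), .groups = "drop")
  if (!is.null(terms)) {
    terms <- if (level == "pt") normalize_term(terms) else terms
    out <- tibble(term = terms) %>%
      left_join(out, by = "term") %>%
      mutate(a = if_else(is.na(.data$a), 0L, as.integer(.data$a)),
             c = if_else(is.na(.data$c), 0L, as.integer(.data$c)))
  }
  out %>%
    mutate(level = level,
           b = tot_target - .data$a,
           d = tot_other - .data$c,
           n = .data$a + .data$b + .data$c + .data$d) %>%
    select("level", "term", "a", "b", "c", "d", "n") %>%
    arrange(desc(.data$a), .data$term)
}

#' Pearson chi-squared statistic for a 2x2 table
#'
#' No continuity correction is applied: the uncorrected statistic is the one
#' whose back-solved margins are consistent with published EBGM and ROR
#' confidence bounds (see the methods vignette).
#'
#' @param a,b,c,d Cell counts (vectorized).
#' @return Numeric vector of chi-squared values.
#' @export
pearson_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' Back-solve contingency margins from published summary statistics
#'
#' Given the target-drug cells (`a` and the row total `a + b`) together with a
#' published proportional reporting ratio and Pearson chi-squared, recovers
#' the comparator cells `c` and `d`. The PRR fixes the comparator event rate
#' `c / (c + d)`; the comparator scale `c + d` is then located by bisection on
#' the (monotone) chi-squared statistic over a log-spaced bracket.
#'
#' @param a Target events with the term.
#' @param row_total Target event total `a + b`.
#' @param prr Published proportional reporting ratio (must differ from 1).
#' @param chi2 Published uncorrected Pearson chi-squared (must be positive).
#' @param interval Bracket for `c + d`.
#' @param tol Relative tolerance on the chi-squared match.
#' @return A one-row tibble with `a`, `b`, `c`, `d`, `n` (real-valued cells).
#' @export
solve_margins <- function(a, row_total, prr, chi2,
                          interval = c(1e3, 1e10), tol = 1e-3) {
  if (a >= row_total) abort("a must be smaller than row_total")
  if (prr <= 0 || chi2 <= 0) abort("prr and chi2 must be positive")
  if (abs(prr - 1) < 1e-12) {
    abort("unidentifiable: prr = 1 carries no information about the scale")
  }
  b <- row_total - a
  rate <- (a / row_total) / prr  # comparator event rate c / (c + d)
  if (rate <= 0 || rate >= 1) abort("prr implies an impossible comparator rate")

  f <- function(log10_m) {
    m <- 10^log10_m
    pearson_chi2(a, b, rate * m, (1 - rate) * m) - chi2
  }
  lo <- log10(interval[[1]]); hi <- log10(interval[[2]])
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || sign(flo) == sign(fhi)) {
    abort("no bracketing sign change for chi2 over the given interval")
  }
  # iterate to interval convergence: near the large-sample asymptote chi2 is
  # insensitive to the scale, so a chi2-based stop would be premature
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  m <- 10^((lo + hi) / 2)
  if (abs(f((lo + hi) / 2)) > tol * chi2) {
    warn("back-solved scale matches chi2 only approximately (near-degenerate input)")
  }
  tibble(a = a, b = b, c = rate * m, d = (1 - rate) * m,
         n = a + b + m)
}
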