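# Cohort descriptives: the demographic / reporter / seriousness breakdown and
# yearly report counts. Percentages are always 100 * n / total rounded to two
# decimals, recomputable from the count columns.

pct2 <- function(n, total) round(100 * n / total, 2)

#' Parse a possibly partial FAERS date
#'
#' FAERS date fields may be full (`YYYYMMDD`), month-level (`YYYYMM`),
#' year-level (`YYYY`) or absent. Partial dates are kept for year extraction
#' but count as missing wherever day-level arithmetic is required.
#'
#' @param x Character vector of raw date fields.
#' @return A tibble with `date` (a `Date`, `NA` unless full and valid),
#'   `year` (integer, `NA` if absent) and `precision`
#'   (`"day"`, `"month"`, `"year"` or `"missing"`).
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  prec <- dplyr::case_when(
    grepl("^[0-9]{8}$", x) ~ "day",
    grepl("^[0-9]{6}$", x) ~ "month",
    grepl("^[0-9]{4}$", x) ~ "year",
    TRUE ~ "missing"
  )
  date <- as.Date(ifelse(prec == "day", x, NA), format = "%Y%m%d")
  prec[prec == "day" & is.na(date)] <- "missing"  # e.g. 20231345
  year <- ifelse(prec == "missing", NA_integer_,
                 as.integer(substr(x, 1, 4)))
  tibble(date = date, year = year, precision = prec)
}

age_in_years <- function(age_value, age_unit) {
  v <- suppressWarnings(as.numeric(age_value))
  u <- toupper(trimws(age_unit))
  dplyr::case_when(
    is.na(v) ~ NA_real_,
    u == "YR" ~ v,
    u == "DEC" ~ v * 10,
    u == "MON" ~ v / 12,
    u == "WK" ~ v * 7 / 365.25,
    u == "DY" ~ v / 365.25,
    TRUE ~ NA_real_
  )
}

age_band <- function(years) {
  dplyr::case_when(
    is.na(years) ~ "Not specified",
    years < 18 ~ "<18",
    years < 45 ~ "18-44",
    years < 65 ~ "45-64",
    TRUE ~ ">=65"
  )
}

reporter_label <- function(code) {
  lab <- c(MD = "Physician", PH = "Pharmacist", OT = "Other health-professional",
           HP = "Other health-professional", CN = "Consumer", LW = "Lawyer")
  out <- unname(lab[toupper(trimws(code))])
  ifelse(is.na(out), "Not specified", out)
}

outcome_label <- function(code) {
  lab <- c(DE = "Death", LT = "Life-threatening", HO = "Hospitalization",
           DS = "Disability", CA = "Congenital anomaly",
           RI = "Required intervention", OT = "Other serious")
  out <- unname(lab[toupper(trimws(code))])
  if (anyNA(out)) {
    abort(paste0("unknown outcome code: ",
                 paste(unique(code[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Summarize a deduplicated report cohort
#'
#' One row per category: the report total, then sex, age band, reporter type,
#' top reporting countries, seriousness and (when `outcomes` is supplied) the
#' per-outcome-code breakdown. Sex, age and reporter counts each sum to the
#' report total; outcome counts need not (a report can carry several outcome
#' codes). A report is "serious" if it has at least one outcome row.
#'
#' @param reports Deduplicated report tibble with `primaryid`, `sex`,
#'   `age_value`, `age_unit`, `reporter` (code), `country` columns.
#' @param outcomes Optional outcome tibble with `primaryid`, `outcome` code.
#' @param top_countries How many countries to list (ties broken
#'   alphabetically).
#' @return A tibble with columns `section`, `category`, `n`, `pct`.
#' @export
summarize_cohort <- function(reports, outcomes = NULL, top_countries = 5) {
  reports <- as_tibble(reports)
  total <- nrow(reports)
  if (total == 0) abort("no reports to summarize")

  row_block <- function(section, category_vec, levels) {
    tibble(category = factor(category_vec, levels = levels)) %>%
      count(.data$category, .drop = FALSE) %>%
      mutate(section = section, category = as.character(.data$category),
             pct = pct2(.data$n, total)) %>%
      select("section", "category", "n", "pct")
  }

  sex <- dplyr::case_when(
    toupper(reports$sex) == "F" ~ "Female",
    toupper(reports$sex) == "M" ~ "Male",
    TRUE ~ "Not specified"
  )
  band <- age_band(age_in_years(reports$age_value, reports$age_unit))
  rep_type <- reporter_label(reports$reporter)

  country <- reports %>%
    mutate(country = ifelse(is.na(.data$country) | .data$country == "",
                            "Unknown", .data$country)) %>%
    count(.data$country) %>%
    arrange(desc(.data$n), .data$country) %>%
    head(top_countries) %>%
    mutate(section = "country", pct = pct2(.data$n, total)) %>%
    rename(category = "country") %>%
    select("section", "category", "n", "pct")

  out <- bind_rows(
    tibble(section = "total", category = "Number of reports",
           n = total, pct = NA_real_),
    row_block("sex", sex, c("Female", "Male", "Not specified")),
    row_block("age", band,
              c("<18", "18-44", "45-64", ">=65", "Not specified")),
    row_block("reporter", rep_type,
              c("Consumer", "Physician", "Pharmacist", "Lawyer",
                "Other health-professional", "Not specified")),
    country
  )

  if (!is.null(outcomes)) {
    outcomes <- as_tibble(outcomes) %>%
      semi_join(reports, by = "primaryid")
    n_serious <- dplyr::n_distinct(outcomes$primaryid)
    out <- bind_rows(
      out,
      tibble(section = "seriousness",
             category = c("Serious", "Non-serious"),
             n = c(n_serious, total - n_serious),
             pct = pct2(c(n_serious, total - n_serious), total)),
      outcome_distribution(outcomes, total) %>%
        mutate(section = "outcome") %>%
        rename(category = "outcome") %>%
        select("section", "category", "n", "pct")
    )
  }
  out
}

#' Per-outcome-code counts and percentages
#'
#' A report contributes to every outcome code it carries, so percentages can
#' sum to more than 100.
#'
#' @param outcomes Outcome tibble with `primaryid` and `outcome` code columns.
#' @param total_reports Denominator for the percentages.
#' @return A tibble `outcome`, `n`, `pct` in a fixed code order.
#' @export
outcome_distribution <- function(outcomes, total_reports) {
  if (total_reports <= 0) abort("total_reports must be positive")
  levels <- c("Death", "Life-threatening", "Hospitalization", "Disability",
              "Congenital anomaly", "Required intervention", "Other serious")
  outcomes <- as_tibble(outcomes) %>%
    distinct(.data$primaryid, .data$outcome)
  lab <- if (nrow(outcomes) > 0) outcome_label(outcomes$outcome) else character()
  tibble(outcome = factor(lab, levels = levels)) %>%
    count(.data$outcome, .drop = FALSE) %>%
    mutate(outcome = as.character(.data$outcome),
           pct = pct2(.data$n, total_reports))
}

#' Yearly report counts
#'
#' Counts deduplicated reports by FDA receipt year, ascending, with the peak
#' year flagged.
#'
#' @param reports Report tibble with an `fda_dt` column.
#' @return A tibble `year`, `n`, `peak` (logical); empty input gives zero
#'   rows.
#' @export
yearly_counts <- function(reports) {
  reports <- as_tibble(reports)
  if (nrow(reports) == 0) {
    return(tibble(year = integer(), n = integer(), peak = logical()))
  }
  yr <- parse_faers_date(reports$fda_dt)$year
  if (anyNA(yr)) abort("fda_dt must parse to at least a year for all reports")
  tibble(year = yr) %>%
    count(.data$year) %>%
    arrange(.data$year) %>%
    mutate(peak = .data$n == max(.data$n))
}
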