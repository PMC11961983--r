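# Time-to-onset analysis: calendar days from the earliest target-drug therapy
# start to the event date, one duration per report. Only full (day-level)
# dates enter the arithmetic; day-0 onsets are valid, negative durations are
# excluded as incorrect.

#' Day count between two full dates
#'
#' @param start,event Character vectors of raw FAERS dates.
#' @return A tibble with `days` (integer, `NA` when undefined) and `status`:
#'   `"ok"`, `"missing start"`, `"missing event date"`, `"partial date"` or
#'   `"negative duration"`.
#' @export
onset_days <- function(start, event) {
  s <- parse_faers_date(start)
  e <- parse_faers_date(event)
  days <- as.integer(e$date - s$date)
  status <- dplyr::case_when(
    s$precision == "missing" ~ "missing start",
    e$precision == "missing" ~ "missing event date",
    s$precision != "day" | e$precision != "day" ~ "partial date",
    days < 0 ~ "negative duration",
    TRUE ~ "ok"
  )
  tibble(days = ifelse(status == "ok", days, NA_integer_), status = status)
}

#' Collect valid onset durations for target reports
#'
#' For every target report the duration is the event date minus the earliest
#' therapy start among therapy rows linked (via `dsg_drug_seq`/`drug_seq`) to
#' a target-drug row. Reports without such a therapy row are excluded with
#' reason `"missing start"`; partial dates, missing event dates and negative
#' durations are excluded with their own reasons.
#'
#' @param universe A `pv_universe`; its reports must carry `event_dt`.
#' @param therapies Therapy tibble with `primaryid`, `dsg_drug_seq`,
#'   `start_dt`.
#' @param drugs Drug tibble with `primaryid`, `drug_seq`, `drugname`, `role`.
#' @param lexicon Target-drug lexicon.
#' @return An object of class `pv_onsets`: a tibble with one row per target
#'   report (`primaryid`, `days`, `status`, `included`), plus an `exclusions`
#'   attribute tallying reasons.
#' @export
collect_valid_onsets <- function(universe, therapies, drugs,
                                 lexicon = azacitidine_lexicon()) {
  stopifnot(inherits(universe, "pv_universe"))
  therapies <- as_tibble(therapies)
  drugs <- as_tibble(drugs)

  target_drug_rows <- drugs %>%
    filter(normalize_drug_name(.data$drugname) %in% lexicon) %>%
    select("primaryid", "drug_seq")

  starts <- therapies %>%
    dplyr::inner_join(target_drug_rows,
                      by = c(primaryid = "primaryid", dsg_drug_seq = "drug_seq")) %>%
    mutate(parsed = parse_faers_date(.data$start_dt)) %>%
    tidyr::unnest("parsed") %>%
    group_by(.data$primaryid) %>%
    summarise(
      # earliest full start date; a report whose starts are all partial keeps
      # the partial-date status rather than silently dropping to "missing"
      start_dt = if (any(.data$precision == "day")) {
        format(min(.data$date, na.rm = TRUE), "%Y%m%d")
      } else if (any(.data$precision %in% c("month", "year"))) {
        first(.data$start_dt[.data$precision != "missing"])
      } else NA_character_,
      .groups = "drop")

  cand <- universe$reports %>%
    filter(.data$primaryid %in% universe$target_ids) %>%
    select("primaryid", "event_dt") %>%
    left_join(starts, by = "primaryid")

  od <- onset_days(cand$start_dt, cand$event_dt)
  # a report with no linked therapy row at all is a missing start
  no_row <- !cand$primaryid %in% starts$primaryid
  od$status[no_row] <- "missing start"
  od$days[no_row] <- NA_integer_

  out <- cand %>%
    mutate(days = od$days, status = od$status,
           included = .data$status == "ok") %>%
    select("primaryid", "days", "status", "included")
  excl <- out %>%
    filter(!.data$included) %>%
    count(reason = .data$status)
  structure(out, class = c("pv_onsets", class(out)), exclusions = excl)
}

#' Summarize onset durations
#'
#' Mean, median and quartiles (linear interpolation between order statistics,
#' R's default quantile type 7) plus a binned distribution. Default bins are
#' 0-30, 30-60, 60-90, 90-120, 120-180 and over 180 days (left-closed first
#' bin, right-closed thereafter).
#'
#' @param durations Numeric vector of non-negative day counts.
#' @param breaks Bin edges (first bin includes its left edge).
#' @return An object of class `pv_onset_summary`.
#' @export
summarize_onsets <- function(durations, breaks = c(0, 30, 60, 90, 120, 180, Inf)) {
  durations <- durations[!is.na(durations)]
  if (length(durations) == 0) abort("no durations to summarize")
  if (any(durations < 0)) abort("negative durations must be excluded upstream")
  q <- unname(quantile(durations, c(0.25, 0.5, 0.75), type = 7))
  labs <- paste0(
    ifelse(seq_len(length(breaks) - 1) == 1, "[", "("),
    breaks[-length(breaks)], ",",
    ifelse(is.finite(breaks[-1]), paste0(breaks[-1], "]"), "Inf)"))
  bins <- tibble(
    bin = factor(labs[findInterval(durations, breaks, left.open = TRUE,
                                   rightmost.closed = FALSE) %>%
                        pmax(1)],  # values equal to the left edge of bin 1
                 levels = labs)) %>%
    count(.data$bin, .drop = FALSE) %>%
    mutate(prop = .data$n / length(durations))
  structure(
    list(n = length(durations), mean = mean(durations),
         median = q[[2]], q1 = q[[1]], q3 = q[[3]], bins = bins),
    class = "pv_onset_summary")
}

#' @export
print.pv_onset_summary <- function(x, ...) {
  cat("<pv_onset_summary>\n")
  cat(sprintf("  n = %d, mean = %.2f d, median = %g d (IQR %g-%g)\n",
              x$n, x$mean, x$median, x$q1, x$q3))
  print(x$bins)
  invisible(x)
}

#' @describeIn summarize_onsets The binned distribution as a tibble.
#' @param x A `pv_onset_summary`.
#' @param ... Unused.
#' @export
tidy.pv_onset_summary <- function(x, ...) x$bins

#' @describeIn summarize_onsets One-row tibble of n, mean, median, quartiles.
#' @export
glance.pv_onset_summary <- function(x, ...) {
  tibble(n = x$n, mean = x$mean, median = x$median, q1 = x$q1, q3 = x$q3)
}

#' Empirical cumulative onset curve
#'
#' Step points of the empirical CDF at each distinct duration; the final
#' proportion is exactly 1.
#'
#' @param durations Numeric vector of day counts.
#' @return A tibble with `day` (ascending) and `cum_prop`.
#' @export
cumulative_curve <- function(durations) {
  durations <- durations[!is.na(durations)]
  if (length(durations) == 0) abort("no durations for a cumulative curve")
  tibble(day = durations) %>%
    count(.data$day) %>%
    arrange(.data$day) %>%
    mutate(cum_prop = cumsum(.data$n) / sum(.data$n)) %>%
    select("day", "cum_prop")
}
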