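# Ingest of FAERS-style quarterly ASCII tables: dollar-delimited, one header
# row, one record per line. Case deduplication follows the FDA convention:
# within a CASEID keep the latest FDA_DT, ties broken by the highest PRIMARYID.

#' Read a FAERS-style dollar-delimited table
#'
#' Parses the quarterly ASCII dialect used by the FDA Adverse Event Reporting
#' System: a single header line, `$` as field delimiter, one record per line.
#' A single trailing delimiter on a line is tolerated. Column names are
#' lower-cased; all columns are read as character (dates and codes are
#' interpreted downstream).
#'
#' @param file Path to the table, or a character vector of lines (useful in
#'   tests).
#' @param schema Optional character vector of column names that must be
#'   present in the header (extra header columns are kept as-is).
#' @param strict If `TRUE` (default) a row whose field count does not match
#'   the header is an error naming the offending line; if `FALSE` such rows
#'   are skipped, a message reports how many, and the count is attached as
#'   attribute `"skipped"`.
#' @return A tibble with one row per record.
#' @export
#' @examples
#' read_faers_table(c("primaryid$caseid$fda_dt", "100$1$20230105"))
read_faers_table <- function(file, schema = NULL, strict = TRUE) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[!(seq_along(lines) > 1 & lines == "")]
  if (length(lines) == 0L) abort("empty input: no header line found")

  header <- tolower(strsplit(sub("\\$$", "", lines[[1]]), "$", fixed = TRUE)[[1]])
  header <- trimws(header)
  if (!is.null(schema)) {
    missing_cols <- setdiff(tolower(schema), header)
    if (length(missing_cols) > 0) {
      abort(paste0("header is missing required column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
  }
  n_fields <- length(header)

  body <- lines[-1]
  if (length(body) == 0L) {
    out <- as_tibble(setNames(rep(list(character()), n_fields), header))
    return(out)
  }

  # strsplit drops trailing empties, so pad rows that end in "$" back up to
  # the header width; rows short or long after padding are contract violations
  parts <- strsplit(body, "$", fixed = TRUE)
  lens <- lengths(parts)
  trailing <- endsWith(body, "$")
  pad_ok <- trailing & lens >= n_fields - 1L & lens < n_fields
  parts[pad_ok] <- lapply(parts[pad_ok], function(p) c(p, ""))
  lens <- lengths(parts)

  bad <- which(lens != n_fields)
  if (length(bad) > 0) {
    if (strict) {
      abort(sprintf("line %d has %d field(s); header declares %d",
                    bad[[1]] + 1L, lens[[bad[[1]]]], n_fields))
    }
    parts <- parts[-bad]
    inform(sprintf("skipped %d malformed row(s)", length(bad)))
    if (length(parts) == 0) {
      out <- as_tibble(setNames(rep(list(character()), n_fields), header))
      attr(out, "skipped") <- length(bad)
      return(out)
    }
  }

  mat <- matrix(unlist(parts, use.names = FALSE), ncol = n_fields, byrow = TRUE)
  out <- as_tibble(setNames(lapply(seq_len(n_fields), function(j) mat[, j]),
                            header))
  if (!strict) attr(out, "skipped") <- length(bad)
  out
}

#' Deduplicate case reports by the FDA rule
#'
#' Spontaneous reports are versioned: the same case (CASEID) can be
#' resubmitted across quarters under new report identifiers. Within each
#' `caseid`, the record with the latest FDA receipt date (`fda_dt`) is kept;
#' if dates tie, the record with the highest `primaryid` wins.
#'
#' @param reports A data frame with at least `primaryid`, `caseid`, `fda_dt`
#'   (8-digit `YYYYMMDD`) columns, e.g. a parsed DEMO table.
#' @return A tibble with exactly one row per `caseid`, sorted by `caseid`.
#' @export
dedup_reports <- function(reports) {
  reports <- as_tibble(reports)
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(reports)))
  fda <- as.Date(reports$fda_dt, format = "%Y%m%d")
  bad <- which(is.na(fda) | nchar(reports$fda_dt) != 8L)
  if (length(bad) > 0) {
    abort(sprintf(
      "unparseable fda_dt '%s' for primaryid %s (record %d)",
      reports$fda_dt[[bad[[1]]]], reports$primaryid[[bad[[1]]]], bad[[1]]))
  }
  pid <- suppressWarnings(as.numeric(reports$primaryid))
  if (anyNA(pid)) {
    abort(sprintf("non-numeric primaryid '%s'",
                  reports$primaryid[[which(is.na(pid))[[1]]]]))
  }
  reports %>%
    mutate(.fda = fda, .pid = pid) %>%
    group_by(.data$caseid) %>%
    filter(.data$.fda == max(.data$.fda)) %>%
    filter(.data$.pid == max(.data$.pid)) %>%
    ungroup() %>%
    arrange(.data$caseid) %>%
    select(-".fda", -".pid")
}

#' Normalize a drug name for lexicon matching
#'
#' Upper-cases, strips punctuation, collapses internal whitespace, trims.
#'
#' @param x Character vector of verbatim drug names.
#' @return Normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(x)
  x <- gsub("[[:punct:]]", " ", x)
  stringr::str_squish(x)
}

#' Default lexicon for the target drug
#'
#' Brand and generic spellings of azacitidine matched against the primary
#' suspect drug name. The matching is exact on normalized names; supply your
#' own vector to [select_target_reports()] for another drug.
#'
#' @return Character vector of normalized drug names.
#' @export
azacitidine_lexicon <- function() c("AZACITIDINE", "VIDAZA", "ONUREG")

#' Identify reports with the target drug as primary suspect
#'
#' A report qualifies if at least one of its drug rows has role code `PS`
#' (primary suspect) and a normalized drug name in the lexicon. Secondary
#' suspect, concomitant and interacting rows never qualify.
#'
#' @param drugs A data frame with `primaryid`, `role` and `drugname` columns.
#' @param lexicon Character vector of normalized drug names.
#' @return Character vector of qualifying `primaryid` values (unique, sorted).
#' @export
select_target_reports <- function(drugs, lexicon = azacitidine_lexicon()) {
  if (length(lexicon) == 0) abort("lexicon must be non-empty")
  drugs <- as_tibble(drugs)
  hits <- drugs$role == "PS" &
    normalize_drug_name(drugs$drugname) %in% lexicon
  sort(unique(drugs$primaryid[hits]))
}

#' Read a drug lexicon file
#'
#' One drug name per line, UTF-8; names are normalized on read.
#'
#' @param file Path to the lexicon file.
#' @return Character vector of normalized names.
#' @export
read_lexicon <- function(file) {
  x <- readLines(file, warn = FALSE, encoding = "UTF-8")
  x <- normalize_drug_name(x[nzchar(trimws(x))])
  if (length(x) == 0) abort("lexicon file contains no names")
  unique(x)
}

#' Assemble the event universe
#'
#' The counting unit of the analysis is the adverse EVENT: the unique pair of
#' a deduplicated report and a normalized preferred term. Duplicate mentions
#' of a term within one report collapse to a single event. Each event is
#' flagged target/non-target according to whether its report names the target
#' drug as primary suspect. Reactions whose `primaryid` has no report row are
#' dropped (and counted).
#'
#' @param reports Deduplicated report table (see [dedup_reports()]).
#' @param drugs Drug table with `primaryid`, `role`, `drugname`.
#' @param reactions Reaction table with `primaryid`, `pt` columns.
#' @param lexicon Target-drug lexicon (normalized names).
#' @return An object of class `pv_universe`: a list with `reports`, `events`
#'   (tibble `primaryid`, `pt`, `target`), the target report ids, totals, and
#'   the number of orphan reactions dropped.
#' @export
assemble_event_universe <- function(reports, drugs, reactions,
                                    lexicon = azacitidine_lexicon()) {
  reports <- as_tibble(reports)
  reactions <- as_tibble(reactions)
  # restrict to surviving reports: drug rows of removed case versions must
  # not contribute target ids
  target_ids <- intersect(select_target_reports(drugs, lexicon),
                          reports$primaryid)

  known <- reactions$primaryid %in% reports$primaryid
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d reaction row(s) referencing unknown reports",
                   n_dropped))
  }
  events <- reactions[known, , drop = FALSE] %>%
    mutate(pt = normalize_term(.data$pt)) %>%
    distinct(.data$primaryid, .data$pt) %>%
    mutate(target = .data$primaryid %in% target_ids) %>%
    arrange(.data$primaryid, .data$pt)

  structure(
    list(
      reports = reports,
      events = events,
      target_ids = target_ids,
      n_target_events = sum(events$target),
      n_events = nrow(events),
      n_dropped_reactions = n_dropped
    ),
    class = "pv_universe"
  )
}

#' @export
print.pv_universe <- function(x, ...) {
  cat("<pv_universe>\n")
  cat("  reports:      ", nrow(x$reports), "\n")
  cat("  target reports:", length(x$target_ids), "\n")
  cat("  events:       ", x$n_events,
      sprintf("(%d target, %d other)\n",
              x$n_target_events, x$n_events - x$n_target_events))
  if (x$n_dropped_reactions > 0) {
    cat("  orphan reactions dropped:", x$n_dropped_reactions, "\n")
  }
  invisible(x)
}

#' @describeIn assemble_event_universe One row per adverse event
#'   (`primaryid`, `pt`, `target`).
#' @param x A `pv_universe`.
#' @param ... Unused.
#' @export
tidy.pv_universe <- function(x, ...) x$events

#' @describeIn assemble_event_universe One-row summary of the universe
#'   (report, target-report and event totals).
#' @export
glance.pv_universe <- function(x, ...) {
  tibble(
    n_reports = nrow(x$reports),
    n_target_reports = length(x$target_ids),
    n_events = x$n_events,
    n_target_events = x$n_target_events,
    n_other_events = x$n_events - x$n_target_events,
    n_dropped_reactions = x$n_dropped_reactions
  )
}
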