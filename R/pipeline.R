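# One-command orchestration: raw quarterly tables -> deduplicated universe ->
# signal tables (PT and SOC), cohort summary, yearly counts, onset summary and
# cumulative curve, plus a run log of stage counts. Artifacts are CSV with
# fixed sort orders and rounding, so re-runs on identical inputs are
# byte-identical.

#' Pipeline run configuration
#'
#' @param input_dir Directory holding `demo*.txt`, `drug*.txt`, `reac*.txt`,
#'   `ther*.txt`, `outc*.txt` (several quarter files per table are
#'   concatenated before deduplication).
#' @param output_dir Directory for artifacts (created if missing).
#' @param dictionary Path to a PT-to-SOC dictionary file, or a
#'   `pv_dictionary`; defaults to the bundled toy dictionary.
#' @param lexicon Target-drug lexicon (normalized names) or path to a
#'   one-name-per-line file.
#' @param thresholds A [signal_thresholds()] object.
#' @param ic_method IC interval method, `"se"` or `"bcpnn-bayes"`.
#' @param onset_breaks Onset bin edges.
#' @param full_precision If `TRUE`, artifact statistics are written at full
#'   precision instead of 2 decimals.
#' @param verbose Emit progress messages.
#' @return A list of class `pv_run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       dictionary = NULL,
                       lexicon = azacitidine_lexicon(),
                       thresholds = signal_thresholds(),
                       ic_method = "se",
                       onset_breaks = c(0, 30, 60, 90, 120, 180, Inf),
                       full_precision = FALSE,
                       verbose = TRUE) {
  if (is.character(lexicon) && length(lexicon) == 1 && file.exists(lexicon)) {
    lexicon <- read_lexicon(lexicon)
  }
  dict <- if (is.null(dictionary)) {
    toy_dictionary()
  } else if (inherits(dictionary, "pv_dictionary")) {
    dictionary
  } else {
    read_term_dictionary(dictionary)
  }
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 dictionary = dict, lexicon = lexicon,
                 thresholds = thresholds, ic_method = ic_method,
                 onset_breaks = onset_breaks,
                 full_precision = full_precision, verbose = verbose),
            class = "pv_run_config")
}

read_table_set <- function(input_dir, stem) {
  files <- sort(list.files(input_dir, pattern = paste0("^", stem, ".*\\.txt$"),
                           full.names = TRUE))
  if (length(files) == 0) {
    abort(sprintf("missing input file: no '%s*.txt' in %s", stem, input_dir))
  }
  bind_rows(lapply(files, read_faers_table))
}

#' Run the full signal-detection pipeline
#'
#' Parses all quarter files, deduplicates cases, assembles the event
#' universe, and writes: `signal_pt.csv`, `signal_soc.csv`, `cohort.csv`,
#' `yearly_counts.csv`, `onset_summary.csv`, `onset_bins.csv`,
#' `onset_curve.csv` and `run_log.csv` (record counts at each stage) under
#' the configured output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the stage `counts`, artifact `paths` and
#'   the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pv_run_config"))
  say <- function(...) if (config$verbose) inform(sprintf(...))
  if (!dir.exists(config$input_dir)) {
    abort(sprintf("input directory does not exist: %s", config$input_dir))
  }

  demo <- read_table_set(config$input_dir, "demo")
  drug <- read_table_set(config$input_dir, "drug")
  reac <- read_table_set(config$input_dir, "reac")
  ther <- read_table_set(config$input_dir, "ther")
  outc <- read_table_set(config$input_dir, "outc")
  say("parsed %d demo, %d drug, %d reac, %d ther, %d outc rows",
      nrow(demo), nrow(drug), nrow(reac), nrow(ther), nrow(outc))

  reports <- dedup_reports(demo)
  say("deduplicated to %d cases", nrow(reports))
  universe <- assemble_event_universe(reports, drug, reac,
                                      lexicon = config$lexicon)
  if (universe$n_target_events == 0) abort("no target events in the universe")

  sig_pt <- signal_table(universe, "pt", dict = config$dictionary,
                         thresholds = config$thresholds,
                         ic_method = config$ic_method)
  sig_soc <- signal_table(universe, "soc", dict = config$dictionary,
                          thresholds = config$thresholds,
                          ic_method = config$ic_method)

  target_reports <- reports %>% filter(.data$primaryid %in% universe$target_ids)
  cohort <- summarize_cohort(target_reports, outc)
  yearly <- yearly_counts(target_reports)

  onsets <- collect_valid_onsets(universe, ther, drug,
                                 lexicon = config$lexicon)
  valid <- onsets$days[onsets$included]
  onset_sum <- if (length(valid) > 0) {
    summarize_onsets(valid, breaks = config$onset_breaks)
  } else NULL
  curve <- if (length(valid) > 0) cumulative_curve(valid) else NULL

  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  p <- function(f) file.path(config$output_dir, f)
  digits <- if (config$full_precision) NA else 2
  paths <- c(
    signal_pt = write_signal_table(sig_pt, "pt", p("signal_pt.csv"), digits),
    signal_soc = write_signal_table(sig_soc, "soc", p("signal_soc.csv"), digits),
    cohort = p("cohort.csv"),
    yearly = p("yearly_counts.csv"))
  readr::write_csv(cohort, p("cohort.csv"))
  readr::write_csv(yearly, p("yearly_counts.csv"))
  if (!is.null(onset_sum)) {
    readr::write_csv(glance(onset_sum), p("onset_summary.csv"))
    readr::write_csv(onset_sum$bins, p("onset_bins.csv"))
    readr::write_csv(curve, p("onset_curve.csv"))
    paths <- c(paths, onset_summary = p("onset_summary.csv"),
               onset_bins = p("onset_bins.csv"), onset_curve = p("onset_curve.csv"))
  }

  excl <- attr(onsets, "exclusions")
  counts <- tibble(
    stage = c("demo_rows", "drug_rows", "reac_rows", "ther_rows", "outc_rows",
              "deduplicated_reports", "target_reports", "events",
              "target_events", "onset_candidates", "onsets_included",
              "onsets_excluded"),
    n = c(nrow(demo), nrow(drug), nrow(reac), nrow(ther), nrow(outc),
          nrow(reports), length(universe$target_ids), universe$n_events,
          universe$n_target_events, nrow(onsets), sum(onsets$included),
          sum(!onsets$included)))
  readr::write_csv(counts, p("run_log.csv"))
  paths <- c(paths, run_log = p("run_log.csv"))
  say("wrote %d artifacts to %s", length(paths), config$output_dir)

  invisible(list(counts = counts, paths = paths, universe = universe,
                 signal_pt = sig_pt, signal_soc = sig_soc, cohort = cohort,
                 yearly = yearly, onsets = onsets, onset_summary = onset_sum,
                 onset_curve = curve, exclusions = excl))
}

#' Write a signal table artifact
#'
#' Fixed column order and sort (case count descending, ties by term
#' alphabetically); statistics rendered at 2 decimals by default, counts
#' exact.
#'
#' @param results A [disproportionality()] tibble with `term` and `level`
#'   columns.
#' @param level Level label written into the first column.
#' @param path Output CSV path.
#' @param digits Decimal places for statistics (`NA` for full precision).
#' @return The path, invisibly.
#' @export
write_signal_table <- function(results, level, path, digits = 2) {
  stopifnot(nrow(results) > 0)
  stat_cols <- c("ror", "ror_l", "ror_u", "prr", "prr_l", "prr_u",
                 "chi_square", "ic", "ic025", "ebgm", "ebgm05")
  out <- results %>%
    mutate(level = level, case_number = .data$a) %>%
    rename(ror_l = "ror_lower", ror_u = "ror_upper",
           prr_l = "prr_lower", prr_u = "prr_upper",
           chi_square = "chi2", ic025 = "ic_lower",
           ebgm05 = "ebgm_lower") %>%
    arrange(desc(.data$case_number), .data$term) %>%
    select("level", "term", "case_number", "b", "c", "d",
           all_of(stat_cols), "count_pass", "ror_pass", "prr_pass",
           "ic_pass", "ebgm_pass", "significant")
  if (!is.na(digits)) {
    out <- out %>%
      mutate(across(all_of(stat_cols),
                    ~ ifelse(is.na(.x), NA, formatC(.x, format = "f",
                                                    digits = digits))))
  }
  readr::write_csv(out, path)
  invisible(path)
}
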