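# Synthetic spontaneous-reporting database generator. Emits the same
# quarterly dollar-delimited tables the ingest module reads, together with a
# ground-truth ledger, so every pipeline stage is testable without a FAERS
# download. The defaults emulate the reporting profile of a cytotoxic
# haematology drug cohort: ~2.76 events per report, a mostly elderly and male
# cohort reported largely by health professionals, a log-normal onset-time
# distribution with median 36 days, duplicate case submissions across
# quarters, and partially missing dates.

#' Configuration for the synthetic reporting database
#'
#' @param n_reports Number of unique cases before duplicate injection.
#' @param target_share Fraction of reports with the target drug as primary
#'   suspect.
#' @param pt_catalog Tibble with `pt`, `soc`, `prob` (background sampling
#'   weights); defaults to the toy dictionary terms with Zipf-like weights.
#' @param risk_multipliers Named numeric vector: relative reporting-rate
#'   multiplier applied to a PT's weight in target reports. PTs not named
#'   have multiplier 1.
#' @param events_per_report_mean Mean of the zero-truncated Poisson number of
#'   distinct adverse events per report (default 2.759, i.e. 44295/16056).
#' @param duplicate_rate Fraction of cases re-submitted as a newer version.
#' @param missing_start_rate,partial_start_rate Probability a therapy start
#'   date is absent, or truncated to month precision.
#' @param missing_event_rate,partial_event_rate Same for the event date.
#' @param incorrect_onset_rate Probability the recorded event date precedes
#'   the therapy start (an "incorrect" record the onset analysis must drop).
#' @param onset_median_days,onset_sdlog Log-normal onset model: median in
#'   days, standard deviation of the log (1.8 reproduces a Q3/Q1 ratio near
#'   126/11).
#' @param sex_probs,age_probs,reporter_probs,country_probs Categorical
#'   demographic mixes (named probability vectors summing to 1).
#' @param serious_rate Probability a report carries at least one serious
#'   outcome code.
#' @param outcome_probs Per-code probabilities conditional on seriousness
#'   (codes may co-occur).
#' @param n_background_drugs Size of the background drug universe.
#' @return A list of class `pv_generator_config`.
#' @export
generator_config <- function(
    n_reports = 5000,
    target_share = 0.10,
    pt_catalog = NULL,
    risk_multipliers = c(
      "FEBRILE NEUTROPENIA" = 8, "NEUTROPENIA" = 5, "THROMBOCYTOPENIA" = 5,
      "ACUTE MYELOID LEUKAEMIA" = 12, "MYELODYSPLASTIC SYNDROME" = 20,
      "PNEUMONIA" = 4, "SEPSIS" = 4, "PANCYTOPENIA" = 6),
    events_per_report_mean = 44295 / 16056,
    duplicate_rate = 0.05,
    missing_start_rate = 0.30,
    partial_start_rate = 0.10,
    missing_event_rate = 0.25,
    partial_event_rate = 0.05,
    incorrect_onset_rate = 0.02,
    onset_median_days = 36,
    onset_sdlog = 1.8,
    sex_probs = c(F = 0.3253, M = 0.5353, UNK = 0.1394),
    age_probs = c("<18" = 0.0164, "18-44" = 0.0318, "45-64" = 0.1479,
                  ">=65" = 0.5536, "UNK" = 0.2503),
    reporter_probs = c(CN = 0.0803, MD = 0.3769, PH = 0.2439, UNK = 0.0287,
                       LW = 0.0001, OT = 0.2701),
    country_probs = c(US = 0.2640, JP = 0.1228, FR = 0.0766, ES = 0.0659,
                      DE = 0.0605, OTHER = 0.4102),
    serious_rate = 0.9578,
    outcome_probs = c(DE = 6562, LT = 1741, HO = 7075, DS = 289, CA = 5,
                      RI = 29, OT = 7280) / 15379,
    n_background_drugs = 40) {
  if (is.null(pt_catalog)) {
    d <- toy_dictionary()
    w <- 1 / seq_len(nrow(d))
    pt_catalog <- tibble(pt = d$pt, soc = d$soc, prob = w / sum(w))
  }
  cfg <- list(
    n_reports = n_reports, target_share = target_share,
    pt_catalog = as_tibble(pt_catalog), risk_multipliers = risk_multipliers,
    events_per_report_mean = events_per_report_mean,
    duplicate_rate = duplicate_rate,
    missing_start_rate = missing_start_rate,
    partial_start_rate = partial_start_rate,
    missing_event_rate = missing_event_rate,
    partial_event_rate = partial_event_rate,
    incorrect_onset_rate = incorrect_onset_rate,
    onset_median_days = onset_median_days, onset_sdlog = onset_sdlog,
    sex_probs = sex_probs, age_probs = age_probs,
    reporter_probs = reporter_probs, country_probs = country_probs,
    serious_rate = serious_rate, outcome_probs = outcome_probs,
    n_background_drugs = n_background_drugs)
  validate_generator_config(cfg)
  structure(cfg, class = "pv_generator_config")
}

validate_generator_config <- function(cfg) {
  chk <- function(ok, field) if (!ok) abort(paste0("invalid config field: ", field))
  chk(is.numeric(cfg$n_reports) && cfg$n_reports >= 1, "n_reports")
  chk(cfg$target_share > 0 && cfg$target_share <= 1, "target_share")
  chk(all(c("pt", "soc", "prob") %in% names(cfg$pt_catalog)) &&
        all(cfg$pt_catalog$prob >= 0 & cfg$pt_catalog$prob <= 1), "pt_catalog")
  chk(all(cfg$risk_multipliers > 0), "risk_multipliers")
  chk(cfg$events_per_report_mean > 1, "events_per_report_mean")
  for (f in c("duplicate_rate", "missing_start_rate", "partial_start_rate",
              "missing_event_rate", "partial_event_rate",
              "incorrect_onset_rate")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] < 1, f)
  }
  chk(cfg$onset_median_days > 0 && cfg$onset_sdlog > 0, "onset_model")
  for (f in c("sex_probs", "age_probs", "reporter_probs", "country_probs")) {
    chk(abs(sum(cfg[[f]]) - 1) < 1e-6 && all(cfg[[f]] >= 0), f)
  }
  chk(cfg$serious_rate >= 0 && cfg$serious_rate <= 1, "serious_rate")
  chk(all(cfg$outcome_probs >= 0 & cfg$outcome_probs <= 1), "outcome_probs")
  invisible(cfg)
}

# zero-truncated Poisson sample with the given (untruncated) rate via
# inverse-CDF on the truncated distribution
rztpois <- function(n, lambda) {
  f0 <- exp(-lambda)
  stats::qpois(f0 + runif(n) * (1 - f0), lambda)
}

# rate of the untruncated Poisson whose zero-truncated mean is m
ztpois_lambda <- function(m) {
  uniroot(function(l) l / (1 - exp(-l)) - m, c(1e-8, m + 10))$root
}

#' Sample onset durations from the log-normal onset model
#'
#' Day counts are `round(rlnorm(n, log(median_days), sdlog))`, hence
#' non-negative integers with the configured median.
#'
#' @param n Number of draws.
#' @param median_days Median of the log-normal, in days.
#' @param sdlog Standard deviation of the log.
#' @param seed Optional integer seed (local to this call).
#' @return Integer vector of day counts.
#' @export
sample_onsets <- function(n, median_days = 36, sdlog = 1.8, seed = NULL) {
  stopifnot(n >= 1)
  draw <- function() as.integer(round(rlnorm(n, log(median_days), sdlog)))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Inject duplicate case submissions
#'
#' Re-emits a random subset of cases as newer report versions: every table
#' row of a selected case is duplicated under a higher `primaryid`, and the
#' DEMO copy gets a later-or-equal `fda_dt`. The returned ledger designates
#' the survivor the FDA deduplication rule must keep (always the re-emitted
#' version).
#'
#' @param tables Named list of tibbles `demo`, `drug`, `reac`, `ther`,
#'   `outc`.
#' @param rate Fraction of cases to duplicate, in `[0, 1)`.
#' @param seed Optional integer seed (local to this call).
#' @return A list with `tables` (augmented) and `ledger` (tibble `caseid`,
#'   `original_primaryid`, `duplicate_primaryid`, `survivor`).
#' @export
inject_duplicates <- function(tables, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  run <- function() {
    demo <- tables$demo
    pick <- runif(nrow(demo)) < rate
    if (!any(pick)) {
      return(list(tables = tables,
                  ledger = tibble(caseid = character(),
                                  original_primaryid = character(),
                                  duplicate_primaryid = character(),
                                  survivor = character())))
    }
    sel <- demo[pick, , drop = FALSE]
    new_pid <- as.character(as.numeric(sel$primaryid) + 1)
    old_fda <- as.Date(sel$fda_dt, format = "%Y%m%d")
    new_fda <- format(old_fda + sample(0:90, nrow(sel), replace = TRUE),
                      "%Y%m%d")
    map <- tibble(primaryid = sel$primaryid, new_pid = new_pid)
    dup_rows <- function(tb) {
      dup <- tb %>% dplyr::inner_join(map, by = "primaryid") %>%
        mutate(primaryid = .data$new_pid) %>% select(-"new_pid")
      bind_rows(tb, dup)
    }
    demo2 <- sel %>% mutate(primaryid = new_pid, fda_dt = new_fda)
    out <- list(
      demo = bind_rows(demo, demo2),
      drug = dup_rows(tables$drug),
      reac = dup_rows(tables$reac),
      ther = dup_rows(tables$ther),
      outc = dup_rows(tables$outc))
    list(tables = out,
         ledger = tibble(caseid = sel$caseid,
                         original_primaryid = sel$primaryid,
                         duplicate_primaryid = new_pid,
                         survivor = new_pid))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a synthetic spontaneous-reporting database
#'
#' Produces DEMO/DRUG/REAC/THER/OUTC tibbles in the quarterly ASCII dialect
#' (optionally written to disk as dollar-delimited files) plus a ground-truth
#' ledger: the distinct (case, PT) event counts by target status the pipeline
#' must recover after parsing and deduplication, the injected duplicate
#' pairs, and the onset model parameters. The same `config` and `seed` yield
#' byte-identical output.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @param dir Optional directory; when given, `demo.txt` ... `outc.txt` and
#'   `ledger_pt_counts.csv` are written there.
#' @return A list with `tables` (named list of tibbles) and `ledger` (list
#'   with `pt_counts`, `duplicates`, `onset`, `n_reports`, `n_target_reports`).
#' @export
generate_database <- function(config = generator_config(), seed = 1,
                              dir = NULL) {
  validate_generator_config(config)
  withr::with_seed(seed, generate_database_impl(config, dir))
}

generate_database_impl <- function(cfg, dir) {
  n <- as.integer(cfg$n_reports)
  caseid <- as.character(seq_len(n))
  primaryid <- as.character(seq_len(n) * 100 + 1)
  target <- runif(n) < cfg$target_share

  # therapy start and onset define the event date; FDA receipt follows the
  # event after a reporting delay
  start <- as.Date("2004-01-01") +
    sample(0:as.integer(as.Date("2024-06-30") - as.Date("2004-01-01")),
           n, replace = TRUE)
  onset <- sample_onsets(n, cfg$onset_median_days, cfg$onset_sdlog)
  wrong <- runif(n) < cfg$incorrect_onset_rate
  onset[wrong] <- -pmax(1L, abs(onset[wrong]))  # event precedes start
  event <- start + onset
  fda <- pmax(event, start) + sample(0:90, n, replace = TRUE)

  sex <- sample(names(cfg$sex_probs), n, TRUE, cfg$sex_probs)
  band <- sample(names(cfg$age_probs), n, TRUE, cfg$age_probs)
  age_value <- dplyr::case_when(
    band == "<18" ~ as.character(sample(1:17, n, TRUE)),
    band == "18-44" ~ as.character(sample(18:44, n, TRUE)),
    band == "45-64" ~ as.character(sample(45:64, n, TRUE)),
    band == ">=65" ~ as.character(sample(65:90, n, TRUE)),
    TRUE ~ "")
  age_unit <- ifelse(band == "UNK", "", "YR")
  reporter <- sample(names(cfg$reporter_probs), n, TRUE, cfg$reporter_probs)
  country <- sample(names(cfg$country_probs), n, TRUE, cfg$country_probs)

  # date fields as recorded: missing or month-truncated with configured rates
  obscure <- function(full, missing_rate, partial_rate) {
    s <- format(full, "%Y%m%d")
    u <- runif(length(s))
    s[u < missing_rate] <- ""
    part <- u >= missing_rate & u < missing_rate + partial_rate
    s[part] <- substr(s[part], 1, 6)
    s
  }
  event_rec <- obscure(event, cfg$missing_event_rate, cfg$partial_event_rate)
  start_rec <- obscure(start, cfg$missing_start_rate, cfg$partial_start_rate)

  demo <- tibble(
    primaryid = primaryid, caseid = caseid,
    fda_dt = format(fda, "%Y%m%d"), event_dt = event_rec,
    sex = sex, age_value = age_value, age_unit = age_unit,
    reporter = reporter, country = country,
    quarter = paste0(format(fda, "%Y"), "Q", (as.integer(format(fda, "%m")) - 1) %/% 3 + 1))

  # drugs: target reports carry the target drug as PS (verbatim spellings
  # vary); others a background PS drug; a few non-target reports mention the
  # target drug as concomitant only
  spellings <- c("AZACITIDINE", "Vidaza", "azacitidine", "ONUREG", "VIDAZA ")
  bg_names <- sprintf("DRUG_%02d", seq_len(cfg$n_background_drugs))
  ps_name <- ifelse(target, sample(spellings, n, TRUE),
                    sample(bg_names, n, TRUE))
  drug <- tibble(primaryid = primaryid, drug_seq = "1", role = "PS",
                 drugname = ps_name, start_dt = start_rec)
  conc <- !target & runif(n) < 0.02
  if (any(conc)) {
    drug <- bind_rows(drug, tibble(
      primaryid = primaryid[conc], drug_seq = "2", role = "C",
      drugname = "AZACITIDINE", start_dt = ""))
  }

  # adverse events: zero-truncated Poisson count per report, PTs sampled
  # with background weights, multiplied in target reports
  lambda <- ztpois_lambda(cfg$events_per_report_mean)
  k <- rztpois(n, lambda)
  cat_pt <- cfg$pt_catalog$pt
  w_bg <- cfg$pt_catalog$prob
  mult <- rep(1, length(cat_pt))
  idx <- match(names(cfg$risk_multipliers), cat_pt)
  mult[idx[!is.na(idx)]] <- cfg$risk_multipliers[!is.na(idx)]
  w_tg <- w_bg * mult; w_tg <- w_tg / sum(w_tg)

  rep_id <- rep(primaryid, k)
  rep_target <- rep(target, k)
  pts <- character(length(rep_id))
  pts[rep_target] <- sample(cat_pt, sum(rep_target), TRUE, w_tg)
  pts[!rep_target] <- sample(cat_pt, sum(!rep_target), TRUE, w_bg)
  reac <- tibble(primaryid = rep_id, pt = pts)

  ther <- tibble(primaryid = primaryid, dsg_drug_seq = "1",
                 start_dt = start_rec)

  serious <- runif(n) < cfg$serious_rate
  oc <- names(cfg$outcome_probs)
  hit <- matrix(runif(n * length(oc)) <
                  rep(cfg$outcome_probs, each = n), nrow = n)
  hit[!serious, ] <- FALSE
  none <- serious & rowSums(hit) == 0
  hit[none, which(oc == "HO")] <- TRUE  # a serious report carries >= 1 code
  outc <- tibble(primaryid = rep(primaryid, times = rowSums(hit)),
                 outcome = oc[unlist(apply(hit, 1, which), use.names = FALSE)])

  tables <- list(demo = demo, drug = drug, reac = reac, ther = ther,
                 outc = outc)
  dup <- inject_duplicates(tables, cfg$duplicate_rate)
  tables <- dup$tables

  # ground truth: distinct (case, PT) pairs of the pre-duplication database,
  # which is exactly what parsing + deduplication must recover
  pt_counts <- tibble(primaryid = rep_id, pt = normalize_term(pts),
                      target = rep_target) %>%
    distinct(.data$primaryid, .data$pt, .keep_all = TRUE) %>%
    group_by(.data$pt) %>%
    summarise(target_events = sum(.data$target),
              other_events = sum(!.data$target), .groups = "drop")

  ledger <- list(
    pt_counts = pt_counts,
    duplicates = dup$ledger,
    onset = list(median_days = cfg$onset_median_days, sdlog = cfg$onset_sdlog),
    n_reports = n,
    n_target_reports = sum(target))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(tables)) {
      write_faers_table(tables[[nm]], file.path(dir, paste0(nm, ".txt")))
    }
    readr::write_csv(pt_counts, file.path(dir, "ledger_pt_counts.csv"))
    readr::write_csv(dup$ledger, file.path(dir, "ledger_duplicates.csv"))
  }
  list(tables = tables, ledger = ledger)
}

#' Write a table in the dollar-delimited quarterly dialect
#'
#' @param x A data frame (all columns rendered as character).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_faers_table <- function(x, file) {
  header <- paste(names(x), collapse = "$")
  body <- do.call(paste, c(lapply(x, as.character), sep = "$"))
  writeLines(c(header, body), file)
  invisible(file)
}
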