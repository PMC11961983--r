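test_that("dollar-delimited tables parse positionally by header", {
  tb <- read_faers_table("primaryid$caseid$fda_dt\n100$1$20230105")
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$primaryid, "100")
  expect_equal(tb$caseid, "1")
  expect_equal(tb$fda_dt, "20230105")

  expect_equal(nrow(read_faers_table("primaryid$caseid$fda_dt")), 0L)

  # trailing delimiter means an empty final field, not an extra column
  tb2 <- read_faers_table("a$b$c\n1$2$\n4$5$6")
  expect_equal(tb2$c, c("", "6"))

  # unknown extra columns are preserved
  tb3 <- read_faers_table("primaryid$mystery\n1$zzz", schema = "primaryid")
  expect_equal(tb3$mystery, "zzz")
})

test_that("mismatched field counts error with the line number or skip on request", {
  bad <- "a$b$c\n100$1"
  expect_error(read_faers_table(bad), "line 2")
  expect_message(ok <- read_faers_table(bad, strict = FALSE), "skipped 1")
  expect_equal(nrow(ok), 0L)
  expect_equal(attr(ok, "skipped"), 1L)
  expect_error(read_faers_table("a$b\n1$2", schema = c("a", "b", "zz")),
               "missing required")
})

test_that("deduplication keeps the latest FDA date, ties broken by highest primaryid", {
  r <- make_reports(c("1", "2"), caseid = c("A", "A"),
                    fda_dt = c("20230101", "20230601"))
  expect_equal(dedup_reports(r)$primaryid, "2")

  r <- make_reports(c("5", "9"), caseid = c("B", "B"),
                    fda_dt = c("20230101", "20230101"))
  expect_equal(dedup_reports(r)$primaryid, "9")

  r <- make_reports(c("1", "2"), caseid = c("A", "B"))
  expect_equal(nrow(dedup_reports(r)), 2L)

  expect_error(dedup_reports(make_reports("1", fda_dt = "202301")),
               "unparseable fda_dt")
})

test_that("deduplication is idempotent and the survivor maximises (fda_dt, primaryid)", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    r <- make_reports(
      primaryid = sample(1000, n),
      caseid = sample(LETTERS[1:6], n, replace = TRUE),
      fda_dt = format(as.Date("2020-01-01") + sample(0:400, n, TRUE), "%Y%m%d"))
    d1 <- dedup_reports(r)
    expect_identical(dedup_reports(d1), d1)
    expect_false(any(duplicated(d1$caseid)))
    # brute-force survivor: lexicographic max of (fda_dt, numeric primaryid)
    for (cs in unique(r$caseid)) {
      grp <- r[r$caseid == cs, ]
      grp <- grp[order(grp$fda_dt, as.numeric(grp$primaryid)), ]
      expect_equal(d1$primaryid[d1$caseid == cs], grp$primaryid[nrow(grp)])
    }
  }
})

test_that("target selection requires primary-suspect role and a lexicon match", {
  drugs <- tibble::tibble(
    primaryid = c("1", "2", "3", "4"),
    role = c("PS", "C", "PS", "SS"),
    drugname = c("Vidaza", "AZACITIDINE", "azacitidine.", "AZACITIDINE"))
  expect_equal(select_target_reports(drugs), c("1", "3"))
  expect_equal(select_target_reports(drugs, lexicon = "NOSUCHDRUG"),
               character())
  expect_error(select_target_reports(drugs, lexicon = character()),
               "non-empty")
})

test_that("event universe counts unique report-PT pairs with target flags", {
  u <- make_universe(target_pts = list(c("P1", "P1", "P2")),
                     other_pts = list("P1"))
  expect_equal(u$n_events, 3L)
  expect_equal(u$n_target_events, 2L)
  expect_equal(sort(tidy(u)$pt), c("P1", "P1", "P2"))
  expect_equal(u$n_target_events + sum(!u$events$target), u$n_events)

  empty <- make_universe(list(), list())
  expect_equal(empty$n_events, 0L)

  # a reaction for an unknown report id is dropped and counted
  reports <- make_reports("1")
  drugs <- tibble::tibble(primaryid = "1", drug_seq = "1", role = "PS",
                          drugname = "AZACITIDINE", start_dt = "")
  reac <- tibble::tibble(primaryid = c("1", "99"), pt = c("P1", "P2"))
  expect_message(u2 <- assemble_event_universe(reports, drugs, reac),
                 "dropped 1")
  expect_equal(u2$n_events, 1L)
  expect_equal(u2$n_dropped_reactions, 1L)
})

test_that("generated tables round-trip through the parser to the ledger counts", {
  dir <- withr::local_tempdir()
  db <- generate_database(generator_config(n_reports = 300), seed = 7,
                          dir = dir)
  for (nm in names(db$tables)) {
    parsed <- read_faers_table(file.path(dir, paste0(nm, ".txt")))
    expect_equal(nrow(parsed), nrow(db$tables[[nm]]))
    expect_identical(parsed, dplyr::mutate(db$tables[[nm]],
                                           dplyr::across(dplyr::everything(),
                                                         as.character)))
  }
})
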