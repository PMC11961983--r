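test_that("the generator is deterministic given config and seed", {
  cfg <- generator_config(n_reports = 200)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_database(cfg, seed = 5, dir = d1)
  generate_database(cfg, seed = 5, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  a <- generate_database(cfg, seed = 5)
  b <- generate_database(cfg, seed = 6)
  expect_false(identical(a$tables$reac$pt, b$tables$reac$pt))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(generator_config(n_reports = 0), "n_reports")
  expect_error(generator_config(target_share = 0), "target_share")
  expect_error(generator_config(duplicate_rate = 1), "duplicate_rate")
  expect_error(generator_config(risk_multipliers = c(X = -1)),
               "risk_multipliers")
  expect_error(generator_config(sex_probs = c(F = 0.5, M = 0.4)),
               "sex_probs")
})

test_that("duplicate injection adds ledgered rows that deduplication resolves", {
  cfg <- generator_config(n_reports = 1000, duplicate_rate = 0.1)
  db <- generate_database(cfg, seed = 13)
  n_dup <- nrow(db$ledger$duplicates)
  expect_equal(nrow(db$tables$demo), 1000 + n_dup)
  expect_gt(n_dup, 60); expect_lt(n_dup, 140)  # ~Binomial(1000, 0.1)

  kept <- dedup_reports(db$tables$demo)
  expect_equal(nrow(kept), 1000L)
  # every injected pair resolves to the ledger's designated survivor
  led <- db$ledger$duplicates
  expect_true(all(led$survivor %in% kept$primaryid))
  expect_false(any(led$original_primaryid %in% kept$primaryid))
})

test_that("inject_duplicates at rate zero is the identity and its ledger is consistent", {
  db <- generate_database(generator_config(n_reports = 50,
                                           duplicate_rate = 0), seed = 3)
  out <- inject_duplicates(db$tables, rate = 0, seed = 1)
  expect_identical(out$tables, db$tables)
  expect_equal(nrow(out$ledger), 0L)

  out2 <- inject_duplicates(db$tables, rate = 0.5, seed = 2)
  extra <- nrow(out2$tables$demo) - nrow(db$tables$demo)
  expect_equal(extra, nrow(out2$ledger))
})

test_that("sampled onsets are seeded non-negative integers", {
  one <- sample_onsets(1, seed = 8)
  expect_length(one, 1)
  expect_gte(one, 0)
  expect_identical(sample_onsets(50, seed = 8), sample_onsets(50, seed = 8))
  expect_false(identical(sample_onsets(50, seed = 8), sample_onsets(50, seed = 9)))
})

test_that("pipeline counts on synthetic data equal the generator ledger", {
  dir <- withr::local_tempdir()
  db <- generate_database(generator_config(n_reports = 400), seed = 17,
                          dir = dir)
  demo <- read_faers_table(file.path(dir, "demo.txt"))
  drug <- read_faers_table(file.path(dir, "drug.txt"))
  reac <- read_faers_table(file.path(dir, "reac.txt"))
  reports <- dedup_reports(demo)
  expect_equal(nrow(reports), db$ledger$n_reports)
  u <- suppressMessages(assemble_event_universe(reports, drug, reac))
  expect_equal(length(u$target_ids), db$ledger$n_target_reports)

  cells <- build_contingency(u, "pt")
  led <- db$ledger$pt_counts
  merged <- merge(cells, led, by.x = "term", by.y = "pt")
  expect_equal(nrow(merged), nrow(led))
  expect_equal(merged$a, merged$target_events)
  expect_equal(merged$c, merged$other_events)
  expect_equal(u$n_target_events, sum(led$target_events))
})

test_that("with all multipliers at one, significant flags stay rare", {
  set.seed(71)
  cfg <- generator_config(n_reports = 600, target_share = 0.2,
                          risk_multipliers = c(PNEUMONIA = 1),
                          duplicate_rate = 0)
  hits <- 0L; terms <- 0L
  for (s in 1:5) {
    db <- generate_database(cfg, seed = 700 + s)
    u <- suppressMessages(assemble_event_universe(
      dedup_reports(db$tables$demo), db$tables$drug, db$tables$reac))
    sig <- signal_table(u, "pt")
    hits <- hits + sum(sig$significant)
    terms <- terms + nrow(sig)
  }
  expect_lt(hits / terms, 0.05)
})
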