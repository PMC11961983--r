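test_that("ROR point and interval follow the closed form", {
  e <- ror_estimate(10, 90, 100, 9900)
  expect_equal(e$ror, 11)  # ad/bc = 10*9900 / (90*100)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(e$ror_lower, exp(log(11) - 1.96 * se))
  expect_equal(e$ror_upper, exp(log(11) + 1.96 * se))

  expect_equal(ror_estimate(10, 90, 20, 180)$ror, 1)  # proportional table
  expect_true(is.na(ror_estimate(0, 90, 100, 9900)$ror))  # zero cell undefined
})

test_that("PRR point, interval and uncorrected chi-squared follow the closed forms", {
  e <- prr_estimate(10, 90, 100, 9900)
  expect_equal(e$prr, 10)  # (10/100) / (100/10000)
  se <- sqrt(1 / 10 - 1 / 100 + 1 / 100 - 1 / 10000)
  expect_equal(e$prr_lower, exp(log(10) - 1.96 * se))
  # independent oracle for the chi-squared variant
  oracle <- unname(suppressWarnings(
    stats::chisq.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE),
                      correct = FALSE))$statistic)
  expect_equal(e$chi2, oracle)
  expect_equal(round(e$chi2, 1), 74.4)

  prop <- prr_estimate(10, 90, 20, 180)
  expect_equal(prop$prr, 1)
  expect_equal(prop$chi2, 0)
  expect_true(is.na(prr_estimate(10, 90, 0, 9900)$prr))
})

test_that("the information component is the base-2 log of observed/expected", {
  e <- ic_estimate(10, 90, 100, 9900)
  expect_equal(e$ic, log2(9.1818182), tolerance = 1e-6)
  expect_equal(ic_estimate(10, 90, 20, 180)$ic, 0)
  expect_true(is.na(ic_estimate(0, 90, 100, 9900)$ic))

  # the Bayesian closed-form bound shrinks harder at small counts
  se_b <- ic_estimate(3, 97, 300, 99700, method = "se")
  bayes <- ic_estimate(3, 97, 300, 99700, method = "bcpnn-bayes")
  expect_lt(bayes$ic_lower, se_b$ic_lower)
})

test_that("the observed/expected ratio (EBGM as printed) and IC agree exactly", {
  e <- ebgm_estimate(10, 90, 100, 9900)
  expect_equal(e$ebgm, 10 * 10100 / (110 * 100))
  expect_equal(ebgm_estimate(10, 90, 20, 180)$ebgm, 1)

  set.seed(51)
  for (i in 1:200) {
    t <- random_table()
    expect_equal(ic_estimate(t["a"], t["b"], t["c"], t["d"])$ic,
                 log2(ebgm_estimate(t["a"], t["b"], t["c"], t["d"])$ebgm))
  }
})

test_that("estimators agree with textbook formulas on random tables", {
  set.seed(52)
  for (i in 1:200) {
    t <- as.numeric(random_table())
    a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
    expect_equal(ror_estimate(a, b, c, d)$ror, (a / c) / (b / d))
    expect_equal(prr_estimate(a, b, c, d)$prr,
                 (a / (a + b)) / (c / (c + d)))
    oracle <- unname(suppressWarnings(
      stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                        correct = FALSE))$statistic)
    expect_equal(prr_estimate(a, b, c, d)$chi2, oracle)
  }
})

test_that("(ROR-1), (PRR-1), IC and (EBGM-1) share a sign; all increase with a", {
  set.seed(53)
  for (i in 1:100) {
    t <- as.numeric(random_table())
    s <- evaluate_signal(t[1], t[2], t[3], t[4])
    signs <- sign(c(s$ror - 1, s$prr - 1, s$ic, s$ebgm - 1))
    expect_lte(length(unique(signs[signs != 0])), 1L)
  }
  lo <- evaluate_signal(10, 90, 100, 9900)
  hi <- evaluate_signal(20, 90, 100, 9900)
  expect_true(all(c(hi$ror > lo$ror, hi$prr > lo$prr,
                    hi$ic > lo$ic, hi$ebgm > lo$ebgm)))
})

test_that("the combined rule needs the count criterion plus all four algorithms", {
  s <- evaluate_signal(20, 80, 200, 19700)
  expect_equal(round(s$ror, 1), 24.6)
  expect_true(s$significant)
  expect_true(all(unlist(s[c("count_pass", "ror_pass", "prr_pass",
                             "ic_pass", "ebgm_pass")])))

  tiny <- evaluate_signal(2, 8, 20, 1970)
  expect_false(tiny$count_pass)
  expect_false(tiny$significant)

  null <- evaluate_signal(5, 95, 50, 950)
  expect_false(any(unlist(null[c("ror_pass", "prr_pass", "ic_pass",
                                 "ebgm_pass")])))
  expect_false(null$significant)

  # undefined estimates fail their criterion rather than erroring
  zero <- evaluate_signal(0, 100, 50, 950)
  expect_false(zero$significant)
  expect_false(zero$ror_pass)

  # thresholds are configurable
  strict <- evaluate_signal(20, 80, 200, 19700,
                            thresholds = signal_thresholds(min_a = 30))
  expect_false(strict$significant)
  expect_error(signal_thresholds(min_a = Inf), "finite")
})

test_that("under simulated independence the estimates centre on the null", {
  set.seed(54)
  pts <- replicate(300, {
    n1 <- 200; n2 <- 2000; p <- runif(1, 0.05, 0.3)
    a <- rbinom(1, n1, p); c0 <- rbinom(1, n2, p)
    if (a == 0 || c0 == 0) return(c(NA, NA))
    s <- evaluate_signal(a, n1 - a, c0, n2 - c0)
    c(s$ebgm, s$ic)
  })
  expect_equal(median(pts[1, ], na.rm = TRUE), 1, tolerance = 0.1)
  expect_equal(median(pts[2, ], na.rm = TRUE), 0, tolerance = 0.15)
})

test_that("externally aggregated counts reconstruct the 2x2 cells", {
  cells <- counts_to_cells(a = 50, drug_total = 200, term_total = 500,
                           n = 10000)
  expect_equal(unlist(cells, use.names = FALSE), c(50, 150, 450, 9350))
  s <- disproportionality(cells)
  expect_equal(s$ror, (50 / 450) / (150 / 9350))
  expect_error(counts_to_cells(50, 200, 500, 600), "negative cell")
})
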