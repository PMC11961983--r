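test_that("2x2 cells match the brute-force count over the event list", {
  # target events P1 x3, P2 x7; other events P1 x20, P2 x1000
  u <- make_universe(
    target_pts = c(replicate(3, "P1", simplify = FALSE),
                   replicate(7, "P2", simplify = FALSE)),
    other_pts = c(replicate(20, "P1", simplify = FALSE),
                  replicate(1000, "P2", simplify = FALSE)))
  t1 <- build_contingency(u, "pt", terms = "P1")
  expect_equal(unlist(t1[, c("a", "b", "c", "d")], use.names = FALSE),
               c(3, 7, 20, 1000))

  absent <- build_contingency(u, "pt", terms = "NOT A TERM")
  expect_equal(absent$a, 0L)
  expect_equal(absent$c, 0L)
  expect_equal(absent$b, 10L)
  expect_equal(absent$d, 1020L)
})

test_that("a SOC-level table equals the cell-wise sum of its member PTs' classification", {
  d <- term_dictionary(c("P1", "P2", "P3"), 1:3,
                       c("Soc one", "Soc one", "Soc two"), c(1, 1, 2))
  u <- make_universe(
    target_pts = list(c("P1", "P2"), "P1", "P3"),
    other_pts = list("P2", c("P1", "P3"), "P3", "P2"))
  soc <- build_contingency(u, "soc", dict = d, terms = "Soc one")
  ev <- tidy(u)
  member <- ev$pt %in% c("P1", "P2")
  expect_equal(soc$a, sum(ev$target & member))
  expect_equal(soc$c, sum(!ev$target & member))
  expect_error(build_contingency(u, "soc"), "dictionary")
})

test_that("cells agree with brute force and sum to the universe total on random universes", {
  set.seed(31)
  for (i in 1:50) {
    u <- random_universe()
    cells <- build_contingency(u, "pt")
    ev <- tidy(u)
    expect_true(all(cells$a + cells$b + cells$c + cells$d == u$n_events))
    for (j in seq_len(nrow(cells))) {
      oracle <- brute_cells(ev, cells$term[[j]])
      expect_equal(unlist(cells[j, c("a", "b", "c", "d")], use.names = FALSE),
                   as.integer(unlist(oracle)))
    }
  }
})

test_that("a-cells of disjoint PTs add; b-cells do not", {
  u <- make_universe(target_pts = list(c("P1", "P2"), "P1"),
                     other_pts = list("P2"))
  cells <- build_contingency(u, "pt", terms = c("P1", "P2"))
  # P1 and P2 jointly exhaust the target events, so the a-cells add up to the
  # target total while the b-cells (each the complement) cannot
  expect_equal(sum(cells$a), u$n_target_events)
  expect_false(sum(cells$b) == u$n_target_events - sum(cells$a))
})

test_that("margin back-solve inverts the forward statistics", {
  a <- 100; b <- 900; c0 <- 5000; d0 <- 94000
  prr <- (a / (a + b)) / (c0 / (c0 + d0))
  chi2 <- pearson_chi2(a, b, c0, d0)
  sol <- solve_margins(a, a + b, prr, chi2)
  expect_equal(sol$c, c0, tolerance = 1e-3)
  expect_equal(sol$d, d0, tolerance = 1e-3)

  expect_error(solve_margins(10, 100, prr = 1, chi2 = 5), "unidentifiable")
  expect_error(solve_margins(10, 100, prr = 2, chi2 = 0), "positive")
  # chi2 beyond the large-sample asymptote cannot be bracketed
  expect_error(solve_margins(10, 100, prr = 2, chi2 = 1e9), "bracketing")
})

test_that("back-solve round-trips on random tables with PRR away from 1", {
  set.seed(41)
  for (i in 1:40) {
    t <- as.list(random_table())
    t$c <- t$c + 2000  # keep c + d inside the default bracket
    t$d <- t$d + 2000
    prr <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
    if (abs(prr - 1) < 0.05) next
    chi2 <- pearson_chi2(t$a, t$b, t$c, t$d)
    if (chi2 < 1e-6) next
    sol <- solve_margins(t$a, t$a + t$b, prr, chi2)
    expect_equal(sol$c / t$c, 1, tolerance = 1e-3)
    expect_equal(sol$d / t$d, 1, tolerance = 1e-3)
  }
})
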