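# Builders for small in-code fixtures and independent brute-force oracles.
# Oracles use base R only and never call the code paths they check.

make_reports <- function(primaryid, caseid = primaryid,
                         fda_dt = rep("20230101", length(primaryid)),
                         event_dt = rep("", length(primaryid)), ...) {
  tibble::tibble(primaryid = as.character(primaryid),
                 caseid = as.character(caseid),
                 fda_dt = fda_dt, event_dt = event_dt, ...)
}

# universe where each target report lists the given PTs (one report per list
# element); drug assignment goes through the real PS/lexicon path
make_universe <- function(target_pts, other_pts) {
  n_t <- length(target_pts); n_o <- length(other_pts)
  ids <- as.character(seq_len(n_t + n_o))
  reports <- make_reports(ids)
  drugs <- tibble::tibble(
    primaryid = ids, drug_seq = "1", role = "PS",
    drugname = c(rep("AZACITIDINE", n_t), rep("DRUG_X", n_o)),
    start_dt = "")
  reac <- tibble::tibble(
    primaryid = rep(ids, times = c(lengths(target_pts), lengths(other_pts))),
    pt = as.character(unlist(c(target_pts, other_pts), use.names = FALSE)))
  suppressMessages(assemble_event_universe(reports, drugs, reac))
}

# brute-force 2x2 cells from a raw (report, pt, target) event list
brute_cells <- function(events, term) {
  a <- sum(events$target & events$pt == term)
  c <- sum(!events$target & events$pt == term)
  list(a = a, b = sum(events$target) - a,
       c = c, d = sum(!events$target) - c)
}

# random small universe: a handful of reports, PTs drawn with replacement so
# duplicate mentions occur, some reports with no reaction
random_universe <- function() {
  n_t <- sample(2:5, 1); n_o <- sample(3:8, 1)
  pts <- paste0("PT", 1:5)
  draw <- function(n) replicate(n, sample(pts, sample(1:4, 1), replace = TRUE),
                                simplify = FALSE)
  make_universe(draw(n_t), draw(n_o))
}

# random strictly positive 2x2 table
random_table <- function(max_cell = 500) {
  c(a = sample(1:50, 1), b = sample(1:max_cell, 1),
    c = sample(1:max_cell, 1), d = sample(1:(10 * max_cell), 1))
}
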