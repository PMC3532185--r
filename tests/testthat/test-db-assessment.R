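test_that("window membership honours openness flags", {
  w_open <- detection_window(500, Inf)
  peps <- data.frame(sequence = "X", mono_mass = c(500.0, 500.1, NA))
  kept <- peptide_window_filter(peps, w_open)
  expect_equal(kept$mono_mass, 500.1)  # boundary excluded, NA never passes
  expect_equal(attr(kept, "n_undefined_mass"), 1L)

  w_closed <- detection_window(500, Inf, lower_open = FALSE)
  expect_equal(peptide_window_filter(peps, w_closed)$mono_mass, c(500.0, 500.1))

  w_all <- detection_window(0, Inf)
  expect_equal(nrow(peptide_window_filter(peps, w_all)), 2L)
})

test_that("digest of MKWVTFRK filters to the hand-computed in-window subset", {
  dg <- peptide_physchem(digest_database(make_db("MKWVTFRK"), max_missed = 1))
  w <- detection_window(500, 5000)
  kept <- peptide_window_filter(dg$peptides, w)
  manual <- vapply(dg$peptides$sequence, oracle_mass, 0)
  expect_setequal(kept$sequence,
                  dg$peptides$sequence[manual > 500 & manual < 5000])
  # MK (277.1), K (146.1) fall below; the three longer peptides pass
  expect_setequal(kept$sequence, c("MKWVTFR", "WVTFR", "WVTFRK"))
})

test_that("proteins_below_peptide_threshold isolates undetectable proteins", {
  # A: both peptides inside (500,1000); B: both outside; C: mixed
  db <- make_db(c("WWWWKWWWWK",
                  "WWWWWWWWWWKWWWWWWWWWWK",
                  "WWWWKWWWWWWWWWWK"),
                acc = c("A", "B", "C"))
  dg <- peptide_physchem(digest_database(db, max_missed = 0))
  w <- detection_window(500, 1000)
  expect_equal(proteins_below_peptide_threshold(dg, w, k = 0), "B")
  expect_setequal(proteins_below_peptide_threshold(dg, w, k = 1), c("B", "C"))
  # brute-force recount per protein
  for (acc in c("A", "B", "C")) {
    m <- vapply(dg$peptides$sequence[dg$peptides$accession == acc], oracle_mass, 0)
    n_in <- sum(m > 500 & m < 1000)
    expect_equal(acc %in% proteins_below_peptide_threshold(dg, w, 0), n_in == 0)
  }
  # a window below every peptide mass lists every protein
  tiny <- detection_window(0, 100)
  expect_setequal(proteins_below_peptide_threshold(dg, tiny, 0), c("A", "B", "C"))
})

test_that("window_scan equals a brute-force recount on a synthetic database", {
  gen <- generate_database(synthetic_db_params(n_proteins = 200L, seed = 5L))
  dg <- peptide_physchem(digest_database(gen$db, max_missed = 1))
  windows <- default_detection_windows()
  ks <- 0:3
  scan <- window_scan(dg, windows, ks)
  peps <- dg$peptides
  for (w in windows) {
    lbl <- if (is.infinite(w$upper)) paste0(">", format(w$lower)) else
      paste0(format(w$lower), "<x<", format(w$upper))
    for (k in ks) {
      # independent recount straight off the peptide table
      counts <- tapply(!is.na(peps$mono_mass) &
                         peps$mono_mass > w$lower & peps$mono_mass < w$upper,
                       peps$accession, sum)
      want <- sort(names(counts)[counts <= k])
      got <- scan$accessions[[lbl]][[as.character(k)]]
      expect_equal(got, want)
      expect_equal(scan$counts$n_proteins[scan$counts$window == lbl &
                                            scan$counts$k == k],
                   length(want))
    }
  }
  # monotonicity in k; anti-monotonicity in window width
  for (lbl in names(scan$accessions)) {
    n_by_k <- scan$counts$n_proteins[scan$counts$window == lbl]
    expect_true(all(diff(n_by_k[order(scan$counts$k[scan$counts$window == lbl])]) >= 0))
  }
  narrow <- scan$counts$n_proteins[scan$counts$window == "500<x<3000"]
  wide <- scan$counts$n_proteins[scan$counts$window == "500<x<5000"]
  expect_true(all(wide <= narrow))
})

test_that("disjoint windows covering (0, Inf) partition the defined-mass peptides", {
  dg <- peptide_physchem(digest_database(
    generate_database(synthetic_db_params(n_proteins = 30L, seed = 8L))$db,
    max_missed = 1))
  cover <- list(detection_window(0, 500, upper_open = FALSE),
                detection_window(500, 1000, upper_open = FALSE),
                detection_window(1000, Inf))
  n_in <- vapply(cover, function(w) nrow(peptide_window_filter(dg$peptides, w)), 0L)
  expect_equal(sum(n_in), sum(!is.na(dg$peptides$mono_mass)))
})

test_that("pi_distribution bins, thresholds and conservation behave", {
  h <- pi_distribution(rep(6.25, 10), bin_edges = 0:14)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$fraction[h$counts > 0], 1)

  h2 <- pi_distribution(c(1, 2, NA, 13.5), bin_edges = 0:14, thresholds = c(5, 8))
  expect_equal(sum(h2$counts) + h2$n_excluded, 4L)
  expect_equal(unname(h2$below), c(2 / 3, 2 / 3))

  set.seed(31)
  vals <- ifelse(rbinom(10000, 1, 0.30) == 1, runif(10000, 3, 5), runif(10000, 5, 9))
  h3 <- pi_distribution(vals, bin_edges = 0:14, thresholds = 5)
  se <- sqrt(0.30 * 0.70 / 10000)
  expect_lt(abs(h3$below[["5"]] - 0.30), 3 * se)

  # empty threshold list: histogram only
  expect_length(pi_distribution(vals, 0:14)$below, 0L)
})

test_that("database_fractions rounds half away from zero at two decimals", {
  expect_equal(database_fractions(113, 13117), 0.86)
  expect_equal(database_fractions(0, 10), 0)
  expect_equal(database_fractions(10, 10), 100)
  expect_equal(database_fractions(1, 800), 0.13)  # 0.125 rounds up, not to even
  expect_error(database_fractions(1, 0), "denominator")
})
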