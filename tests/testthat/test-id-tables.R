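toy_reps <- function() {
  r <- function(codes, ng, fmol = ng * 20) {
    data.frame(uniprot_code = codes,
               description = paste("Protein", codes),
               protein_mw = 50000, score = 1000, products = 50,
               peptides = 10, fmol = fmol, ng = ng,
               stringsAsFactors = FALSE)
  }
  list(r(c("P1", "P2", "P3"), c(10, 5, 1)),
       r(c("P1", "P2"), c(10, 7)),
       r(c("P1", "P2", "P4"), c(10, 6, 2)),
       r(c("P1", "P2"), c(10, 6)))
}

test_that("read_protein_table autodetects delimiters and synonyms", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Uniprot code,Description,ScoreAVG,PeptidesAVG,NgramAVG,Extra",
               "P1,Glycinin G1,100.5,12,3.5,keepme",
               "P2,Lectin,88,4,,x"), f)
  tab <- read_protein_table(f)
  expect_equal(names(tab)[1:5],
               c("uniprot_code", "description", "score", "peptides", "ng"))
  expect_equal(tab$ng, c(3.5, NA))  # empty ng is absent, not zero
  expect_equal(tab$Extra, c("keepme", "x"))

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("Uniprot code,Description,ScoreAVG,PeptidesAVG",
               "P1,x,1,2"), f2)
  expect_error(read_protein_table(f2), "ng")

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("Uniprot code,Description,ScoreAVG,PeptidesAVG,NgramAVG",
               "P1,x,abc,2,1"), f3)
  expect_error(read_protein_table(f3), "row 1")

  f4 <- tempfile(fileext = ".csv")
  writeLines("Uniprot code,Description,ScoreAVG,PeptidesAVG,NgramAVG", f4)
  expect_warning(tab4 <- read_protein_table(f4), "header-only")
  expect_equal(nrow(tab4), 0L)
})

test_that("the packaged fixture loads as the published 113-row table", {
  tab <- fixture_table1()
  expect_s3_class(tab, "merged_table")
  expect_equal(nrow(tab), 113L)
  expect_equal(tab$uniprot_code[1], "P04776")
  expect_equal(names(tab)[1:10],
               c("uniprot_code", "description", "protein_mw", "score_avg",
                 "products_avg", "peptides_avg", "fmol_variation", "ng_avg",
                 "repeat_rate", "pct_tsp"))
  expect_equal(sum(is.na(tab$fmol_variation)), 20L)  # blank cells preserved
  expect_true(all(tab$repeat_rate >= attr(tab, "min_repeat")))
})

test_that("merge_replicates averages, filters and orders deterministically", {
  reps <- toy_reps()
  m <- merge_replicates(reps, min_repeat = 2)
  expect_equal(m$uniprot_code, c("P1", "P2"))  # P3, P4 seen once -> dropped
  p1 <- m[m$uniprot_code == "P1", ]
  expect_equal(p1$repeat_rate, 4L)
  expect_equal(p1$ng_avg, 10)
  expect_equal(p1$fmol_variation, 0)  # constant replicates
  p2 <- m[m$uniprot_code == "P2", ]
  expect_equal(p2$ng_avg, 6)
  expect_equal(p2$fmol_variation, sd(c(100, 140, 120, 120)) / 120)

  # permutation invariance in replicate order
  m2 <- merge_replicates(rev(reps), min_repeat = 2)
  expect_equal(as.data.frame(m2), as.data.frame(m))
  # raising min_repeat is a monotone filter
  m1 <- merge_replicates(reps, min_repeat = 1)
  expect_true(all(m$uniprot_code %in% m1$uniprot_code))
  expect_equal(merge_replicates(reps, 4)$uniprot_code, c("P1", "P2"))
  expect_error(merge_replicates(reps, 5), "min_repeat")
})

test_that("percent_tsp normalises to 100 with absent-ng rows excluded", {
  base <- data.frame(uniprot_code = c("A", "B", "C"),
                     description = "x", ng_avg = c(3, 1, NA))
  t <- percent_tsp(base)
  expect_equal(t$pct_tsp, c(75, 25, NA))
  expect_equal(sum(t$pct_tsp_full, na.rm = TRUE), 100)
  expect_equal(percent_tsp(data.frame(uniprot_code = "A", description = "x",
                                      ng_avg = 7))$pct_tsp, 100)
  expect_error(percent_tsp(data.frame(uniprot_code = "A", description = "x",
                                      ng_avg = NA_real_)), "ng")
})

test_that("fixture %TSP recomputes to the printed column", {
  tab <- fixture_table1()
  t <- percent_tsp(tab)
  expect_equal(t$pct_tsp[t$uniprot_code == "P04776"], 17.68)
  expect_true(all(abs(t$pct_tsp - tab$pct_tsp) <= 0.01 + 1e-12, na.rm = TRUE))
  expect_equal(sum(t$pct_tsp_full, na.rm = TRUE), 100)
  # rounded shares stay within the 113-row rounding bound of 100
  expect_lt(abs(sum(t$pct_tsp, na.rm = TRUE) - 100), 0.57)
})

test_that("repeat-rate summary partitions the table", {
  tab <- fixture_table1()
  rr <- repeat_rate_summary(tab)
  expect_equal(sum(rr$counts), nrow(tab))
  expect_equal(rr$counts[["4"]], 98L)
  expect_equal(rr$percent[["4"]], 87)
  all4 <- data.frame(uniprot_code = letters[1:5], repeat_rate = 4L)
  expect_equal(repeat_rate_summary(all4)$percent[["4"]], 100)
})

test_that("dynamic range counts complete decades of positive abundance", {
  expect_equal(dynamic_range_logs(c(1, 10, 1000))$decades, 3L)
  expect_equal(dynamic_range_logs(c(5, 5))$decades, 0L)
  expect_equal(dynamic_range_logs(c(0, 1, 99))$decades, 1L)  # zeros excluded
  expect_error(dynamic_range_logs(c(0, 0)), "positive")
  tab <- fixture_table1()
  dr <- dynamic_range_logs(tab)
  expect_equal(dr$min_positive, 0.04)
  expect_equal(dr$decades, 3L)
})

test_that("keyword TSP shares sum with their complement to the total", {
  t <- percent_tsp(fixture_table1())
  kw <- keyword_tsp_share(t, "glycinin")
  expect_equal(kw$share, 78L)
  expect_equal(nrow(kw$matched), 41L)
  expect_equal(keyword_tsp_share(t, "zzz_no_such")$share, 0L)
  expect_equal(keyword_tsp_share(t, "")$share, 100L)
  # complement property at full precision
  anti <- sum(t$pct_tsp_full[!grepl("glycinin", t$description, ignore.case = TRUE)],
              na.rm = TRUE)
  expect_equal(kw$share_full + anti, 100)
})

test_that("functional classification is ordered, deterministic and total", {
  t <- percent_tsp(fixture_table1())
  cf <- classify_function(t)
  expect_equal(nrow(cf$table), nrow(t))
  kunitz <- cf$table$category[grepl("Kunitz trypsin inhibitor", cf$table$description)]
  expect_true(all(kunitz == "defense"))
  expect_error(classify_function(t, data.frame()), "ruleset")
  # planted category mix recovers exactly
  synth <- percent_tsp(data.frame(
    uniprot_code = sprintf("S%d", 1:10),
    description = c(rep("Glycinin G1", 4), rep("Kunitz trypsin inhibitor", 3),
                    rep("Totally novel thing", 3)),
    ng_avg = rep(1, 10)))
  cs <- classify_function(synth)
  expect_equal(cs$by_rows[["storage"]], 40)
  expect_equal(cs$by_rows[["defense"]], 30)
  expect_equal(cs$by_rows[["uncharacterized/other"]], 30)
})

test_that("match-type and ppm summaries enforce the closed vocabulary", {
  hits <- data.frame(match_type = rep("PepFrag1", 5),
                     ppm_error = c(-4.9, 0, 2, 4.9, 5.1),
                     parent_code = "P1")
  mt <- match_type_summary(hits)
  expect_equal(mt$percent[["PepFrag1"]], 100)
  expect_equal(sum(mt$counts), 5L)
  expect_error(match_type_summary(data.frame(match_type = "Mystery",
                                             ppm_error = 0)), "unknown match type")
  # strict |e| < 5: 4.9 in, 5.1 out
  two <- data.frame(match_type = "PepFrag1", ppm_error = c(4.9, 5.1))
  expect_equal(ppm_histogram(two, 5)$fraction_within, 0.5)

  pp <- per_protein_distributions(
    data.frame(match_type = "PepFrag1", ppm_error = 0,
               parent_code = rep(c("A", "B"), c(12, 3))),
    coverage = c(45, 20))
  expect_equal(unname(pp$peptides_per_protein), c(12L, 3L))
  expect_equal(pp$fraction_at_least_min_peptides, 0.5)
  expect_equal(pp$fraction_above_min_coverage, 0.5)
})
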