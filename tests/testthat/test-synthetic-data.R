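test_that("database generation is seeded, deterministic and validated", {
  p <- synthetic_db_params(n_proteins = 10L, duplicate_fraction = 0.2, seed = 1L)
  gen <- generate_database(p)
  expect_equal(nrow(gen$db), 10L)
  expect_length(gen$manifest$duplicate_parent, 2L)
  groups <- find_duplicate_sequences(gen$db)
  expect_setequal(unlist(groups),
                  unique(c(names(gen$manifest$duplicate_parent),
                           unname(gen$manifest$duplicate_parent))))

  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(generate_database(p)$db, f1)
  write_fasta(generate_database(p)$db, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical

  plain <- generate_database(synthetic_db_params(n_proteins = 50L, seed = 3L))
  expect_length(find_duplicate_sequences(plain$db), 0L)
  expect_error(synthetic_db_params(duplicate_fraction = 0.6,
                                   fragment_fraction = 0.5), "fraction")
})

test_that("fragment entries are proper truncations of their parents", {
  gen <- generate_database(synthetic_db_params(
    n_proteins = 40L, fragment_fraction = 0.25, seed = 21L))
  fp <- gen$manifest$fragment_parent
  expect_length(fp, 10L)
  for (frag in names(fp)) {
    child <- gen$db$sequence[gen$db$accession == frag]
    parent <- gen$db$sequence[gen$db$accession == fp[[frag]]]
    expect_true(grepl(child, parent, fixed = TRUE))
    expect_lt(nchar(child), nchar(parent))
    expect_match(gen$db$description[gen$db$accession == frag], "Fragment")
  }
})

test_that("replicate generation respects planted detection structure", {
  db <- generate_database(synthetic_db_params(n_proteins = 30L, seed = 2L))$db
  # detection probability 1: every true protein at full repeat rate
  run <- generate_replicates(db, synthetic_run_params(
    n_true_proteins = 20L, n_peptides = 400L, detection_prob = 1, seed = 5L))
  expect_true(all(run$manifest$repeat_rates == 4L))
  m <- merge_replicates(run, min_repeat = 2)
  expect_equal(nrow(m), 20L)
  expect_true(all(m$repeat_rate == 4L))

  # direct-assignment mode plants rates exactly
  rates <- rep(c(4L, 3L, 2L, 1L), each = 5L)
  run2 <- generate_replicates(db, synthetic_run_params(
    n_true_proteins = 20L, n_peptides = 400L, repeat_rates = rates, seed = 6L))
  m2 <- merge_replicates(run2, min_repeat = 1)
  got <- repeat_rate_summary(m2)$counts
  expect_equal(unname(got[as.character(1:4)]), rep(5L, 4))
})

test_that("protein and peptide tables are mutually consistent", {
  db <- generate_database(synthetic_db_params(n_proteins = 50L, seed = 4L))$db
  run <- generate_replicates(db, synthetic_run_params(
    n_true_proteins = 40L, n_peptides = 1000L, seed = 9L))
  expect_equal(nrow(run$peptide_hits), 1000L)  # conservation of draws
  for (r in seq_along(run$replicates)) {
    tab <- run$replicates[[r]]
    hits_r <- run$peptide_hits[run$peptide_hits$replicate_id == r, ]
    # a protein appears in the table iff at least one of its peptides does
    expect_setequal(tab$uniprot_code, unique(hits_r$parent_code))
    counts <- table(hits_r$parent_code)
    expect_equal(unname(tab$peptides),
                 as.integer(counts[tab$uniprot_code]))
    expect_true(all(tab$peptides >= 1L))
  }
  # identical seed reruns identically
  run_b <- generate_replicates(db, synthetic_run_params(
    n_true_proteins = 40L, n_peptides = 1000L, seed = 9L))
  expect_identical(run$peptide_hits, run_b$peptide_hits)
})

test_that("infeasible run parameters error out", {
  db <- generate_database(synthetic_db_params(n_proteins = 10L, seed = 1L))$db
  expect_error(generate_replicates(db, synthetic_run_params(n_true_proteins = 20L)),
               "exceeds")
  expect_error(synthetic_run_params(fraction_pepfrag1 = 0.9,
                                    fraction_in_source = 0.2), "sum")
  expect_error(generate_replicates(db, synthetic_run_params(
    n_true_proteins = 10L, n_peptides = 10L, detection_prob = 1)), "n_peptides")
})

test_that("ppm sigma is solved from the coverage target", {
  p <- synthetic_run_params(ppm_within_target = 0.82, ppm_threshold = 5)
  # by construction P(|N(0, sd)| < 5) = 0.82
  expect_equal(2 * pnorm(5, sd = p$ppm_sd) - 1, 0.82, tolerance = 1e-12)
})
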