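# Independent oracles used across the suite. Deliberately written from
# first principles (loops over characters, all-substring enumeration,
# grid search) so they share no code path with the package.

# residue monoisotopic masses, restated independently of the packaged table
ORACLE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

oracle_mass <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  if (!all(res %in% names(ORACLE_MONO))) return(NA_real_)
  sum(ORACLE_MONO[res]) + 18.0105646
}

oracle_sites <- function(seq, cut_after = c("K", "R"), suppress = "P",
                         apply_suppression = TRUE) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  sites <- integer()
  for (i in seq_len(max(0L, n - 1L))) {
    if (res[i] %in% cut_after &&
        !(apply_suppression && res[i + 1L] %in% suppress)) {
      sites <- c(sites, i)
    }
  }
  sites
}

# all-substring enumeration: keep [s, e] iff both boundaries are termini or
# cleavage sites and the number of spanned internal sites is <= max_missed
oracle_digest <- function(seq, max_missed, ...) {
  n <- nchar(seq)
  sites <- oracle_sites(seq, ...)
  starts_ok <- c(0L, sites)  # s - 1 must be a boundary
  ends_ok <- c(sites, n)
  out <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (!(s - 1L) %in% starts_ok || !e %in% ends_ok) next
      spanned <- sum(sites > s - 1L & sites < e)
      if (spanned <= max_missed) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = e, sequence = substr(seq, s, e),
          missed_cleavages = spanned)
      }
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), ]
}

# 1e-4-step grid search for the zero of the net-charge equation
oracle_pi <- function(seq, pks) {
  res <- strsplit(seq, "")[[1]]
  cnt <- function(a) sum(res == a)
  ph <- seq(0, 14, by = 1e-4)
  q <- 1 / (1 + 10^(ph - pks[["nterm"]])) +
    cnt("K") / (1 + 10^(ph - pks[["K"]])) +
    cnt("R") / (1 + 10^(ph - pks[["R"]])) +
    cnt("H") / (1 + 10^(ph - pks[["H"]])) -
    1 / (1 + 10^(pks[["cterm"]] - ph)) -
    cnt("D") / (1 + 10^(pks[["D"]] - ph)) -
    cnt("E") / (1 + 10^(pks[["E"]] - ph)) -
    cnt("C") / (1 + 10^(pks[["C"]] - ph)) -
    cnt("Y") / (1 + 10^(pks[["Y"]] - ph))
  ph[which.min(abs(q))]
}

random_protein <- function(len, letters = names(ORACLE_MONO)) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

make_db <- function(seqs, acc = sprintf("T%03d", seq_along(seqs))) {
  protein_db(data.frame(accession = acc, sequence = seqs,
                        stringsAsFactors = FALSE), source_label = "test")
}
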