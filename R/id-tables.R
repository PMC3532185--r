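# Parsing, merging and summarising replicated label-free protein
# identification tables.
#
# A merged table is a data.frame (class "merged_table") with columns
#   uniprot_code, description, protein_mw, score_avg, products_avg,
#   peptides_avg, fmol_variation, ng_avg, repeat_rate, pct_tsp
# plus pct_tsp_full (unrounded), and attributes n_replicates / min_repeat.

#' Closed vocabulary of peptide match types
#'
#' First-pass and second-pass database matches, variable-modification
#' matches, in-source fragmentation, missed-cleavage matches, and water /
#' ammonia neutral losses. Unknown strings on input are an error, never a
#' silent "other".
#' @export
MATCH_TYPES <- c("PepFrag1", "PepFrag2", "VarMod", "InSource",
                 "MissedCleavage", "NeutralLoss_H2O", "NeutralLoss_NH3")

# header-synonym map after normalisation (lowercase, alnum only)
.col_synonyms <- list(
  uniprot_code = c("uniprotcode", "accession", "uniprot", "code", "entry"),
  description = c("description", "desc", "proteinname"),
  protein_mw = c("proteinmw", "mw", "mwda"),
  score = c("score", "scoreavg"),
  products = c("products", "productsavg"),
  peptides = c("peptides", "peptidesavg"),
  fmol = c("fmol", "fmolcovariance", "fmolvariation", "fmolcv"),
  ng = c("ng", "ngram", "ngramavg", "ngavg", "nanograms"),
  repeat_rate = c("repeatrate", "repeaterate"),
  pct_tsp = c("pcttsp", "oftsp", "tsp", "percentoftsp")
)

#' Read a protein identification table
#'
#' Accepts comma- or tab-delimited text (auto-detected from the header
#' line) with a header row. Column names are matched case-insensitively
#' against common synonyms (e.g. `ScoreAVG` -> `score`, `NgramAVG` ->
#' `ng`); extra columns are preserved untouched. At minimum
#' `uniprot_code`, `description`, `score`, `peptides` and `ng` must be
#' present. Empty ng cells are read as `NA` (absent, not zero).
#'
#' @param path file path.
#' @return data.frame with canonical column names.
#' @export
read_protein_table <- function(path) {
  if (!file.exists(path)) stop_ctx("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  norm <- tolower(gsub("[^A-Za-z]", "", names(tab)))
  canon <- names(tab)
  for (target in names(.col_synonyms)) {
    hit <- which(norm %in% .col_synonyms[[target]])
    if (length(hit)) canon[hit[1]] <- target
  }
  names(tab) <- canon
  mandatory <- c("uniprot_code", "description", "score", "peptides", "ng")
  missing_cols <- setdiff(mandatory, names(tab))
  if (length(missing_cols)) {
    stop_ctx("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    warning("header-only table: ", path, call. = FALSE)
  }
  numeric_cols <- intersect(c("protein_mw", "score", "products", "peptides",
                              "fmol", "ng", "repeat_rate", "pct_tsp"),
                            names(tab))
  for (col in numeric_cols) {
    raw <- trimws(tab[[col]])
    raw[raw == ""] <- NA
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      stop_ctx("non-numeric value in column '", col, "' at row ", bad[1],
               ": '", raw[bad[1]], "'")
    }
    tab[[col]] <- val
  }
  tab
}

as_merged_table <- function(tab, n_replicates, min_repeat) {
  structure(tab, class = c("merged_table", "data.frame"),
            n_replicates = n_replicates, min_repeat = min_repeat)
}

#' @export
print.merged_table <- function(x, ...) {
  cat(sprintf("merged_table: %d proteins (R = %s, min repeat rate = %s)\n",
              nrow(x), attr(x, "n_replicates") %||% "?",
              attr(x, "min_repeat") %||% "?"))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...", nrow(x) - 5, "more rows\n")
  invisible(x)
}

#' Merge per-replicate identification tables
#'
#' For every protein observed in any replicate: the repeat rate is the
#' number of replicates containing it; score/products/peptides/ng are
#' arithmetic means over the replicates where present; `fmol_variation`
#' is the coefficient of variation (sd/mean) of per-replicate fmol, blank
#' when fewer than two observations. Proteins with repeat rate below
#' `min_repeat` are dropped. Rows are sorted by `ng_avg` descending with
#' `uniprot_code` as the tie-break, so output order is deterministic and
#' invariant to replicate order.
#'
#' @param reps list of per-replicate data.frames (as from
#'   [read_protein_table()]), or a `replicate_set` from
#'   [generate_replicates()].
#' @param min_repeat minimum repeat rate kept (1 <= min_repeat <= R).
#' @return a merged table; `pct_tsp` is not yet computed (see
#'   [percent_tsp()]).
#' @export
merge_replicates <- function(reps, min_repeat = 2L) {
  if (inherits(reps, "replicate_set")) reps <- reps$replicates
  stopifnot(is.list(reps), length(reps) >= 1L)
  R <- length(reps)
  if (min_repeat < 1L || min_repeat > R) {
    stop_ctx("min_repeat must be between 1 and the number of replicates (", R, ")")
  }
  for (i in seq_along(reps)) {
    stopifnot(is.data.frame(reps[[i]]))
    if (anyDuplicated(reps[[i]]$uniprot_code)) {
      stop_ctx("duplicate uniprot_code within replicate ", i)
    }
  }
  all_codes <- unique(unlist(lapply(reps, `[[`, "uniprot_code")))
  pull <- function(code, col) {
    vals <- vapply(reps, function(r) {
      i <- match(code, r$uniprot_code)
      if (is.na(i) || !col %in% names(r)) NA_real_ else as.numeric(r[[col]][i])
    }, 0)
    vals[!is.na(vals)]
  }
  first_chr <- function(code, col) {
    for (r in reps) {
      i <- match(code, r$uniprot_code)
      if (!is.na(i) && col %in% names(r) && nzchar(r[[col]][i] %||% "")) {
        return(as.character(r[[col]][i]))
      }
    }
    ""
  }
  rows <- lapply(all_codes, function(code) {
    present <- vapply(reps, function(r) code %in% r$uniprot_code, TRUE)
    fmol <- pull(code, "fmol")
    ng <- pull(code, "ng")
    data.frame(
      uniprot_code = code,
      description = first_chr(code, "description"),
      protein_mw = if (length(pull(code, "protein_mw"))) pull(code, "protein_mw")[1] else NA_real_,
      score_avg = mean(pull(code, "score")),
      products_avg = if (length(pull(code, "products"))) mean(pull(code, "products")) else NA_real_,
      peptides_avg = mean(pull(code, "peptides")),
      fmol_variation = if (length(fmol) >= 2L && mean(fmol) != 0) sd(fmol) / mean(fmol) else NA_real_,
      ng_avg = if (length(ng)) mean(ng) else NA_real_,
      repeat_rate = sum(present),
      pct_tsp = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  merged <- do.call(rbind, rows)
  merged <- merged[merged$repeat_rate >= min_repeat, , drop = FALSE]
  ord <- order(-ifelse(is.na(merged$ng_avg), -Inf, merged$ng_avg),
               merged$uniprot_code)
  merged <- merged[ord, , drop = FALSE]
  rownames(merged) <- NULL
  as_merged_table(merged, n_replicates = R, min_repeat = min_repeat)
}

#' Compute percent of total soluble protein
#'
#' `pct_tsp = 100 * ng_avg / sum(ng_avg)` over the rows carrying a ng
#' value; rows with absent ng are kept with blank `pct_tsp` and excluded
#' from both numerator and denominator. The reported column is rounded
#' half-away-from-zero to two decimals; `pct_tsp_full` retains full
#' precision (unrounded shares sum to exactly 100).
#'
#' @param table a merged table with `ng_avg`.
#' @return the table with `pct_tsp` and `pct_tsp_full` filled in.
#' @export
percent_tsp <- function(table) {
  stopifnot(is.data.frame(table), "ng_avg" %in% names(table))
  has_ng <- !is.na(table$ng_avg)
  total <- sum(table$ng_avg[has_ng])
  if (!any(has_ng) || total <= 0) stop_ctx("no positive ng values to normalise by")
  full <- rep(NA_real_, nrow(table))
  full[has_ng] <- 100 * table$ng_avg[has_ng] / total
  table$pct_tsp_full <- full
  table$pct_tsp <- round_half_away(full, 2)
  table
}

#' Repeat-rate composition of a merged table
#'
#' @param table a non-empty merged table.
#' @return list: `counts` (named integer vector over observed rates 1..R)
#'   and `percent` (same shape, integer percents rounded half away from
#'   zero).
#' @export
repeat_rate_summary <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0L, "repeat_rate" %in% names(table))
  R <- attr(table, "n_replicates")
  if (is.null(R) || is.na(R)) R <- max(table$repeat_rate)
  counts <- table(factor(table$repeat_rate, levels = seq_len(R)))
  counts <- setNames(as.integer(counts), names(counts))
  percent <- round_half_away(100 * counts / nrow(table), 0)
  list(counts = counts, percent = percent)
}

#' Abundance dynamic range in complete decades
#'
#' Ratio of the largest to the smallest positive `ng_avg`; zero-ng rows are
#' excluded from the minimum. The integer decade count is
#' `floor(log10(ratio))`.
#'
#' @param table a merged table, or a numeric vector of abundances.
#' @return list: `decades` (integer), `ratio`, `max`, `min_positive`.
#' @export
dynamic_range_logs <- function(table) {
  ng <- if (is.data.frame(table)) table$ng_avg else table
  ng <- ng[!is.na(ng)]
  pos <- ng[ng > 0]
  if (!length(pos)) stop_ctx("no positive abundances")
  ratio <- max(pos) / min(pos)
  list(decades = as.integer(floor(log10(ratio) + 1e-9)),
       ratio = ratio, max = max(pos), min_positive = min(pos))
}

#' Summed TSP share of description-matching rows
#'
#' Case-insensitive fixed-substring containment over the description
#' column (so `"glycinin"` also captures `"conglycinin"`). Shares are
#' summed at full precision and rounded half away from zero to an integer
#' percent.
#'
#' @param table a merged table after [percent_tsp()].
#' @param pattern substring; `""` matches every row.
#' @return list: `share` (integer percent), `share_full` (unrounded),
#'   `matched` (the matching rows).
#' @export
keyword_tsp_share <- function(table, pattern) {
  stopifnot(is.data.frame(table))
  if (!"pct_tsp_full" %in% names(table)) {
    stop_ctx("pct_tsp not computed; run percent_tsp() first")
  }
  hit <- grepl(pattern, table$description, ignore.case = TRUE, fixed = FALSE)
  if (pattern == "") hit <- rep(TRUE, nrow(table))
  share_full <- sum(table$pct_tsp_full[hit], na.rm = TRUE)
  list(share = as.integer(round_half_away(share_full, 0)),
       share_full = share_full,
       matched = table[hit, , drop = FALSE])
}

#' Default functional-category keyword rules
#'
#' An ordered, documented approximation of the storage / defense / energy /
#' abiotic-stress / maturation clustering used for seed proteomes; first
#' matching keyword wins, unmatched rows fall back to
#' `"uncharacterized/other"`. Not an acceptance surface -- amend freely.
#'
#' @return data.frame with columns `keyword`, `category` (ordered).
#' @export
default_category_rules <- function() {
  data.frame(
    keyword = c("glycinin", "conglycinin", "albumin", "globulin", "lectin",
                "storage protein", "sucrose binding",
                "inhibitor",
                "amylase", "lipoxygenase", "phosphorylase", "carboxylase",
                "isomerase", "oxidoreductase",
                "dehydrin", "lea protein", "em protein",
                "late embryongenesis", "late embryogenesis",
                "maturation",
                "uncharacterized"),
    category = c(rep("storage", 7),
                 "defense",
                 rep("energy", 6),
                 rep("abiotic stress", 5),
                 "maturation",
                 "uncharacterized/other"),
    stringsAsFactors = FALSE
  )
}

#' Assign functional categories by ordered keyword rules
#'
#' @param table a merged table (after [percent_tsp()] if TSP shares are
#'   wanted).
#' @param ruleset data.frame with `keyword`, `category` columns; first
#'   matching rule wins; rows matching nothing get
#'   `"uncharacterized/other"`. Must be non-empty.
#' @return list: `table` (input with a `category` column), `by_rows`
#'   (integer percent of rows per category), `by_tsp` (integer percent of
#'   summed TSP per category, when available).
#' @export
classify_function <- function(table, ruleset = default_category_rules()) {
  stopifnot(is.data.frame(table), "description" %in% names(table))
  if (!is.data.frame(ruleset) || nrow(ruleset) == 0L ||
      !all(c("keyword", "category") %in% names(ruleset))) {
    stop_ctx("ruleset must be a non-empty data.frame with keyword and category columns")
  }
  category <- rep("uncharacterized/other", nrow(table))
  assigned <- rep(FALSE, nrow(table))
  for (i in seq_len(nrow(ruleset))) {
    hit <- !assigned & grepl(ruleset$keyword[i], table$description,
                             ignore.case = TRUE)
    category[hit] <- ruleset$category[i]
    assigned <- assigned | hit
  }
  table$category <- category
  lv <- unique(c(ruleset$category, "uncharacterized/other"))
  by_rows <- round_half_away(
    100 * table(factor(category, levels = lv)) / nrow(table), 0)
  by_tsp <- NULL
  if ("pct_tsp_full" %in% names(table)) {
    sums <- tapply(table$pct_tsp_full, factor(category, levels = lv),
                   function(x) sum(x, na.rm = TRUE))
    sums[is.na(sums)] <- 0
    by_tsp <- round_half_away(as.numeric(sums), 0)
    names(by_tsp) <- lv
  }
  list(table = table,
       by_rows = setNames(as.numeric(by_rows), lv),
       by_tsp = by_tsp)
}

validate_peptide_hits <- function(hits) {
  stopifnot(is.data.frame(hits), nrow(hits) > 0L)
  need <- c("match_type", "ppm_error")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop_ctx("peptide hits missing column(s): ",
                             paste(miss, collapse = ", "))
  unknown <- setdiff(unique(hits$match_type), MATCH_TYPES)
  if (length(unknown)) {
    stop_ctx("unknown match type(s): ", paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(hits$ppm_error))) stop_ctx("non-finite ppm_error values")
  invisible(hits)
}

#' Peptide match-type composition
#'
#' @param peptide_hits data.frame with `match_type` (from the closed
#'   [MATCH_TYPES] vocabulary; unknown values are an error) and
#'   `ppm_error`.
#' @return list: `counts`, `fraction` (proportions) and `percent`
#'   (integer, rounded half away from zero) per match type.
#' @export
match_type_summary <- function(peptide_hits) {
  validate_peptide_hits(peptide_hits)
  counts <- table(factor(peptide_hits$match_type, levels = MATCH_TYPES))
  counts <- setNames(as.integer(counts), MATCH_TYPES)
  fraction <- counts / nrow(peptide_hits)
  list(counts = counts, fraction = fraction,
       percent = round_half_away(100 * fraction, 0))
}

#' Fraction of peptides within a ppm-error threshold
#'
#' Uses strict inequality `|error| < threshold`.
#'
#' @param peptide_hits data.frame with `ppm_error`.
#' @param threshold ppm bound (default 5).
#' @return list: `fraction_within`, `percent_within` (integer), `n`.
#' @export
ppm_histogram <- function(peptide_hits, threshold = 5) {
  validate_peptide_hits(peptide_hits)
  frac <- mean(abs(peptide_hits$ppm_error) < threshold)
  list(fraction_within = frac,
       percent_within = round_half_away(100 * frac, 0),
       n = nrow(peptide_hits))
}

#' Per-protein peptide-count and coverage distributions
#'
#' @param peptide_hits data.frame with a `parent_code` column (one row per
#'   identified peptide occurrence).
#' @param coverage optional numeric vector of per-protein percent sequence
#'   coverage (0-100).
#' @param min_peptides threshold for the "at least n matched peptides"
#'   fraction (default 10).
#' @param min_coverage threshold for the coverage fraction (default 30).
#' @return list: `peptides_per_protein` (named counts),
#'   `fraction_at_least_min_peptides`, and when coverage is supplied,
#'   `fraction_above_min_coverage`.
#' @export
per_protein_distributions <- function(peptide_hits, coverage = NULL,
                                      min_peptides = 10L, min_coverage = 30) {
  stopifnot(is.data.frame(peptide_hits), "parent_code" %in% names(peptide_hits),
            nrow(peptide_hits) > 0L)
  per <- table(peptide_hits$parent_code)
  per <- setNames(as.integer(per), names(per))
  out <- list(peptides_per_protein = per,
              fraction_at_least_min_peptides = mean(per >= min_peptides))
  if (!is.null(coverage)) {
    out$fraction_above_min_coverage <- mean(coverage > min_coverage, na.rm = TRUE)
  }
  out
}
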