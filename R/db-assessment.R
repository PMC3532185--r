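# Detectability and distribution statistics over a digested database.

#' Define a peptide-mass detection window
#'
#' Bounds are open on both sides by default, taking interval notation like
#' `500<x<1000` literally; an unbounded upper end (`upper = Inf`) encodes
#' `>lower` rows.
#'
#' @param lower lower bound in Da.
#' @param upper upper bound in Da, `Inf` for unbounded.
#' @param lower_open,upper_open logical; whether each bound is exclusive
#'   (default TRUE).
#' @return a `detection_window`.
#' @export
detection_window <- function(lower, upper = Inf, lower_open = TRUE,
                             upper_open = TRUE) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower < upper)
  structure(list(lower = lower, upper = upper,
                 lower_open = isTRUE(lower_open), upper_open = isTRUE(upper_open)),
            class = "detection_window")
}

window_label <- function(w) {
  if (is.infinite(w$upper)) {
    paste0(if (w$lower_open) ">" else ">=", format(w$lower))
  } else {
    paste0(format(w$lower), if (w$lower_open) "<x" else "<=x",
           if (w$upper_open) "<" else "<=", format(w$upper))
  }
}

#' Test window membership of masses
#'
#' @param mass numeric vector (Da); `NA` never passes (an undefined mass is
#'   never detectable).
#' @param window a [detection_window()].
#' @return logical vector.
#' @export
in_window <- function(mass, window) {
  stopifnot(inherits(window, "detection_window"))
  lo <- if (window$lower_open) mass > window$lower else mass >= window$lower
  hi <- if (window$upper_open) mass < window$upper else mass <= window$upper
  ok <- lo & hi
  ok[is.na(mass)] <- FALSE
  ok
}

#' Filter peptides to a mass window
#'
#' @param peptides peptide data.frame with a `mono_mass` column (see
#'   [peptide_physchem()]).
#' @param window a [detection_window()].
#' @return the window-passing subset; the number of excluded
#'   undefined-mass peptides is attached as attribute `n_undefined_mass`.
#' @export
peptide_window_filter <- function(peptides, window) {
  stopifnot(is.data.frame(peptides), "mono_mass" %in% names(peptides))
  keep <- in_window(peptides$mono_mass, window)
  out <- peptides[keep, , drop = FALSE]
  attr(out, "n_undefined_mass") <- sum(is.na(peptides$mono_mass))
  out
}

per_protein_window_counts <- function(digest_result, window) {
  peps <- if (inherits(digest_result, "digest_result")) digest_result$peptides else digest_result
  if (!"mono_mass" %in% names(peps)) {
    stop_ctx("peptides lack a mono_mass column; run peptide_physchem() first")
  }
  acc <- unique(peps$accession)
  hits <- peps$accession[in_window(peps$mono_mass, window)]
  counts <- table(factor(hits, levels = acc))
  setNames(as.integer(counts), acc)
}

#' Proteins with at most k detectable peptides in a window
#'
#' A protein is listed iff its count of window-passing peptide occurrences
#' is `<= k`. Counting is per protein (occurrences), not unique sequences
#' across the database: a peptide shared between proteins still evidences
#' each parent. Undefined-mass peptides never count as detectable.
#'
#' @param digest_result a mass-annotated `digest_result` or peptide
#'   data.frame.
#' @param window a [detection_window()].
#' @param k maximum detectable-peptide count (>= 0).
#' @return character vector of accessions, sorted.
#' @export
proteins_below_peptide_threshold <- function(digest_result, window, k = 0L) {
  stopifnot(k >= 0L)
  counts <- per_protein_window_counts(digest_result, window)
  sort(names(counts)[counts <= k])
}

#' Scan detectability over windows and peptide thresholds
#'
#' For each (window, k) cell, counts the proteins with at most `k`
#' detectable peptides in that window and records their accessions --
#' the structure of a "number of proteins with 0/1/2/3 peptides per
#' detection range" table.
#'
#' @param digest_result a mass-annotated `digest_result`.
#' @param windows list of [detection_window()] (non-empty).
#' @param ks integer vector of thresholds (default 0).
#' @return a `window_scan`: list with `counts` (data.frame `window`, `k`,
#'   `n_proteins`) and `accessions` (nested list `[[window label]][[as
#'   character(k)]]`).
#' @export
window_scan <- function(digest_result, windows, ks = 0L) {
  stopifnot(length(windows) > 0L, all(ks >= 0L))
  if (inherits(windows, "detection_window")) windows <- list(windows)
  labels <- vapply(windows, window_label, "")
  counts <- expand.grid(window = labels, k = ks, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  counts$n_proteins <- NA_integer_
  accessions <- setNames(vector("list", length(windows)), labels)
  for (i in seq_along(windows)) {
    per_prot <- per_protein_window_counts(digest_result, windows[[i]])
    accessions[[i]] <- setNames(vector("list", length(ks)), as.character(ks))
    for (k in ks) {
      accs <- sort(names(per_prot)[per_prot <= k])
      accessions[[i]][[as.character(k)]] <- accs
      sel <- counts$window == labels[i] & counts$k == k
      counts$n_proteins[sel] <- length(accs)
    }
  }
  structure(list(counts = counts, accessions = accessions),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat("window_scan over", length(unique(x$counts$window)), "window(s),",
      length(unique(x$counts$k)), "threshold(s)\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Histogram of pI (or mass) values with threshold fractions
#'
#' Bins defined values over the given edges (left-closed, right-open;
#' final bin right-closed) and reports the cumulative fraction below each
#' requested threshold. `NA` values are excluded and counted, so totals
#' reconcile: sum(counts) + n_excluded = length(values).
#'
#' @param values numeric vector (e.g. the `pi` or `mono_mass` column), or
#'   a data.frame carrying a `pi` column.
#' @param bin_edges increasing numeric vector of bin edges.
#' @param thresholds numeric vector; for each `t`, the fraction of defined
#'   values `< t` is reported (may be empty).
#' @return list: `bin_edges`, `counts`, `fraction` (of defined values),
#'   `below` (named fractions per threshold), `n_excluded`.
#' @export
pi_distribution <- function(values, bin_edges, thresholds = numeric()) {
  if (is.data.frame(values)) values <- values$pi
  stopifnot(is.numeric(bin_edges), length(bin_edges) >= 2L,
            !is.unsorted(bin_edges, strictly = TRUE))
  n_excluded <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (any(v < bin_edges[1] | v > bin_edges[length(bin_edges)])) {
    stop_ctx("values fall outside the bin range")
  }
  cuts <- cut(v, breaks = bin_edges, right = FALSE, include.lowest = FALSE)
  # cut(right = FALSE) drops values equal to the last edge; fold them in
  counts <- as.integer(table(cuts))
  counts[length(counts)] <- counts[length(counts)] + sum(v == bin_edges[length(bin_edges)])
  frac <- if (length(v)) counts / length(v) else rep(0, length(counts))
  below <- vapply(thresholds, function(t) if (length(v)) mean(v < t) else 0, 0)
  names(below) <- as.character(thresholds)
  list(bin_edges = bin_edges, counts = counts, fraction = frac,
       below = below, n_excluded = n_excluded)
}

#' Percentage of a count over a total
#'
#' `100 * numerator / denominator`, rounded half away from zero to two
#' decimals -- the convention used for "x% of the database" statements.
#'
#' @param numerator_count,denominator_count non-negative integers with
#'   `numerator <= denominator`, `denominator > 0`.
#' @return percent, two decimals.
#' @export
#' @examples
#' database_fractions(113, 13117)  # 0.86
database_fractions <- function(numerator_count, denominator_count) {
  if (denominator_count <= 0) stop_ctx("denominator must be > 0")
  stopifnot(numerator_count >= 0, numerator_count <= denominator_count)
  round_half_away(100 * numerator_count / denominator_count, 2)
}
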