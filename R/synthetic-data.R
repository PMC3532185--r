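# Seeded synthetic protein databases and replicate identification runs
# with a full ground-truth manifest, so every pipeline stage is testable
# without external downloads.

SEED_STORAGE_FREQS <- c(
  # globulin-like composition: enriched in Q/N/E (amide/acidic), K/R
  A = 0.06, C = 0.01, D = 0.05, E = 0.10, F = 0.05, G = 0.06, H = 0.02,
  I = 0.05, K = 0.06, L = 0.08, M = 0.01, N = 0.07, P = 0.06, Q = 0.09,
  R = 0.06, S = 0.06, T = 0.04, V = 0.05, W = 0.01, Y = 0.01)

#' Parameters for the synthetic protein-database generator
#'
#' @param n_proteins number of records (>= 1).
#' @param length_meanlog,length_sdlog log-normal residue-length
#'   distribution (defaults give a median near 300 residues).
#' @param length_range lengths are clamped to this range (default 50-800).
#' @param composition `"uniform"` over the 20 canonical residues, or
#'   `"seed-storage"` for a storage-globulin-like composition.
#' @param duplicate_fraction fraction of records planted as exact copies
#'   of another record (in `[0, 1)`).
#' @param fragment_fraction fraction planted as truncated copies,
#'   emulating "Fragment" database entries (in `[0, 1)`).
#' @param seed RNG seed; identical params give byte-identical FASTA.
#' @return a `synthetic_db_params` list.
#' @export
synthetic_db_params <- function(n_proteins = 100L,
                                length_meanlog = log(300), length_sdlog = 0.4,
                                length_range = c(50L, 800L),
                                composition = c("uniform", "seed-storage"),
                                duplicate_fraction = 0,
                                fragment_fraction = 0,
                                seed = 1L) {
  composition <- match.arg(composition)
  stopifnot(n_proteins >= 1L,
            duplicate_fraction >= 0, duplicate_fraction < 1,
            fragment_fraction >= 0, fragment_fraction < 1,
            duplicate_fraction + fragment_fraction < 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 length_range = as.integer(length_range),
                 composition = composition,
                 duplicate_fraction = duplicate_fraction,
                 fragment_fraction = fragment_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_db_params")
}

random_sequences <- function(n, params) {
  len <- pmin(pmax(round(rlnorm(n, params$length_meanlog, params$length_sdlog)),
                   params$length_range[1]), params$length_range[2])
  freqs <- if (params$composition == "seed-storage") {
    SEED_STORAGE_FREQS
  } else setNames(rep(1 / 20, 20), names(SEED_STORAGE_FREQS))
  vapply(len, function(L) {
    paste(sample(names(freqs), L, replace = TRUE, prob = freqs), collapse = "")
  }, "")
}

#' Generate a synthetic protein database
#'
#' Planted structure: `floor(duplicate_fraction * n)` records are exact
#' sequence copies of a randomly chosen original, and
#' `floor(fragment_fraction * n)` are proper truncations of an original
#' (description suffixed "Fragment"). The returned manifest records every
#' planted relationship.
#'
#' @param params a [synthetic_db_params()].
#' @return list: `db` (a [protein_db()]) and `manifest` with
#'   `duplicate_parent` (named: duplicate accession -> source accession),
#'   `fragment_parent` (named), `duplicate_groups` (the expected
#'   [find_duplicate_sequences()] output).
#' @export
generate_database <- function(params = synthetic_db_params()) {
  stopifnot(inherits(params, "synthetic_db_params"))
  set.seed(params$seed)
  n <- params$n_proteins
  n_dup <- as.integer(floor(params$duplicate_fraction * n))
  n_frag <- as.integer(floor(params$fragment_fraction * n))
  n_orig <- n - n_dup - n_frag
  if (n_orig < 1L) stop_ctx("infeasible params: no original records left")
  acc <- sprintf("SYN%05d", seq_len(n))
  seqs <- character(n)
  desc <- sprintf("Synthetic protein %d OS=Synthetica genomica", seq_len(n))
  seqs[seq_len(n_orig)] <- random_sequences(n_orig, params)
  dup_parent <- character(); frag_parent <- character()
  if (n_dup > 0L) {
    src <- sample(n_orig, n_dup, replace = TRUE)
    idx <- n_orig + seq_len(n_dup)
    seqs[idx] <- seqs[src]
    desc[idx] <- desc[src]
    dup_parent <- setNames(acc[src], acc[idx])
  }
  if (n_frag > 0L) {
    src <- sample(n_orig, n_frag, replace = TRUE)
    idx <- n_orig + n_dup + seq_len(n_frag)
    for (j in seq_len(n_frag)) {
      full <- seqs[src[j]]
      L <- nchar(full)
      keep <- sample(seq(20L, L - 1L), 1L)  # proper truncation, >= 20 aa
      start <- sample(seq_len(L - keep + 1L), 1L)
      seqs[idx[j]] <- substr(full, start, start + keep - 1L)
    }
    desc[idx] <- paste(sub(" OS=.*$", "", desc[src]), "Fragment OS=Synthetica genomica")
    frag_parent <- setNames(acc[src], acc[idx])
  }
  db <- protein_db(data.frame(accession = acc, description = desc,
                              sequence = seqs, stringsAsFactors = FALSE),
                   source_label = sprintf("synthetic(seed=%d)", params$seed))
  groups <- split(c(names(dup_parent), unname(dup_parent)),
                  c(unname(dup_parent), unname(dup_parent)))
  groups <- lapply(groups, function(g) sort(unique(g)))
  list(db = db,
       manifest = list(params = params,
                       duplicate_parent = dup_parent,
                       fragment_parent = frag_parent,
                       duplicate_groups = unname(groups)))
}

#' Parameters for the synthetic replicate-run generator
#'
#' Defaults encode the stated world of a typical seed-proteome DIA run:
#' four technical replicates, ~3,400 peptide identifications over ~113
#' proteins spanning three decades of abundance, 58%/6% first/second-pass
#' matches, 17% missed-cleavage matches, 13% in-source fragmentation, and
#' mass errors drawn so that 82% fall within 5 ppm.
#'
#' @param n_replicates technical replicates (default 4).
#' @param n_true_proteins proteins truly present (default 113).
#' @param abundance_decades decades spanned by the log-normal abundance
#'   model (default 3).
#' @param detection_slope,detection_midpoint logistic detection-probability
#'   curve over log10 abundance; the default midpoint sits at 15% of the
#'   abundance span so high-abundance proteins are detected in nearly all
#'   replicates. `detection_prob` overrides the curve with a constant.
#' @param detection_prob optional constant detection probability.
#' @param repeat_rates optional integer vector (length `n_true_proteins`)
#'   planting each protein's repeat rate exactly (direct-assignment mode).
#' @param n_peptides target number of peptide identifications
#'   (default 3400).
#' @param fraction_pepfrag1,fraction_pepfrag2,fraction_missed_cleavage,fraction_in_source
#'   match-type probabilities (defaults 0.58 / 0.06 / 0.17 / 0.13); the
#'   remainder is split over VarMod and neutral losses.
#' @param ppm_within_target,ppm_threshold the ppm-error sd is solved from
#'   `P(|e| < threshold) = target` via the normal quantile
#'   (default 0.82 within 5 ppm).
#' @param seed RNG seed.
#' @return a `synthetic_run_params` list (includes the derived
#'   `match_probs` vector and `ppm_sd`).
#' @export
synthetic_run_params <- function(n_replicates = 4L, n_true_proteins = 113L,
                                 abundance_decades = 3,
                                 detection_slope = 4,
                                 detection_midpoint = NULL,
                                 detection_prob = NULL,
                                 repeat_rates = NULL,
                                 n_peptides = 3400L,
                                 fraction_pepfrag1 = 0.58,
                                 fraction_pepfrag2 = 0.06,
                                 fraction_missed_cleavage = 0.17,
                                 fraction_in_source = 0.13,
                                 ppm_within_target = 0.82,
                                 ppm_threshold = 5,
                                 seed = 1L) {
  core <- c(PepFrag1 = fraction_pepfrag1, PepFrag2 = fraction_pepfrag2,
            MissedCleavage = fraction_missed_cleavage,
            InSource = fraction_in_source)
  if (any(core < 0) || sum(core) > 1) {
    stop_ctx("match-type fractions must be non-negative and sum to at most 1")
  }
  rest <- 1 - sum(core)
  match_probs <- c(core, VarMod = rest * 2 / 3,
                   NeutralLoss_H2O = rest / 6, NeutralLoss_NH3 = rest / 6)
  match_probs <- match_probs[MATCH_TYPES]
  stopifnot(ppm_within_target > 0, ppm_within_target < 1, ppm_threshold > 0,
            n_replicates >= 1L, n_true_proteins >= 1L, n_peptides >= 1L,
            abundance_decades > 0)
  if (!is.null(repeat_rates)) {
    stopifnot(length(repeat_rates) == n_true_proteins,
              all(repeat_rates >= 0L), all(repeat_rates <= n_replicates))
  }
  structure(list(
    n_replicates = as.integer(n_replicates),
    n_true_proteins = as.integer(n_true_proteins),
    abundance_decades = abundance_decades,
    detection_slope = detection_slope,
    detection_midpoint = detection_midpoint %||% (0.15 * abundance_decades),
    detection_prob = detection_prob,
    repeat_rates = repeat_rates,
    n_peptides = as.integer(n_peptides),
    match_probs = match_probs,
    ppm_within_target = ppm_within_target,
    ppm_threshold = ppm_threshold,
    ppm_sd = ppm_threshold / qnorm((1 + ppm_within_target) / 2),
    seed = as.integer(seed)
  ), class = "synthetic_run_params")
}

#' Generate synthetic replicate identification tables
#'
#' Draws true abundances from a log-normal spanning
#' `abundance_decades`, detects each protein in each replicate by a
#' logistic curve over log10 abundance (so abundance and repeat rate
#' correlate), then distributes `n_peptides` peptide identifications over
#' the detected (protein, replicate) pairs -- each detected pair receives
#' at least one peptide, so protein and peptide tables are mutually
#' consistent. Match types are drawn per peptide from a single categorical
#' distribution and ppm errors from `Normal(0, ppm_sd)`.
#'
#' @param db a [protein_db()] with at least `n_true_proteins` records.
#' @param params a [synthetic_run_params()].
#' @return list: `replicates` (list of per-replicate protein tables with
#'   columns uniprot_code/description/protein_mw/score/products/peptides/
#'   fmol/ng), `peptide_hits` (pooled data.frame: sequence, match_type,
#'   ppm_error, parent_code, replicate_id) and `manifest` (true
#'   abundances, detection matrix, planted repeat rates, per-hit draws,
#'   params). Class `replicate_set`.
#' @export
generate_replicates <- function(db, params = synthetic_run_params()) {
  stopifnot(inherits(db, "protein_db"), inherits(params, "synthetic_run_params"))
  if (params$n_true_proteins > nrow(db)) {
    stop_ctx("n_true_proteins exceeds database size")
  }
  set.seed(params$seed)
  R <- params$n_replicates
  n <- params$n_true_proteins
  sel <- sort(sample(nrow(db), n))
  acc <- db$accession[sel]
  dec <- params$abundance_decades
  x <- rnorm(n, mean = dec / 2, sd = dec / 6)  # log10 abundance
  ng <- 10^x
  p <- if (!is.null(params$detection_prob)) {
    rep(params$detection_prob, n)
  } else {
    plogis(params$detection_slope * (x - params$detection_midpoint))
  }
  detect <- matrix(FALSE, n, R)
  if (!is.null(params$repeat_rates)) {
    for (i in seq_len(n)) {
      if (params$repeat_rates[i] > 0L) {
        detect[i, sample(R, params$repeat_rates[i])] <- TRUE
      }
    }
  } else {
    detect[] <- rbinom(n * R, 1L, rep(p, R)) == 1L
  }
  pairs <- which(detect, arr.ind = TRUE)
  if (nrow(pairs) == 0L) stop_ctx("no detections; infeasible detection parameters")
  if (params$n_peptides < nrow(pairs)) {
    stop_ctx("n_peptides (", params$n_peptides,
             ") below the number of detected protein x replicate pairs (",
             nrow(pairs), ")")
  }
  # one guaranteed peptide per detected pair, remainder abundance-weighted
  extra <- params$n_peptides - nrow(pairs)
  draw <- sample(nrow(pairs), extra, replace = TRUE, prob = ng[pairs[, 1]])
  pair_idx <- c(seq_len(nrow(pairs)), draw)
  hits <- data.frame(
    sequence = sprintf("PEP%06d", seq_along(pair_idx)),
    match_type = sample(MATCH_TYPES, length(pair_idx), replace = TRUE,
                        prob = params$match_probs),
    ppm_error = rnorm(length(pair_idx), 0, params$ppm_sd),
    parent_code = acc[pairs[pair_idx, 1]],
    replicate_id = as.integer(pairs[pair_idx, 2]),
    stringsAsFactors = FALSE
  )
  replicates <- vector("list", R)
  for (r in seq_len(R)) {
    i_det <- which(detect[, r])
    h <- hits[hits$replicate_id == r, ]
    pep_counts <- table(factor(h$parent_code, levels = acc[i_det]))
    replicates[[r]] <- data.frame(
      uniprot_code = acc[i_det],
      description = db$description[sel][i_det],
      protein_mw = round(nchar(db$sequence[sel][i_det]) * 110.0, 2),
      score = round(ng[i_det] * exp(rnorm(length(i_det), 0, 0.2)) * 100, 2),
      products = as.integer(pep_counts) * 5L,
      peptides = as.integer(pep_counts),
      fmol = ng[i_det] / 0.05 * exp(rnorm(length(i_det), 0, 0.1)),
      ng = ng[i_det] * exp(rnorm(length(i_det), 0, 0.1)),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    replicates = replicates,
    peptide_hits = hits,
    manifest = list(params = params, accessions = acc, true_ng = setNames(ng, acc),
                    detection = detect,
                    repeat_rates = setNames(rowSums(detect), acc),
                    match_type = hits$match_type, ppm_error = hits$ppm_error)
  ), class = "replicate_set")
}

#' The packaged published merged identification table
#'
#' A 113-protein soybean-seed merged table (four technical replicates,
#' minimum repeat rate 2) reproduced exactly as published, including its
#' blank fmol cells. Serves as the reference surface for the merge and
#' quantification statistics.
#'
#' @return a `merged_table` with columns `uniprot_code`, `description`,
#'   `protein_mw`, `score_avg`, `products_avg`, `peptides_avg`,
#'   `fmol_variation`, `ng_avg`, `repeat_rate` and the published
#'   `pct_tsp`.
#' @export
fixture_table1 <- function() {
  tab <- read_protein_table(extdata_path("table1_soybean_seed.tsv"))
  names(tab)[names(tab) == "score"] <- "score_avg"
  names(tab)[names(tab) == "products"] <- "products_avg"
  names(tab)[names(tab) == "peptides"] <- "peptides_avg"
  names(tab)[names(tab) == "fmol"] <- "fmol_variation"
  names(tab)[names(tab) == "ng"] <- "ng_avg"
  as_merged_table(tab, n_replicates = 4L, min_repeat = 2L)
}
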