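# Pipeline driver and command-line entry point tying the stages together:
# digest -> physchem -> window scan / distributions on the database side,
# read -> merge -> %TSP / repeat-rate / dynamic-range / categories on the
# experiment side. All acceptance surfaces are the TSV/JSON numbers; plots
# are out of scope.

#' Standard peptide-mass detection windows
#'
#' The eleven windows of a detectability scan: nested `500 < x < U` ranges
#' for U in 1000..5000 Da, the disjoint 1000-Da decade bands up to 6000 Da
#' and the unbounded `> 6000` tail.
#'
#' @return list of [detection_window()].
#' @export
default_detection_windows <- function() {
  c(lapply(seq(1000, 5000, by = 1000), function(u) detection_window(500, u)),
    lapply(seq(1000, 5000, by = 1000), function(l) detection_window(l, l + 1000)),
    list(detection_window(6000, Inf)))
}

#' Assemble and validate a pipeline configuration
#'
#' Every field is validated against the preconditions of the stage that
#' consumes it before any work starts.
#'
#' @param fasta optional protein FASTA path (database assessment side).
#' @param replicates optional character vector of per-replicate
#'   identification table paths.
#' @param table optional already-merged table path (fixture-only mode).
#' @param enzyme protease name (currently `"trypsin"`).
#' @param proline_rule apply Keil-rule suppression (default TRUE).
#' @param max_missed missed cleavages allowed (default 1).
#' @param pk_set_name pK set for pI calculation.
#' @param windows list of [detection_window()] (default
#'   [default_detection_windows()]).
#' @param ks detectable-peptide thresholds (default 0:3).
#' @param min_repeat minimum repeat rate for the merge (default 2).
#' @param keyword description substring for the TSP-share summary
#'   (default `"glycinin"`).
#' @param ruleset functional-category rules (default
#'   [default_category_rules()]).
#' @param out_dir output directory (created if absent).
#' @param seed integer seed recorded in the summary (the pipeline itself
#'   is deterministic; the seed matters only when inputs are generated).
#' @return a validated `run_config`.
#' @export
run_config <- function(fasta = NULL, replicates = NULL, table = NULL,
                       enzyme = "trypsin", proline_rule = TRUE,
                       max_missed = 1L, pk_set_name = "bjellqvist",
                       windows = default_detection_windows(), ks = 0:3,
                       min_repeat = 2L, keyword = "glycinin",
                       ruleset = default_category_rules(),
                       out_dir = tempfile("seedscape_run_"), seed = 1L) {
  for (p in c(fasta, replicates, table)) {
    if (!file.exists(p)) stop_ctx("input not found: ", p)
  }
  if (!identical(enzyme, "trypsin")) {
    stop_ctx("unknown enzyme '", enzyme, "' (supported: trypsin)")
  }
  stopifnot(max_missed >= 0L, min_repeat >= 1L, all(ks >= 0L),
            length(windows) >= 1L)
  pk_set(pk_set_name)  # errors early on unknown sets
  structure(list(fasta = fasta, replicates = replicates, table = table,
                 enzyme = enzyme, proline_rule = isTRUE(proline_rule),
                 max_missed = as.integer(max_missed),
                 pk_set_name = pk_set_name, windows = windows,
                 ks = as.integer(ks), min_repeat = as.integer(min_repeat),
                 keyword = keyword, ruleset = ruleset,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full assessment pipeline
#'
#' Executes whichever halves the configuration provides inputs for and
#' writes every figure-level statistic as TSV plus a machine-readable JSON
#' summary. Deterministic given the configuration and inputs; any stage
#' error aborts with a stage-named message.
#'
#' @param config a [run_config()].
#' @return (invisibly) the summary list; side effect: files under
#'   `config$out_dir` (`digestion_summary.tsv`, `window_scan.tsv`,
#'   histogram TSVs, `merged_table.tsv`, `summary.json` as applicable).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed)
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_ctx("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  if (!is.null(config$fasta)) {
    db <- stage("read_fasta", read_fasta(config$fasta))
    rule <- cleavage_rule(apply_suppression = config$proline_rule)
    dg <- stage("digestion", {
      d <- digest_database(db, rule, config$max_missed)
      peptide_physchem(d, mass_model(), pk_set(config$pk_set_name))
    })
    message("digested ", dg$summary$n_proteins, " proteins -> ",
            dg$summary$n_peptides_total, " peptides")
    summary$digestion <- dg$summary
    dsum <- data.frame(metric = c("n_proteins", "n_peptides_fully_cleaved",
                                  "n_peptides_total", "n_unique_sequences"),
                       value = c(dg$summary$n_proteins,
                                 dg$summary$n_peptides_fully_cleaved,
                                 dg$summary$n_peptides_total,
                                 dg$summary$n_unique_sequences))
    outputs <- c(outputs, write_tsv(dsum, file.path(config$out_dir, "digestion_summary.tsv")))

    ws <- stage("window_scan", window_scan(dg, config$windows, config$ks))
    summary$window_scan <- ws$counts
    outputs <- c(outputs, write_tsv(ws$counts, file.path(config$out_dir, "window_scan.tsv")))

    prot <- data.frame(sequence = db$sequence)
    prot <- stage("protein_physchem",
                  peptide_physchem(prot, mass_model(), pk_set(config$pk_set_name)))
    pep_pi <- stage("pi_histograms",
                    pi_distribution(dg$peptides$pi, bin_edges = 0:14, thresholds = c(5, 8)))
    prot_pi <- stage("pi_histograms",
                     pi_distribution(prot$pi, bin_edges = 0:14, thresholds = c(5, 8)))
    summary$peptide_pi_below <- pep_pi$below
    summary$protein_pi_below <- prot_pi$below
    hist_df <- function(h) data.frame(bin_lower = h$bin_edges[-length(h$bin_edges)],
                                      bin_upper = h$bin_edges[-1],
                                      count = h$counts, fraction = h$fraction)
    outputs <- c(outputs,
                 write_tsv(hist_df(pep_pi), file.path(config$out_dir, "pi_histogram_peptides.tsv")),
                 write_tsv(hist_df(prot_pi), file.path(config$out_dir, "pi_histogram_proteins.tsv")))
  }

  merged <- NULL
  if (!is.null(config$replicates)) {
    reps <- stage("read_replicates", lapply(config$replicates, read_protein_table))
    merged <- stage("merge", merge_replicates(reps, config$min_repeat))
  } else if (!is.null(config$table)) {
    tab <- stage("read_table", read_protein_table(config$table))
    names(tab)[names(tab) == "score"] <- "score_avg"
    names(tab)[names(tab) == "products"] <- "products_avg"
    names(tab)[names(tab) == "peptides"] <- "peptides_avg"
    names(tab)[names(tab) == "fmol"] <- "fmol_variation"
    names(tab)[names(tab) == "ng"] <- "ng_avg"
    merged <- as_merged_table(tab, n_replicates = NA_integer_,
                              min_repeat = NA_integer_)
  }
  if (!is.null(merged)) {
    merged <- stage("percent_tsp", percent_tsp(merged))
    rr <- stage("repeat_rate", repeat_rate_summary(merged))
    dr <- stage("dynamic_range", dynamic_range_logs(merged))
    kw <- stage("keyword_share", keyword_tsp_share(merged, config$keyword))
    cf <- stage("classify", classify_function(merged, config$ruleset))
    message("merged table: ", nrow(merged), " proteins; dynamic range ",
            dr$decades, " decades")
    summary$merged <- list(
      n_proteins = nrow(merged),
      repeat_rate_counts = rr$counts, repeat_rate_percent = rr$percent,
      dynamic_range_decades = dr$decades, dynamic_range_ratio = dr$ratio,
      keyword = config$keyword, keyword_tsp_share = kw$share,
      category_share_rows = cf$by_rows, category_share_tsp = cf$by_tsp
    )
    out_tab <- cf$table
    out_tab$pct_tsp_full <- NULL
    outputs <- c(outputs, write_tsv(out_tab, file.path(config$out_dir, "merged_table.tsv")))
  }
  if (is.null(config$fasta) && is.null(merged)) {
    stop_ctx("nothing to do: provide fasta, replicates or table")
  }

  json_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  outputs <- c(outputs, json_path)
  summary$outputs <- outputs
  invisible(summary)
}
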