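# FASTA reading/writing and Uniprot-style header parsing.
# Parsing is backed by Biostrings; validation and header semantics live here.

AMBIGUOUS_RESIDUES <- c("B", "J", "O", "U", "X", "Z")

#' Construct a protein database
#'
#' A `protein_db` is a data.frame with one row per database entry and columns
#' `accession`, `entry_name`, `description`, `organism`, `gene`, `pe_level`,
#' `sv`, `sequence`, `ambiguous`. Accessions must be unique: they are the join
#' key for digestion and identification-table stages.
#'
#' @param records data.frame with at least `accession` and `sequence`;
#'   missing optional columns are filled with `NA`/empty.
#' @param source_label free-text provenance label stored as an attribute.
#' @return a `protein_db` object.
#' @export
protein_db <- function(records, source_label = "unspecified") {
  stopifnot(is.data.frame(records))
  for (need in c("accession", "sequence")) {
    if (!need %in% names(records)) stop_ctx("records must have column '", need, "'")
  }
  opt_chr <- c("entry_name", "description", "organism", "gene")
  for (col in opt_chr) if (!col %in% names(records)) records[[col]] <- ""
  for (col in c("pe_level", "sv")) {
    if (!col %in% names(records)) records[[col]] <- NA_integer_
  }
  records$accession <- as.character(records$accession)
  records$sequence <- toupper(as.character(records$sequence))
  if (any(!nzchar(records$accession))) stop_ctx("empty accession in records")
  if (any(!nzchar(records$sequence))) {
    stop_ctx("empty sequence for record(s): ",
             paste(records$accession[!nzchar(records$sequence)], collapse = ", "))
  }
  bad <- grepl("[^A-Z]", records$sequence)
  if (any(bad)) {
    stop_ctx("sequence characters outside A-Z in record(s): ",
             paste(records$accession[bad], collapse = ", "))
  }
  dup <- duplicated(records$accession)
  if (any(dup)) {
    stop_ctx("duplicate accession(s): ",
             paste(unique(records$accession[dup]), collapse = ", "))
  }
  records$ambiguous <- grepl(paste0("[", paste(AMBIGUOUS_RESIDUES, collapse = ""), "]"),
                             records$sequence)
  cols <- c("accession", "entry_name", "description", "organism", "gene",
            "pe_level", "sv", "sequence", "ambiguous")
  extra <- setdiff(names(records), cols)
  records <- records[, c(cols, extra), drop = FALSE]
  rownames(records) <- NULL
  structure(records, class = c("protein_db", "data.frame"),
            source_label = source_label)
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("protein_db: %d records (source: %s)\n",
              nrow(x), attr(x, "source_label") %||% "unspecified"))
  cat(sprintf("  residues total: %d; entries with ambiguous residues: %d\n",
              sum(nchar(x$sequence)), sum(x$ambiguous)))
  invisible(x)
}

#' Parse a Uniprot-style FASTA header
#'
#' Understands both the canonical `>sp|ACC|ENTRY Description OS=... GN=...
#' PE=n SV=n` dialect and bare `>ACC Description` headers. All metadata
#' fields are optional; an unparseable header falls back to its first
#' whitespace-delimited token as the accession.
#'
#' @param header_line a string starting with `>`.
#' @return named list: `accession`, `entry_name`, `description`, `organism`,
#'   `gene`, `pe_level` (integer or NA), `sv` (integer or NA).
#' @export
#' @examples
#' parse_uniprot_header(">sp|P04776|GLYG1_SOYBN Glycinin G1 OS=Glycine max GN=GY1 PE=1 SV=2")
parse_uniprot_header <- function(header_line) {
  stopifnot(is.character(header_line), length(header_line) == 1L)
  h <- sub("^>", "", header_line)
  h <- trimws(h)
  if (!nzchar(h)) stop_ctx("malformed FASTA header")
  first <- sub("\\s.*$", "", h)
  rest <- trimws(sub("^\\S+\\s*", "", h))
  entry_name <- ""
  accession <- first
  m <- regmatches(first, regexec("^(sp|tr)\\|([^|]+)\\|(\\S+)$", first))[[1]]
  if (length(m) == 4L) {
    accession <- m[3]
    entry_name <- m[4]
  }
  grab <- function(tag) {
    # field runs until the next XX= tag or end of line
    mm <- regmatches(rest, regexec(paste0(tag, "=(.*?)(?=\\s+[A-Z]{2}=|$)"),
                                   rest, perl = TRUE))[[1]]
    if (length(mm) == 2L) trimws(mm[2]) else ""
  }
  organism <- grab("OS")
  gene <- grab("GN")
  pe <- suppressWarnings(as.integer(grab("PE")))
  sv <- suppressWarnings(as.integer(grab("SV")))
  desc <- rest
  tagpos <- regexpr("\\s*[A-Z]{2}=", desc)
  if (tagpos > 0L) desc <- substr(desc, 1L, tagpos - 1L)
  list(accession = accession, entry_name = entry_name,
       description = trimws(desc), organism = organism, gene = gene,
       pe_level = if (length(pe)) pe else NA_integer_,
       sv = if (length(sv)) sv else NA_integer_)
}

#' Read a protein FASTA file
#'
#' Sequence lines may be wrapped or unwrapped, CR/LF line endings are
#' tolerated, lowercase residues are uppercased and `*` (stop/translation
#' artifacts) are stripped with a warning. Any other character outside A-Z
#' is an error naming the offending record.
#'
#' @param path FASTA file path.
#' @param allow_duplicate_ids if `TRUE`, duplicate accessions are suffixed
#'   `.2`, `.3`, ... and a message is emitted instead of an error.
#' @param source_label provenance label; defaults to the file name.
#' @return a [protein_db()].
#' @export
read_fasta <- function(path, allow_duplicate_ids = FALSE, source_label = NULL) {
  if (!file.exists(path)) stop_ctx("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_ctx("no FASTA records in ", path)
  headers <- names(set)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  parsed <- lapply(paste0(">", headers), parse_uniprot_header)
  acc <- vapply(parsed, `[[`, "", "accession")
  if (any(grepl("\\*", seqs))) {
    warning("stripped '*' characters from ",
            sum(grepl("\\*", seqs)), " sequence(s)", call. = FALSE)
    seqs <- gsub("\\*", "", seqs)
  }
  bad <- grepl("[^A-Z]", seqs) | !nzchar(seqs)
  if (any(bad)) {
    stop_ctx("invalid sequence characters (outside A-Z/'*') or empty sequence in record(s): ",
             paste(acc[bad], collapse = ", "))
  }
  if (anyDuplicated(acc)) {
    if (!allow_duplicate_ids) {
      stop_ctx("duplicate accession(s) in FASTA: ",
               paste(unique(acc[duplicated(acc)]), collapse = ", "),
               " (set allow_duplicate_ids = TRUE to relabel)")
    }
    relabeled <- make.unique(acc, sep = ".")
    message("relabeled ", sum(relabeled != acc), " duplicate accession(s)")
    acc <- relabeled
  }
  rec <- data.frame(
    accession = acc,
    entry_name = vapply(parsed, `[[`, "", "entry_name"),
    description = vapply(parsed, `[[`, "", "description"),
    organism = vapply(parsed, `[[`, "", "organism"),
    gene = vapply(parsed, `[[`, "", "gene"),
    pe_level = vapply(parsed, function(p) p$pe_level %||% NA_integer_, 1L),
    sv = vapply(parsed, function(p) p$sv %||% NA_integer_, 1L),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
  message(nrow(rec), " records read from ", path)
  protein_db(rec, source_label = source_label %||% basename(path))
}

#' Write a protein database as FASTA
#'
#' Headers are reconstructed in the `sp|ACC|ENTRY` dialect when an entry
#' name is present, otherwise as bare `>ACC description`. Sequences are
#' wrapped at `width` columns.
#'
#' @param db a [protein_db()].
#' @param path output file.
#' @param width line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 60L) {
  stopifnot(inherits(db, "protein_db"), width >= 1L)
  hdr <- character(nrow(db))
  for (i in seq_len(nrow(db))) {
    core <- if (nzchar(db$entry_name[i])) {
      paste0("sp|", db$accession[i], "|", db$entry_name[i])
    } else db$accession[i]
    tail_fields <- c(
      if (nzchar(db$description[i])) db$description[i],
      if (nzchar(db$organism[i])) paste0("OS=", db$organism[i]),
      if (nzchar(db$gene[i])) paste0("GN=", db$gene[i]),
      if (!is.na(db$pe_level[i])) paste0("PE=", db$pe_level[i]),
      if (!is.na(db$sv[i])) paste0("SV=", db$sv[i])
    )
    hdr[i] <- paste(c(core, tail_fields), collapse = " ")
  }
  set <- Biostrings::BStringSet(db$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Find entries sharing an identical sequence
#'
#' Groups database records by exact full-sequence equality and returns only
#' groups of size two or more. Public protein databases carry many such
#' duplicate entries, which inflate homolog association during search.
#'
#' @param db a [protein_db()].
#' @return named list of character vectors of accessions (names `dup1`,
#'   `dup2`, ... in order of first appearance); empty list when all
#'   sequences are distinct.
#' @export
find_duplicate_sequences <- function(db) {
  stopifnot(inherits(db, "protein_db"))
  idx <- split(seq_len(nrow(db)), factor(db$sequence, levels = unique(db$sequence)))
  groups <- Filter(function(i) length(i) >= 2L, idx)
  out <- lapply(groups, function(i) db$accession[i])
  names(out) <- if (length(out)) paste0("dup", seq_along(out)) else character()
  out
}

#' Tabulate duplicate-sequence groups
#'
#' @param db a [protein_db()].
#' @return data.frame with columns `group_id`, `accession`,
#'   `sequence_length`, one row per member of each duplicate group.
#' @export
duplicate_report <- function(db) {
  groups <- find_duplicate_sequences(db)
  if (!length(groups)) {
    return(data.frame(group_id = character(), accession = character(),
                      sequence_length = integer()))
  }
  len <- setNames(nchar(db$sequence), db$accession)
  do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group_id = g, accession = groups[[g]],
               sequence_length = unname(len[groups[[g]]]))
  }))
}
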