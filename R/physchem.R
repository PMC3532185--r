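# Monoisotopic mass, m/z, ppm error and isoelectric point.
#
# Mass tables and pK sets are shipped as plain-text files under
# inst/extdata so alternates can be added without code changes.

WATER_MONO <- 18.0105646
PROTON_MASS <- 1.0072765

.physchem_cache <- new.env(parent = emptyenv())

residue_mass_table <- function() {
  if (is.null(.physchem_cache$masses)) {
    .physchem_cache$masses <- read.delim(extdata_path("residue_masses.tsv"),
                                         stringsAsFactors = FALSE)
  }
  .physchem_cache$masses
}

#' Build a mass model
#'
#' @param fixed_mods either a named numeric vector of per-residue mass
#'   deltas in Da (e.g. `c(C = 57.021464)`), or the preset name
#'   `"carbamidomethyl-C"`, or `NULL` (default: no fixed modifications --
#'   appropriate for theoretical-database statistics that predate any
#'   search settings).
#' @return a `mass_model`: monoisotopic and average residue mass maps,
#'   water/proton constants and the fixed-modification deltas.
#' @export
mass_model <- function(fixed_mods = NULL) {
  tab <- residue_mass_table()
  if (identical(fixed_mods, "carbamidomethyl-C")) {
    fixed_mods <- c(C = 57.021464)
  }
  if (!is.null(fixed_mods)) {
    stopifnot(is.numeric(fixed_mods), !is.null(names(fixed_mods)))
    if (!all(names(fixed_mods) %in% tab$residue)) {
      stop_ctx("fixed_mods names must be canonical residues")
    }
  }
  structure(list(
    residue_mono = setNames(tab$mono, tab$residue),
    residue_avg = setNames(tab$avg, tab$residue),
    water_mono = WATER_MONO,
    proton = PROTON_MASS,
    fixed_mods = fixed_mods %||% numeric()
  ), class = "mass_model")
}

#' Peptide/protein monoisotopic mass
#'
#' Sum of residue masses plus one water, plus any applicable fixed
#' modifications. Sequences containing residues with no defined mass
#' (B, J, O, U, X, Z by default) get `NA` -- undefined is a value here,
#' not an error -- and their count is reported via a message.
#'
#' @param sequences character vector of uppercase sequences.
#' @param model a [mass_model()].
#' @param quiet suppress the undefined-count message.
#' @return numeric vector of masses in Da (NA where undefined).
#' @export
#' @examples
#' mono_mass("G")  # 75.03203
mono_mass <- function(sequences, model = mass_model(), quiet = TRUE) {
  stopifnot(is.character(sequences), all(nzchar(sequences)))
  counts <- Biostrings::letterFrequency(Biostrings::BStringSet(sequences),
                                        letters = LETTERS)
  known <- names(model$residue_mono)
  undefined_letters <- setdiff(LETTERS, known)
  n_undef <- rowSums(counts[, undefined_letters, drop = FALSE])
  mass_vec <- model$residue_mono[known]
  out <- as.numeric(counts[, known, drop = FALSE] %*% mass_vec) + model$water_mono
  if (length(model$fixed_mods)) {
    out <- out + as.numeric(counts[, names(model$fixed_mods), drop = FALSE] %*%
                              model$fixed_mods)
  }
  out[n_undef > 0] <- NA_real_
  if (!quiet && any(n_undef > 0)) {
    message(sum(n_undef > 0), " sequence(s) contain residues without a defined mass; mass set to NA")
  }
  out
}

#' m/z of a charged species
#'
#' @param neutral_mass neutral monoisotopic mass in Da.
#' @param z charge state (positive integer).
#' @param model a [mass_model()] (supplies the proton mass).
#' @return `(neutral_mass + z * proton) / z`.
#' @export
mz_for_charge <- function(neutral_mass, z, model = mass_model()) {
  if (any(z <= 0)) stop_ctx("charge z must be >= 1")
  (neutral_mass + z * model$proton) / z
}

#' Signed mass error in parts per million
#'
#' @param observed observed mass or m/z.
#' @param theoretical theoretical value in the same units (> 0).
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop_ctx("theoretical mass must be > 0")
  1e6 * (observed - theoretical) / theoretical
}

pk_set_table <- function() {
  if (is.null(.physchem_cache$pks)) {
    .physchem_cache$pks <- read.delim(extdata_path("pk_sets.tsv"),
                                      stringsAsFactors = FALSE)
  }
  .physchem_cache$pks
}

#' Retrieve a named pK set
#'
#' Two sets ship with the package: `"bjellqvist"` (default; the set behind
#' most gel-oriented pI tools) and `"emboss"`. The choice shifts pI
#' distributions slightly, so it is explicit and configurable.
#'
#' @param name set name.
#' @return named numeric vector with entries `nterm`, `cterm`, `C`, `D`,
#'   `E`, `H`, `K`, `R`, `Y` (pH units).
#' @export
pk_set <- function(name = "bjellqvist") {
  tab <- pk_set_table()
  sub <- tab[tab$set == name, ]
  if (!nrow(sub)) {
    stop_ctx("unknown pK set '", name, "'; available: ",
             paste(unique(tab$set), collapse = ", "))
  }
  setNames(sub$pk, sub$group)
}

# Net charge at given pH values for a residue-composition matrix.
# comp: matrix with columns C, D, E, H, K, R, Y (counts per sequence).
net_charge <- function(ph, comp, pks) {
  basic <- cbind(nterm = 1, K = comp[, "K"], R = comp[, "R"], H = comp[, "H"])
  acidic <- cbind(cterm = 1, D = comp[, "D"], E = comp[, "E"],
                  C = comp[, "C"], Y = comp[, "Y"])
  q <- numeric(nrow(comp))
  for (g in colnames(basic)) q <- q + basic[, g] / (1 + 10^(ph - pks[[g]]))
  for (g in colnames(acidic)) q <- q - acidic[, g] / (1 + 10^(pks[[g]] - ph))
  q
}

#' Isoelectric point by bisection
#'
#' Solves the Henderson-Hasselbalch net-charge equation
#' \deqn{Q(pH) = \sum_{basic} \frac{1}{1+10^{pH-pK}} -
#'       \sum_{acidic} \frac{1}{1+10^{pK-pH}}}
#' for its unique zero on pH 0..14. Q is strictly decreasing in pH, so
#' bisection always converges; pI depends only on residue composition.
#' Sequences with residues outside the canonical 20 get `NA`.
#'
#' @param sequences character vector of uppercase sequences.
#' @param pks a pK set from [pk_set()].
#' @param tol bisection tolerance in pH units (default 0.001, below any
#'   reporting precision).
#' @return numeric vector of pI values (NA where undefined).
#' @export
#' @examples
#' isoelectric_point("GGGG")  # (pK_nterm + pK_cterm) / 2
isoelectric_point <- function(sequences, pks = pk_set(), tol = 0.001) {
  stopifnot(is.character(sequences), all(nzchar(sequences)), tol > 0)
  counts <- Biostrings::letterFrequency(Biostrings::BStringSet(sequences),
                                        letters = LETTERS)
  canonical <- residue_mass_table()$residue
  bad <- rowSums(counts[, setdiff(LETTERS, canonical), drop = FALSE]) > 0
  comp <- counts[, c("C", "D", "E", "H", "K", "R", "Y"), drop = FALSE]
  lo <- rep(0, length(sequences)); hi <- rep(14, length(sequences))
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    q <- net_charge(mid, comp, pks)
    pos <- q > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  out <- (lo + hi) / 2
  out[bad] <- NA_real_
  out
}

#' Annotate peptides with mass and pI
#'
#' Adds `mono_mass` and `pi` columns to a peptide table or the `peptides`
#' component of a `digest_result`. Entries containing ambiguous residues
#' get `NA` in both columns and are excluded from downstream MW/pI
#' distributions (their count is what the summaries report as excluded).
#'
#' @param x a `digest_result` or a peptide data.frame with a `sequence`
#'   column.
#' @param model a [mass_model()].
#' @param pks a [pk_set()].
#' @param tol pI tolerance.
#' @return same shape as `x`, annotated.
#' @export
peptide_physchem <- function(x, model = mass_model(), pks = pk_set(), tol = 0.001) {
  if (inherits(x, "digest_result")) {
    x$peptides <- peptide_physchem(x$peptides, model, pks, tol)
    return(x)
  }
  stopifnot(is.data.frame(x), "sequence" %in% names(x))
  x$mono_mass <- mono_mass(x$sequence, model)
  x$pi <- isoelectric_point(x$sequence, pks, tol)
  x
}
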