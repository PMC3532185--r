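---
title: "seedscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seedscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscape)
```

## What the package models

Bottom-up proteomics identifies proteins through their protease-digested
peptides, so whether a protein is *identifiable at all* is a property of its
sequence: if none of its tryptic peptides falls inside the instrument's
usable peptide-mass range, the protein is invisible no matter how abundant
it is. seedscape formalises both sides of that question:

1. **Theoretical side** — digest a protein database in silico, compute each
   peptide's monoisotopic mass and isoelectric point, and count, for any
   peptide-mass window, the proteins left with 0, 1, 2, ... detectable
   peptides.
2. **Experimental side** — merge replicated label-free identification
   tables into one protein table with repeat-rate filtering, and summarise
   it: percent of total soluble protein (%TSP), repeat-rate composition,
   abundance dynamic range, keyword and functional-category shares.

## Digestion model

Trypsin is modelled by the Keil rule: cleave C-terminal to K or R unless
the next residue is proline. Suppression is configurable
(`cleavage_rule(apply_suppression = FALSE)`) because tools differ on this
point, and disabling it can only add cleavage sites (a property the test
suite asserts). The missed-cleavage semantics are strict: a peptide with
exactly *m* missed cleavages spans *m* internal sites, and for a protein
with *k* fully cleaved fragments there are exactly `max(0, k - m)` such
peptides, so allowing one missed cleavage yields `2k - 1` peptides per
protein. No semi-tryptic or non-specific products are generated, the
initiator methionine is not removed (the literal sequence is digested), and
no length/mass filter is applied at the digestion stage — filtering belongs
to the detectability windows downstream.

Coordinates are 1-based inclusive `[start, end]`, the R/IRanges convention,
so `sequence == substr(parent, start, end)` holds for every row.

## Mass and pI

Monoisotopic masses are residue sums plus one water (18.0105646 Da);
proton mass 1.0072765 Da; `mz = (M + z·p)/z`. The residue table and the pK
sets ship as plain-text files under `inst/extdata/` so alternates can be
added without code changes. Fixed modifications default to *off* because
theoretical-database statistics predate any search configuration; a
`"carbamidomethyl-C"` preset (+57.021464 Da) matches the usual alkylation
when experiment-matched masses are wanted.

The isoelectric point solves the Henderson–Hasselbalch net charge

$$Q(\mathrm{pH}) = \sum_{\text{basic}} \frac{1}{1+10^{\mathrm{pH}-pK}}
 - \sum_{\text{acidic}} \frac{1}{1+10^{pK-\mathrm{pH}}}$$

with basic groups {N-terminus, K, R, H} and acidic groups
{C-terminus, D, E, C, Y}. Q is strictly decreasing in pH, so the zero is
unique and bisection on [0, 14] converges unconditionally; the default
tolerance (0.001 pH) sits below any reporting precision. The default pK
set is Bjellqvist, with EMBOSS selectable by name — the choice shifts pI
distributions by a few tenths of a unit, which is why it is explicit.
Sequences containing residues outside the canonical twenty (B, J, O, U, X,
Z) get `NA` mass and pI: guessing masses for ambiguity codes would bias
distribution statistics, so such entries are excluded and counted instead.

## Detectability windows

Windows are open intervals by default — `500 < x < 1000` taken literally —
with flags for closed bounds, and `upper = Inf` for unbounded tails.
Detectability is a per-protein question, so counting uses peptide
occurrences within each protein, not database-wide unique sequences: a
peptide shared by two proteins evidences both. Undefined-mass peptides
never count as detectable. Reported percentages round half away from zero
at the stated decimals, matching the two-decimal style of published
tables (base R's round-half-to-even would disagree on exact halves).

## Replicate merging and quantification

The merge takes per-replicate protein tables keyed by accession. Repeat
rate is the number of replicates containing the protein; numeric fields
are arithmetic means over the replicates where present; `fmol_variation`
is the coefficient of variation (sd/mean) of per-replicate fmol, left
blank under two observations — CV is the standard replicate-variation
statistic, adopted here because the source tables' corresponding column is
otherwise undefined. Rows under the minimum repeat rate (default 2, of 4
replicates) are dropped; sorting is ng descending with accession as
tie-break, so output order is deterministic and invariant to replicate
order.

%TSP is `100 · ng / Σng` over the rows carrying a ng value; rows with
absent ng are kept but blank and excluded from the denominator
(absent is not zero). Unrounded shares sum to exactly 100; the reported
column is rounded to two decimals. Dynamic range is
`floor(log10(max / min positive ng))` — complete decades, zero-ng rows
excluded from the minimum.

Peptide match types form a closed vocabulary (`MATCH_TYPES`): first- and
second-pass database matches, variable-modification matches, in-source
fragmentation, missed-cleavage matches, and two neutral losses. Unknown
strings are an error rather than a silent "other", preventing category
drift. The ppm-error summary uses strict `|e| < threshold`.

The functional-category ruleset (`default_category_rules()`) is an ordered
keyword list (first match wins, fallback "uncharacterized/other"). It is a
documented approximation — no published ruleset exists for this
clustering — and is deliberately not an acceptance surface.

## The synthetic world

`generate_database()` plants known structure: exact duplicate records
(emulating redundant public-database entries) and truncated "Fragment"
copies, both listed in a manifest, with log-normal lengths clamped to
50–800 residues and uniform or storage-globulin-like residue composition.
`generate_replicates()` encodes the stated world of a typical
seed-proteome DIA experiment: 4 technical replicates, 113 true proteins,
abundances log-normal over 3 decades (log10 abundance ~ N(1.5, 0.5)),
~3,400 peptide identifications, match-type probabilities 58% / 6% / 17% /
13% for first-pass / second-pass / missed-cleavage / in-source (the
unpinned 6% remainder is split 4% variable-modification and 1% per
neutral loss — a one-time choice), and ppm errors Normal(0, σ) with σ
solved from `P(|e| < 5) = 0.82` via the normal quantile (σ ≈ 3.73 ppm).
Detection follows a logistic curve over log10 abundance (midpoint at 15%
of the abundance span, slope 4), so repeat rate correlates with abundance
as in real data; a constant-probability override and a direct
repeat-rate-assignment mode exist for exact tests. Every detected
(protein, replicate) pair receives at least one peptide so protein and
peptide tables are mutually consistent.

What the generator does *not* emulate: raw spectra, retention time, ion
mobility, intensity-level noise, shared/degenerate peptides between
proteins, or search-engine scoring. A green synthetic test therefore
establishes that the *arithmetic* of merging and summarising is right and
that planted parameters are recovered within binomial sampling error — it
says nothing about identification quality on real data.

## Numerical choices

* Rounding: half away from zero everywhere percentages are reported
  (two decimals per-row, integer percents for summary fractions).
* pI bisection: domain [0, 14], tol 0.001; an independent 1e-4 grid-search
  oracle in the tests agrees within tolerance.
* Window bounds: strict inequalities by default; boundary masses are
  excluded, asserted explicitly.
* Degenerate inputs: empty sequences, empty rulesets, all-absent ng
  columns, zero denominators and unknown match types are errors with
  named messages; undefined mass/pI is a value (`NA`), not an error.
* Determinism: generators take explicit integer seeds and reproduce
  byte-identical outputs; the pipeline itself is deterministic given its
  inputs.

## Known limitations

* Whole-database absolute counts from any particular public-database
  snapshot are not reproducible (snapshots change); the package instead
  proves its operators against brute-force oracles and reruns the full
  assessment on any user-supplied FASTA.
* The protein `protein_mw` column of merged tables is carried from input,
  not recomputed; whether a given source reports monoisotopic or average
  mass is input-dependent.
* pI prediction ignores cysteine modification state and local sequence
  context; it is composition-only, as in standard gel-oriented tools.
* Only fully tryptic peptides are modelled; chymotryptic or semi-specific
  searches need a different rule than the one shipped.
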