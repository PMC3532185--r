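Package: seedscape
Title: In-Silico Proteome Digestion and Label-Free MS Identification Table Analysis
Version: 0.1.0
Authors@R:
    person("Seedscape", "Maintainers", email = "maintainers@seedscape.dev",
           role = c("aut", "cre"))
Description: Tools for assessing proteome detectability in bottom-up
    mass-spectrometry experiments. Performs theoretical protease digestion
    of protein FASTA databases with missed-cleavage enumeration, computes
    peptide and protein monoisotopic masses and isoelectric points, and
    summarises detectability over peptide-mass windows. Also parses, merges
    and quantifies replicated label-free protein identification tables
    (repeat rate, percent of total soluble protein, dynamic range, keyword
    and functional-category shares), and generates seeded synthetic
    databases and replicate runs with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
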