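Package: varcog
Title: Protein Family Variability from Alignment Column Homogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Alignment-based estimation of protein sequence variability for
    clade-specific clusters of orthologous genes (csCOGs). Scores multiple
    protein alignment columns for homogeneity against a substitution matrix
    (BLOSUM62 by default), converts family- and position-level homogeneity
    into clade-normalized relative variability, compares families by the
    geometry of their smoothed homogeneity distributions (Hellinger
    distances, classical multidimensional scaling), carves clade-specific
    orthologous groups out of genome-labeled gene trees by a
    coverage-paralogy tradeoff index, interprets ancestral-presence
    posterior probabilities into gene gain and loss events, and detects
    microsatellite-like regions in coding nucleotide sequences by binomial
    significance of local k-mer recurrences. Includes generators for
    synthetic alignments, gene trees, presence histories and repeat-bearing
    sequences with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
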