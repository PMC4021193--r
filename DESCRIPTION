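Package: famevol
Title: Gene-Family Expansion and Molecular-Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of plant gene superfamilies
    such as the expansins: domain-based family identification with open
    reading frame checks and protein pI/Mw statistics, neighbor-joining
    phylogenies with reference-guided subfamily assignment, tandem and
    segmental duplication detection with Ks-based dating and 4DTv,
    Nei-Gojobori Ka/Ks estimation, a GY94 codon-substitution likelihood
    engine with site models (M0, M3, M7, M8) and the branch-site model of
    positive selection, type-I and type-II functional-divergence estimators
    with critical amino acid site calling, RPKM expression profiling with
    Pearson-correlation clustering and tissue-specificity classification,
    and IUPAC cis-element scanning of promoter sequences. A seeded
    synthetic-data generator simulates codon alignments under the selection
    models, genome layouts with planted duplications, expression matrices,
    and promoters with planted motifs, so every stage of the pipeline is
    testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    stats
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
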