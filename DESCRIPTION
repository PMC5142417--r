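Package: nmdscreen
Title: Identify NMD Targets from mRNA Decay Time Courses and Screen
    Termination-Codon Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies transcripts as stabilized, destabilized, or
    unaffected from replicated pulse-chase (BRIC-seq style) mRNA decay
    time courses following knockdown of a decay factor, using
    error-propagated curve contrasts rather than half-life fits.
    Computes a 63-feature catalog of termination-codon-proximal sequence
    composition (mono- and dinucleotide densities, nucleotide-run counts
    and their chi-square statistics, upstream ORF / 3'UTR intron / ALU
    annotations), prunes it to a non-redundant set by Spearman
    correlation, and screens features between transcript classes with
    the common-language effect size, Mann-Whitney and Fisher tests under
    FDR control, plus Kruskal-Wallis/Dunn three-group comparisons of RNA
    secondary-structure stability (minimum free energy) around the stop
    codon. Ships a synthetic-data generator with planted decay classes
    and controllable nucleotide enrichment so the whole workflow is
    testable without external data, and a base-pairing fallback fold
    engine alongside an external RNAfold binding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
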