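#!/usr/bin/env Rscript

# Stage 3: build the 63-feature catalog and prune it.
#
# Computes, per transcript, the termination-codon-proximal composition
# features (mono/dinucleotide densities, run counts and their chi-square
# statistics over the 3'UTR and the last 20 CDS bases, lengths, ALU
# density, four binary annotations), then removes features that are
# Spearman-correlated (|R| >= 0.7) with a higher-ranked one, ranking by
# effect size between the stabilized and unaffected classes.  Writes
# results/features.tsv, results/features_meta.tsv,
# results/nonredundant.txt.

suppressPackageStartupMessages(library(nmdscreen))

ts <- read_transcript_set(
  "results/data/transcripts/transcripts.fasta",
  "results/data/transcripts/regions.tsv",
  uorfs = "results/data/transcripts/uorfs.tsv",
  introns = "results/data/transcripts/introns.tsv",
  alus = "results/data/transcripts/alus.tsv")
cls <- read.delim("results/classification.tsv")
labels <- setNames(cls$label, cls$transcript_id)

fm <- build_feature_matrix(ts)
write_feature_matrix(fm, "results/features.tsv",
                     "results/features_meta.tsv")

kept <- prune_redundant(fm, labels)
writeLines(kept, "results/nonredundant.txt")

cat("catalog:", ncol(fm), "features (",
    sum(attr(fm, "meta")$binary), "binary ) for", nrow(fm),
    "transcripts\n")
cat("non-redundant set:", length(kept), "features\n")
cat("dropped as redundant:",
    paste(setdiff(attr(fm, "meta")$feature, kept)[1:8], collapse = ", "),
    "...\n")
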