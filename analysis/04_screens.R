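#!/usr/bin/env Rscript

# Stage 4: screen the non-redundant features between transcript classes.
#
# For each class pair (stabilized vs unaffected, destabilized vs
# unaffected, stabilized vs destabilized): Mann-Whitney tests with
# BH correction and common-language effect sizes for the non-binary
# features, Fisher exact tests for the binaries; a feature discriminates
# when q < 0.05 and |A - 0.5| >= 0.1.  Writes results/screen_<pair>.tsv.

suppressPackageStartupMessages(library(nmdscreen))

fm <- read_feature_matrix("results/features.tsv",
                          "results/features_meta.tsv")
cls <- read.delim("results/classification.tsv")
labels <- setNames(cls$label, cls$transcript_id)
kept <- readLines("results/nonredundant.txt")

pairs <- list(stabilized_vs_unaffected = c("stabilized", "unaffected"),
              destabilized_vs_unaffected = c("destabilized", "unaffected"),
              stabilized_vs_destabilized = c("stabilized", "destabilized"))
for (nm in names(pairs)) {
  p <- pairs[[nm]]
  sc <- screen_features(fm, labels, group_a = p[1], group_b = p[2],
                        features = kept)
  out <- rbind(sc$nonbinary, sc$binary)
  write.table(out, paste0("results/screen_", nm, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hits <- out$feature[which(out$flag)]
  cat(nm, ":", length(hits), "discriminative feature(s)",
      if (length(hits)) paste0("[", paste(hits, collapse = ", "), "]"),
      "\n")
}
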