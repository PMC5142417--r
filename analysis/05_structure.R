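#!/usr/bin/env Rscript

# Stage 5: RNA secondary-structure stability around the stop codon.
#
# Folds the last 60 CDS bases and the whole 3'UTR of every transcript
# with the fallback base-pairing engine, compares absolute MFE across
# the stabilized / destabilized / unaffected classes (Kruskal-Wallis +
# Dunn, Sidak-corrected critical Q) and across the stability tertiles of
# the stabilized class.  Writes results/mfe.tsv,
# results/mfe_three_group.tsv, results/mfe_tertiles.tsv.

suppressPackageStartupMessages(library(nmdscreen))

ts <- read_transcript_set(
  "results/data/transcripts/transcripts.fasta",
  "results/data/transcripts/regions.tsv")
cls <- read.delim("results/classification.tsv")
labels <- setNames(cls$label, cls$transcript_id)

mfe <- tc_region_mfe(ts, upstream_window = 60, engine = fold_engine("fallback"))
write.table(mfe, "results/mfe.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

rows <- list(); trows <- list()
for (rg in c("upstream_tc", "utr3")) {
  d <- mfe[mfe$region == rg, ]
  lab <- labels[d$transcript_id]
  keep <- lab %in% c("stabilized", "destabilized", "unaffected")
  kd <- kruskal_dunn(d$abs_mfe[keep], lab[keep])
  cat(sprintf("%s: Kruskal-Wallis p = %.3g\n", rg, kd$p))
  print(kd$pairs, digits = 3)
  rows[[rg]] <- cbind(region = rg, kd$pairs)

  stab <- cls[cls$label == "stabilized", ]
  if (nrow(stab) >= 3 && length(unique(stab$stability_group)) >= 2) {
    tg <- setNames(stab$stability_group, stab$transcript_id)[d$transcript_id]
    kt <- kruskal_dunn(d$abs_mfe[!is.na(tg)], tg[!is.na(tg)])
    trows[[rg]] <- cbind(region = rg, kt$pairs)
  }
}
write.table(do.call(rbind, rows), "results/mfe_three_group.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
if (length(trows))
  write.table(do.call(rbind, trows), "results/mfe_tertiles.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
cat("fold engine: fallback (pseudo-energy); outputs under results/\n")
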