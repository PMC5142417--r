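NUCLEOTIDES <- c("A", "C", "G", "T")
DINUCLEOTIDES <- as.vector(outer(NUCLEOTIDES, NUCLEOTIDES, paste0))
RUN_LENGTHS <- 3:7

check_seq <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) stop("`seq` must be a string")
  if (nchar(seq) > 0L && grepl("[^ACGT]", seq))
    stop("sequence must be over the alphabet {A, C, G, T}")
  seq
}

#' Mononucleotide density
#'
#' Fraction of positions of a sequence occupied by one nucleotide.
#' Undefined (`NA`) for the empty sequence.
#'
#' @param seq A string over A/C/G/T.
#' @param nt Single nucleotide.
#' @return Density in \[0, 1\], or `NA` for an empty sequence.
#' @export
mono_density <- function(seq, nt) {
  check_seq(seq)
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  sum(strsplit(seq, "", fixed = TRUE)[[1L]] == nt) / n
}

#' Dinucleotide density
#'
#' Overlapping occurrence count of a dinucleotide divided by
#' `length - 1` (the number of overlapping windows).  Undefined (`NA`)
#' for sequences shorter than 2 bases.
#'
#' @param seq A string over A/C/G/T.
#' @param dinuc Two-letter string, e.g. `"AG"`.
#' @return Density in \[0, 1\], or `NA` when fewer than 2 bases.
#' @export
dinuc_density <- function(seq, dinuc) {
  check_seq(seq)
  n <- nchar(seq)
  if (n < 2L) return(NA_real_)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  sum(paste0(ch[-n], ch[-1L]) == dinuc) / (n - 1L)
}

#' Observed counts of maximal nucleotide runs
#'
#' Counts maximal runs (stretches of identical consecutive nucleotides not
#' extendable on either side) of one nucleotide, binned by exact length
#' m = 3..7; maximal runs longer than 7 are counted in the m = 7 bin so
#' that no observed run is discarded.
#'
#' @param seq A string over A/C/G/T.
#' @param nt Single nucleotide.
#' @return Integer vector `O` named `m3`..`m7`.
#' @export
run_counts <- function(seq, nt) {
  check_seq(seq)
  if (nchar(seq) == 0L)
    return(stats::setNames(integer(5), paste0("m", RUN_LENGTHS)))
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1L]])
  len <- r$lengths[r$values == nt]
  O <- vapply(RUN_LENGTHS, function(m)
    if (m < 7L) sum(len == m) else sum(len >= 7L), integer(1))
  stats::setNames(O, paste0("m", RUN_LENGTHS))
}

#' Expected counts of nucleotide runs
#'
#' Under a memoryless model with per-position density `density`, the
#' probability of a run of exactly m identical nucleotides is
#' `density^m * (1 - density)^2`, and for a sequence of length `len` the
#' expected run count is that probability times `len`.
#'
#' @param density Nucleotide density in \[0, 1\].
#' @param len Sequence length (>= 0).
#' @return Numeric vector `E` named `m3`..`m7`.
#' @export
expected_runs <- function(density, len) {
  if (!is.numeric(density) || density < 0 || density > 1)
    stop("`density` must lie in [0, 1]")
  if (!is.numeric(len) || len < 0) stop("`len` must be >= 0")
  stats::setNames(density^RUN_LENGTHS * (1 - density)^2 * len,
                  paste0("m", RUN_LENGTHS))
}

#' Run-count goodness-of-fit chi-square statistic
#'
#' With `n_O = sum(O)` and `n_E = sum(E)`, computes
#' `sum_m (sqrt((n_O / n_E) * E_m) - sqrt((n_E / n_O) * O_m))^2 /
#' (E_m + O_m)`, skipping terms whose denominator is zero.  Defined as 0
#' when either total vanishes.  Large values flag run-count spectra that
#' deviate from the density-based expectation.
#'
#' @param O Observed run counts, indexed m = 3..7 ([run_counts()]).
#' @param E Expected run counts, same indexing ([expected_runs()]).
#' @return The statistic (>= 0).
#' @export
run_chi2 <- function(O, E) {
  if (length(O) != length(E)) stop("`O` and `E` must have equal length")
  if (any(O < 0) || any(E < 0)) stop("`O` and `E` must be non-negative")
  n_O <- sum(O); n_E <- sum(E)
  if (n_O == 0 || n_E == 0) return(0)
  keep <- (O + E) > 0
  sum((sqrt(n_O / n_E * E[keep]) - sqrt(n_E / n_O * O[keep]))^2 /
        (E[keep] + O[keep]))
}

#' Binary annotation features
#'
#' Derives the four 0/1 flags from the interval annotations of a
#' transcript set: `tuorf` (a translated uORF strictly within the 5'UTR),
#' `tovorf` (a uORF overlapping the main ORF), `sejc` (a 3'UTR intron
#' less than 55 bases downstream of the termination codon, i.e. an EJC
#' shallow enough to be cleared by the terminating ribosome's footprint)
#' and `alu` (an ALU interval in the 3'UTR).
#'
#' @param ts A `transcript_set`.
#' @return Data frame `transcript_id`, `tuorf`, `tovorf`, `sejc`, `alu`
#'   (integer 0/1).
#' @export
binary_features <- function(ts) {
  ids <- names(ts$sequences)
  flag <- function(hit_ids) as.integer(ids %in% hit_ids)
  data.frame(
    transcript_id = ids,
    tuorf = flag(ts$uorfs$transcript_id[!ts$uorfs$overlaps_cds]),
    tovorf = flag(ts$uorfs$transcript_id[ts$uorfs$overlaps_cds]),
    sejc = flag(ts$introns$transcript_id[ts$introns$pos < 55]),
    alu = flag(ts$alus$transcript_id),
    stringsAsFactors = FALSE)
}

region_feature_block <- function(seqs, prefix) {
  n <- length(seqs)
  out <- matrix(NA_real_, n, 4 + 16 + 4 + 4,
                dimnames = list(names(seqs), c(
                  paste0(prefix, "_", NUCLEOTIDES),
                  paste0(prefix, "_", DINUCLEOTIDES),
                  paste0(prefix, "_runs_", NUCLEOTIDES),
                  paste0(prefix, "_chi2_", NUCLEOTIDES))))
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    len <- nchar(s)
    if (len == 0L) next
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    dens <- vapply(NUCLEOTIDES, function(nt) sum(ch == nt) / len, numeric(1))
    out[i, paste0(prefix, "_", NUCLEOTIDES)] <- dens
    if (len >= 2L) {
      dimer <- paste0(ch[-len], ch[-1L])
      out[i, paste0(prefix, "_", DINUCLEOTIDES)] <-
        vapply(DINUCLEOTIDES, function(d) sum(dimer == d) / (len - 1L),
               numeric(1))
    }
    r <- rle(ch)
    for (nt in NUCLEOTIDES) {
      rl <- r$lengths[r$values == nt]
      O <- vapply(RUN_LENGTHS, function(m)
        if (m < 7L) sum(rl == m) else sum(rl >= 7L), integer(1))
      out[i, paste0(prefix, "_runs_", nt)] <- sum(O)
      out[i, paste0(prefix, "_chi2_", nt)] <-
        run_chi2(O, expected_runs(dens[[nt]], len))
    }
  }
  out
}

#' Build the 63-feature catalog
#'
#' Computes, for every transcript of a `transcript_set`, the full catalog
#' of termination-codon-proximal features: the four binary annotation
#' flags, 3'UTR and CDS lengths, ALU density (fraction of 3'UTR bases
#' covered by ALU intervals), and -- for each of the two sequence windows,
#' the entire 3'UTR and the last 20 CDS bases (stop codon included) --
#' the 4 mononucleotide densities, 16 overlapping dinucleotide densities,
#' 4 per-nucleotide total run counts and 4 run chi-square statistics.
#' That is 4 + 2 + 1 + 2 x (4 + 16 + 4 + 4) = 63 features, 4 of them
#' binary.
#'
#' Cells whose window is undefined (empty 3'UTR; windows shorter than 2
#' bases for dinucleotides) are marked `NA`, never silently 0.
#'
#' @param ts A `transcript_set`.
#' @return A data frame of class `feature_matrix` (rownames = transcript
#'   ids, 63 columns) with attribute `meta`: a data frame
#'   `feature`/`binary`/`region` describing every column.
#' @export
build_feature_matrix <- function(ts) {
  ids <- names(ts$sequences)
  utr3 <- region_seqs(ts, "utr3")
  cds <- region_seqs(ts, "cds")
  cds20 <- cds_tail_seqs(ts, 20L)
  bin <- binary_features(ts)

  utr3_b <- region_bounds(ts, "utr3")
  utr3_len <- utr3_b$end - utr3_b$start
  alu_cov <- numeric(length(ids))
  if (nrow(ts$alus)) {
    for (j in seq_len(nrow(ts$alus))) {
      i <- match(ts$alus$transcript_id[j], ids)
      ov <- min(ts$alus$end[j], utr3_b$end[i]) -
        max(ts$alus$start[j], utr3_b$start[i])
      if (ov > 0) alu_cov[i] <- alu_cov[i] + ov
    }
  }
  alu_density <- ifelse(utr3_len > 0, alu_cov / utr3_len, NA_real_)

  fm <- data.frame(
    tuorf = bin$tuorf, tovorf = bin$tovorf, sejc = bin$sejc, alu = bin$alu,
    utr3_length = as.numeric(utr3_len),
    cds_length = as.numeric(nchar(cds)),
    alu_density = alu_density,
    row.names = ids, check.names = FALSE)
  fm <- cbind(fm,
              as.data.frame(region_feature_block(utr3, "utr3")),
              as.data.frame(region_feature_block(cds20, "cds20")))

  meta <- data.frame(
    feature = names(fm),
    binary = names(fm) %in% c("tuorf", "tovorf", "sejc", "alu"),
    region = c(rep("annotation", 4), "utr3", "cds", "utr3",
               rep("utr3", 28), rep("cds20", 28)),
    stringsAsFactors = FALSE)
  stopifnot(nrow(meta) == 63L, sum(meta$binary) == 4L)
  attr(fm, "meta") <- meta
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Prune the feature catalog to a non-redundant set
#'
#' Ranks the non-binary features by the magnitude of their
#' common-language effect size, `|A - 0.5|`, between the stabilized and
#' unaffected transcripts, then scans them in rank order: each retained
#' feature eliminates every lower-ranked feature whose Spearman
#' correlation with it has magnitude at or above `r_cutoff`
#' (pairwise-complete over defined values).  The four binary features are
#' appended unconditionally.  Constant features get effect size 0.5 and
#' correlate with nothing, so they are never the cause of an elimination.
#'
#' @param fm A `feature_matrix`.
#' @param labels Class label per transcript, named by transcript id (or
#'   aligned with the rows of `fm`); only `"stabilized"` and
#'   `"unaffected"` rows enter the ranking.
#' @param r_cutoff Spearman magnitude at or above which a pair is
#'   considered redundant.
#' @return Character vector of retained feature names: non-binary
#'   survivors in rank order, then the binaries.
#' @export
prune_redundant <- function(fm, labels, r_cutoff = 0.7) {
  meta <- attr(fm, "meta")
  if (is.null(meta)) stop("`fm` must be a feature_matrix")
  if (nrow(fm) < 2L) stop("need at least 2 transcripts")
  if (!is.null(names(labels))) labels <- labels[rownames(fm)]
  if (length(labels) != nrow(fm))
    stop("`labels` must cover every row of `fm`")

  nonbin <- meta$feature[!meta$binary]
  X <- as.matrix(fm[, nonbin, drop = FALSE])
  a_rows <- which(labels == "stabilized")
  b_rows <- which(labels == "unaffected")
  if (length(a_rows) == 0L || length(b_rows) == 0L)
    stop("ranking needs both stabilized and unaffected transcripts")

  eff <- vapply(nonbin, function(f) {
    xa <- X[a_rows, f]; xb <- X[b_rows, f]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) == 0L || length(xb) == 0L) return(0.5)
    effect_size(xa, xb)
  }, numeric(1))
  ranked <- nonbin[order(-abs(eff - 0.5), nonbin)]

  R <- suppressWarnings(stats::cor(X, method = "spearman",
                                   use = "pairwise.complete.obs"))
  R[!is.finite(R)] <- 0    # constant columns correlate with nothing

  retained <- character(0)
  eliminated <- character(0)
  for (f in ranked) {
    if (f %in% eliminated) next
    retained <- c(retained, f)
    worse <- setdiff(ranked[match(f, ranked) < seq_along(ranked)], retained)
    eliminated <- union(eliminated, worse[abs(R[f, worse]) >= r_cutoff])
  }
  c(retained, meta$feature[meta$binary])
}
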