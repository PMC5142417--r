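write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read an abundance time-course table
#'
#' Tab-separated with columns `transcript_id`, `condition`, `replicate`,
#' `time_h`, `abundance`.
#'
#' @param tab Abundance table.
#' @param path File path.
#' @return `path` (write) or the table (read), invisibly for the writer.
#' @export
write_abundance <- function(tab, path) {
  validate_abundance(tab)
  write_tsv(tab[ABUNDANCE_COLS], path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  tab <- read_tsv(path)
  tab$replicate <- as.integer(tab$replicate)
  validate_abundance(tab)
  tab
}

#' Write a transcript set to FASTA plus interval tables
#'
#' Emits `transcripts.fasta` (sequences), `regions.tsv`
#' (transcript-relative 0-based half-open 5'UTR/CDS/3'UTR bounds),
#' `uorfs.tsv`, `introns.tsv` (positions downstream of the stop codon),
#' `alus.tsv` and `truth.tsv` into a directory.
#'
#' @param ts A `transcript_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_transcript_set <- function(ts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ts$sequences),
                              file.path(dir, "transcripts.fasta"))
  write_tsv(ts$regions, file.path(dir, "regions.tsv"))
  write_tsv(ts$uorfs, file.path(dir, "uorfs.tsv"))
  write_tsv(ts$introns, file.path(dir, "introns.tsv"))
  write_tsv(ts$alus, file.path(dir, "alus.tsv"))
  write_tsv(ts$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Write / read a feature matrix as TSV
#'
#' The values go to `path` (first column `transcript_id`), the column
#' metadata (binary flag, region tag) to `meta_path`, so that the matrix
#' can be reassembled with its typing intact.
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param path,meta_path Value and metadata file paths.
#' @return `path` (write) or the `feature_matrix` (read).
#' @export
write_feature_matrix <- function(fm, path, meta_path) {
  meta <- attr(fm, "meta")
  if (is.null(meta)) stop("`fm` must be a feature_matrix")
  write_tsv(cbind(transcript_id = rownames(fm), as.data.frame(fm)), path)
  write_tsv(meta, meta_path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, meta_path) {
  vals <- read_tsv(path)
  meta <- read_tsv(meta_path)
  fm <- vals[, setdiff(names(vals), "transcript_id"), drop = FALSE]
  rownames(fm) <- vals$transcript_id
  if (!identical(names(fm), meta$feature))
    stop("feature columns do not match the metadata table")
  attr(fm, "meta") <- meta
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Read a transcript set from FASTA plus interval tables
#'
#' Counterpart of [write_transcript_set()]; `uorfs`, `introns`, `alus`
#' and `truth` files are optional (empty annotations assumed).
#'
#' @param fasta FASTA of transcript sequences.
#' @param regions Region table (`transcript_id`, `region`, `start`,
#'   `end`).
#' @param uorfs,introns,alus,truth Optional paths to the interval /
#'   truth tables.
#' @return A `transcript_set`.
#' @export
read_transcript_set <- function(fasta, regions, uorfs = NULL,
                                introns = NULL, alus = NULL, truth = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  sequences <- stats::setNames(as.character(seqs), names(seqs))
  reg <- read_tsv(regions)
  need <- c("transcript_id", "region", "start", "end")
  if (!all(need %in% names(reg)))
    stop("region table needs columns ", paste(need, collapse = ", "))
  opt <- function(path, cols) {
    if (is.null(path))
      return(stats::setNames(
        as.data.frame(c(list(character(0)),
                        rep(list(integer(0)), length(cols) - 1L))), cols))
    read_tsv(path)
  }
  structure(list(
    sequences = sequences,
    regions = reg,
    uorfs = opt(uorfs, c("transcript_id", "start", "end", "overlaps_cds")),
    introns = opt(introns, c("transcript_id", "pos")),
    alus = opt(alus, c("transcript_id", "start", "end")),
    truth = if (is.null(truth)) NULL else read_tsv(truth),
    params = NULL), class = "transcript_set")
}
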