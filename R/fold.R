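#' Fold engines
#'
#' A fold engine maps an RNA/DNA sequence to the minimum free energy
#' (MFE) of its optimal secondary structure (<= 0; 0 for unpairable
#' sequences).  Two engines are provided:
#' \describe{
#'   \item{`fallback`}{a maximum base-pairing dynamic program with a
#'     minimum hairpin loop of 3 unpaired bases, scoring -1 per A:U or
#'     G:U pair and -2 per G:C pair; its value is a pseudo-energy, not
#'     kcal/mol, and must not be compared across engines.}
#'   \item{`rnafold`}{the external `RNAfold` binary (Vienna package) run
#'     with default parameters; requires the binary on the `PATH`.}
#' }
#' Sequences are transcribed T -> U before folding.  Both engines are
#' deterministic for a fixed sequence.
#'
#' @param name `"fallback"` or `"rnafold"`.
#' @return An object of class `fold_engine` with fields `name` and `fold`
#'   (a function sequence -> MFE).
#' @export
fold_engine <- function(name = c("fallback", "rnafold")) {
  name <- match.arg(name)
  fold <- switch(name,
    fallback = function(seq) nussinov_mfe_cpp(seq),
    rnafold = function(seq) rnafold_mfe(seq))
  if (name == "rnafold" && Sys.which("RNAfold") == "")
    stop("RNAfold binary not found on PATH; use the 'fallback' engine")
  structure(list(name = name, fold = fold), class = "fold_engine")
}

rnafold_mfe <- function(seq) {
  rna <- chartr("T", "U", seq)
  out <- tryCatch(
    system2("RNAfold", args = c("--noPS"), input = rna, stdout = TRUE,
            stderr = TRUE),
    error = function(e) stop("RNAfold engine failure: ", conditionMessage(e)))
  m <- regmatches(out, regexpr("\\(\\s*(-?[0-9]+\\.[0-9]+)\\)\\s*$", out))
  if (length(m) == 0L)
    stop("RNAfold engine failure: could not parse output: ",
         paste(out, collapse = " | "))
  as.numeric(gsub("[()\\s]", "", m[[length(m)]], perl = TRUE))
}

#' Minimum free energy of one sequence
#'
#' @param seq Non-empty string over A/C/G/T (T is read as U).
#' @param engine A [fold_engine()] (default: the fallback dynamic
#'   program).
#' @return A list with `mfe` (<= 0), `abs_mfe` and `engine`.
#' @examples
#' fold_mfe("GGGGAAAACCCC")$mfe  # -8 under the fallback scoring
#' @export
fold_mfe <- function(seq, engine = fold_engine("fallback")) {
  if (!inherits(engine, "fold_engine")) stop("`engine` must be a fold_engine")
  check_seq(seq)
  if (nchar(seq) == 0L) stop("cannot fold an empty sequence")
  mfe <- engine$fold(seq)
  if (is.na(mfe) || mfe > 0)
    stop("engine '", engine$name, "' returned an invalid MFE: ", mfe)
  list(mfe = mfe, abs_mfe = abs(mfe), engine = engine$name)
}

#' MFE profile around the termination codon
#'
#' Folds, for every transcript of a set, two regions independently: the
#' final `upstream_window` bases of the CDS (the sequence immediately
#' upstream of and including the stop codon) and the entire 3'UTR.  The
#' absolute MFE and its density (absolute MFE per base of the region)
#' are reported; 3'UTR rows of transcripts with an empty 3'UTR are
#' marked undefined.
#'
#' @param ts A `transcript_set`.
#' @param upstream_window Width in bases of the CDS-end window (must not
#'   exceed the CDS length).
#' @param engine A [fold_engine()].
#' @return Data frame: `transcript_id`, `region`
#'   (`upstream_tc` / `utr3`), `length`, `mfe`, `abs_mfe`, `density`,
#'   `engine`.
#' @export
tc_region_mfe <- function(ts, upstream_window = 60L,
                          engine = fold_engine("fallback")) {
  if (!inherits(engine, "fold_engine")) stop("`engine` must be a fold_engine")
  cds <- region_seqs(ts, "cds")
  if (any(nchar(cds) < upstream_window))
    stop("`upstream_window` exceeds the CDS length of some transcripts")
  up <- cds_tail_seqs(ts, as.integer(upstream_window))
  utr3 <- region_seqs(ts, "utr3")

  fold_block <- function(seqs, region) {
    len <- nchar(seqs)
    mfe <- rep(NA_real_, length(seqs))
    ok <- len > 0L
    mfe[ok] <- vapply(seqs[ok], engine$fold, numeric(1))
    data.frame(transcript_id = names(seqs), region = region,
               length = as.integer(len), mfe = mfe, abs_mfe = abs(mfe),
               density = ifelse(len > 0L, abs(mfe) / len, NA_real_),
               engine = engine$name, stringsAsFactors = FALSE,
               row.names = NULL)
  }
  out <- rbind(fold_block(up, "upstream_tc"), fold_block(utr3, "utr3"))
  rownames(out) <- NULL
  out
}
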