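# Independent oracles and small constructors used across the test files.

# effect size by explicit enumeration of all cross-group pairs
brute_effect_size <- function(x, y) {
  gt <- sum(outer(x, y, ">"))
  eq <- sum(outer(x, y, "=="))
  (gt + 0.5 * eq) / (length(x) * length(y))
}

# maximal-run counter by explicit left-to-right scanning
scan_runs <- function(seq, nt) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  O <- setNames(integer(5), paste0("m", 3:7))
  i <- 1L
  while (i <= n) {
    if (ch[i] == nt) {
      j <- i
      while (j < n && ch[j + 1L] == nt) j <- j + 1L
      len <- j - i + 1L
      if (len >= 3L) {
        b <- paste0("m", min(len, 7L))
        O[b] <- O[b] + 1L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  O
}

# exhaustive maximum base-pairing score: recursively enumerates every
# non-crossing structure with >= 3 unpaired bases in each hairpin loop,
# scoring 2 per G:C and 1 per A:U / G:U pair
oracle_pair_score <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("GC", "CG")) return(2L)
  if (p %in% c("AT", "TA", "GT", "TG", "AU", "UA", "GU", "UG")) return(1L)
  0L
}

oracle_fold_best <- function(ch) {
  n <- length(ch)
  if (n < 5L) return(0L)
  best <- oracle_fold_best(ch[-1L])
  for (k in 5:n) {
    s <- oracle_pair_score(ch[1L], ch[k])
    if (s > 0L) {
      inner <- oracle_fold_best(ch[2:(k - 1L)])
      outer <- if (k < n) oracle_fold_best(ch[(k + 1L):n]) else 0L
      best <- max(best, s + inner + outer)
    }
  }
  best
}

oracle_fold_mfe <- function(seq) {
  -oracle_fold_best(strsplit(seq, "", fixed = TRUE)[[1]])
}

rand_dna <- function(len, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
        collapse = "")
}

# abundance table from per-transcript replicate-by-time matrices
# (rows = replicates 1:2, cols = times 0/4/8/12)
make_abundance <- function(per_id) {
  times <- c(0, 4, 8, 12)
  rows <- lapply(names(per_id), function(id) {
    do.call(rbind, lapply(c("control", "knockdown"), function(cond) {
      m <- per_id[[id]][[cond]]
      data.frame(transcript_id = id, condition = cond,
                 replicate = rep(1:2, each = 4), time_h = rep(times, 2),
                 abundance = c(m[1, ], m[2, ]), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

flat_curves <- function(level = 1) {
  m <- matrix(level, 2, 4)
  list(control = m, knockdown = m)
}

# minimal transcript_set built by hand (annotations empty by default)
manual_ts <- function(seqs, utr5_len, cds_len, utr3_len,
                      uorfs = NULL, introns = NULL, alus = NULL) {
  ids <- names(seqs)
  n <- length(ids)
  utr5_len <- rep_len(utr5_len, n); cds_len <- rep_len(cds_len, n)
  utr3_len <- rep_len(utr3_len, n)
  stopifnot(nchar(seqs) == utr5_len + cds_len + utr3_len)
  empty <- function(cols) setNames(
    as.data.frame(c(list(character(0)),
                    rep(list(integer(0)), length(cols) - 1L))), cols)
  structure(list(
    sequences = seqs,
    regions = data.frame(
      transcript_id = rep(ids, each = 3),
      region = rep(c("utr5", "cds", "utr3"), n),
      start = as.vector(rbind(0L, utr5_len, utr5_len + cds_len)),
      end = as.vector(rbind(utr5_len, utr5_len + cds_len,
                            utr5_len + cds_len + utr3_len)),
      stringsAsFactors = FALSE),
    uorfs = if (is.null(uorfs))
      empty(c("transcript_id", "start", "end", "overlaps_cds")) else uorfs,
    introns = if (is.null(introns))
      empty(c("transcript_id", "pos")) else introns,
    alus = if (is.null(alus))
      empty(c("transcript_id", "start", "end")) else alus,
    truth = NULL, params = NULL), class = "transcript_set")
}

label_swap_map <- c(stabilized = "destabilized", destabilized = "stabilized",
                    unaffected = "unaffected", unclassified = "unclassified",
                    removed_nondecaying = "removed_nondecaying")

swap_conditions <- function(tab) {
  tab$condition <- ifelse(tab$condition == "control", "knockdown", "control")
  tab
}
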