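#' Parameters for the decay time-course simulator
#'
#' Bundles and validates the settings of [simulate_decay_dataset()].  The
#' simulator emulates a two-condition (control vs knockdown), two-replicate
#' pulse-chase experiment sampled at 0, 4, 8 and 12 h: each transcript decays
#' exponentially, and knocking down the decay factor multiplies the decay
#' rate of the planted "stabilized" and "destabilized" classes by
#' `effect_ratio`.
#'
#' @param n_transcripts Number of transcripts to simulate (the stable
#'   reference transcript is emitted in addition to these).
#' @param class_proportions Named fractions over
#'   `c("stabilized", "destabilized", "unaffected")`; must sum to 1.
#' @param base_decay_rate Control decay rate, per hour (> 0).
#' @param effect_ratio Named length-2 vector
#'   `c(stabilized = , destabilized = )`: multiplicative change of the
#'   knockdown decay rate for the two affected classes (< 1 stabilizes,
#'   > 1 destabilizes).  Unaffected transcripts keep the control rate.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise (>= 0; the noise has unit median).
#' @param initial_abundance Abundance at time 0, before noise (> 0).
#' @param seed Integer seed; the output is reproducible given the seed.
#' @return An object of class `sim_decay_params`.
#' @seealso [simulate_decay_dataset()]
#' @export
sim_decay_params <- function(n_transcripts = 1000,
                             class_proportions = c(stabilized = 0.05,
                                                   destabilized = 0.05,
                                                   unaffected = 0.90),
                             base_decay_rate = 0.15,
                             effect_ratio = c(stabilized = 0.3,
                                              destabilized = 3.0),
                             noise_cv = 0.05,
                             initial_abundance = 100,
                             seed = 1L) {
  n_transcripts <- as.integer(n_transcripts)
  if (is.na(n_transcripts) || n_transcripts < 1L)
    stop("`n_transcripts` must be a positive integer")
  cls <- c("stabilized", "destabilized", "unaffected")
  if (length(class_proportions) != 3L || is.null(names(class_proportions)) ||
      !setequal(names(class_proportions), cls))
    stop("`class_proportions` must be named over ",
         paste(cls, collapse = "/"))
  class_proportions <- class_proportions[cls]
  if (any(class_proportions < 0) || any(class_proportions > 1) ||
      abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must lie in [0, 1] and sum to 1")
  if (!is.numeric(base_decay_rate) || base_decay_rate <= 0)
    stop("`base_decay_rate` must be > 0")
  if (length(effect_ratio) != 2L || is.null(names(effect_ratio)) ||
      !setequal(names(effect_ratio), c("stabilized", "destabilized")))
    stop("`effect_ratio` must be named over stabilized/destabilized")
  effect_ratio <- effect_ratio[c("stabilized", "destabilized")]
  if (any(effect_ratio <= 0)) stop("`effect_ratio` entries must be > 0")
  if (!is.numeric(noise_cv) || noise_cv < 0) stop("`noise_cv` must be >= 0")
  if (!is.numeric(initial_abundance) || initial_abundance <= 0)
    stop("`initial_abundance` must be > 0")
  structure(list(n_transcripts = n_transcripts,
                 class_proportions = class_proportions,
                 base_decay_rate = base_decay_rate,
                 effect_ratio = effect_ratio,
                 noise_cv = noise_cv,
                 initial_abundance = initial_abundance,
                 seed = as.integer(seed)),
            class = "sim_decay_params")
}

# largest-remainder integer allocation; deterministic (ties by position)
allocate_counts <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Reserved identifier of the simulated stable reference transcript
#'
#' The decay simulator always emits one extra transcript with decay rate 0
#' in both conditions under this name.  Downstream normalization
#' ([normalize_to_reference()]) uses it as the stable anchor, playing the
#' role a housekeeping transcript (e.g. GAPDH) plays for real pulse-chase
#' quantifications.
#' @export
REF_STABLE <- "REF_STABLE"

#' Simulate a replicated decay time-course dataset with planted classes
#'
#' Draws, for every transcript, condition, replicate and time point,
#' `abundance = initial_abundance * exp(-lambda * t) * eps`, with `eps`
#' lognormal (unit median, CV = `noise_cv`) independent per cell.
#' `lambda` equals `base_decay_rate` in the control condition; in the
#' knockdown condition it is multiplied by the class `effect_ratio` for the
#' planted stabilized/destabilized classes and unchanged for unaffected
#' transcripts.  A stable reference transcript ([REF_STABLE]) with decay
#' rate 0 in both conditions is always appended.
#'
#' @param params A [sim_decay_params()] object.
#' @return A list with `abundance` (long data frame with columns
#'   `transcript_id`, `condition`, `replicate`, `time_h`, `abundance`),
#'   `truth` (data frame `transcript_id`, `class`; the reference transcript
#'   carries no truth row), and `ref_id`.
#' @examples
#' sim <- simulate_decay_dataset(sim_decay_params(n_transcripts = 20, seed = 7))
#' head(sim$abundance)
#' table(sim$truth$class)
#' @export
simulate_decay_dataset <- function(params) {
  if (!inherits(params, "sim_decay_params"))
    stop("`params` must come from sim_decay_params()")
  set.seed(params$seed)
  cls <- c("stabilized", "destabilized", "unaffected")
  counts <- allocate_counts(params$n_transcripts, params$class_proportions)
  classes <- rep(cls, counts)
  ids <- sprintf("TX%05d", seq_len(params$n_transcripts))
  truth <- data.frame(transcript_id = ids, class = classes,
                      stringsAsFactors = FALSE)

  ratio <- c(stabilized = unname(params$effect_ratio["stabilized"]),
             destabilized = unname(params$effect_ratio["destabilized"]),
             unaffected = 1)[classes]
  all_ids <- c(ids, REF_STABLE)
  lam <- cbind(control = c(rep(params$base_decay_rate, params$n_transcripts), 0),
               knockdown = c(params$base_decay_rate * unname(ratio), 0))

  times <- c(0, 4, 8, 12)
  grid <- expand.grid(time_h = times, replicate = 1:2,
                      condition = c("control", "knockdown"),
                      transcript_id = all_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lam_vec <- lam[cbind(match(grid$transcript_id, all_ids),
                       match(grid$condition, colnames(lam)))]
  mu <- params$initial_abundance * exp(-lam_vec * grid$time_h)
  if (params$noise_cv > 0) {
    sdlog <- sqrt(log1p(params$noise_cv^2))
    mu <- mu * rlnorm(nrow(grid), meanlog = 0, sdlog = sdlog)
  }
  grid$abundance <- mu
  tab <- grid[, c("transcript_id", "condition", "replicate", "time_h",
                  "abundance")]
  rownames(tab) <- NULL
  list(abundance = tab, truth = truth, ref_id = REF_STABLE)
}

#' Parameters for the transcript-sequence simulator
#'
#' Settings of [simulate_transcripts()].  Each simulated transcript is
#' `utr5_len + cds_len + utr3_len` bases of A/C/G/T; the CDS ends with a
#' stop codon.  `g_enrichment` is an additive boost to the G probability
#' applied within the last 20 CDS bases and the whole 3'UTR (the remaining
#' bases are scaled down proportionally so the composition still sums to 1,
#' making the realized G-density boost additive in expectation).
#' Binary annotations (translated uORFs strictly inside the 5'UTR, uORFs
#' overlapping the main ORF, 3'UTR introns < 55 bases downstream of the
#' stop codon, ALU intervals in the 3'UTR) are planted as interval
#' annotations with the given probabilities and recorded in the truth
#' table; they are never re-discovered from sequence.
#'
#' @param n_transcripts Number of transcripts.
#' @param utr5_len,cds_len,utr3_len Region lengths in bases.  `cds_len`
#'   must be a positive multiple of 3 of at least 23 (i.e. >= 24);
#'   `utr3_len` must be >= 1 (3'UTR features are undefined otherwise).
#' @param base_composition Named probabilities over A/C/G/T, summing to 1.
#' @param g_enrichment Additive boost to the G probability in the enriched
#'   windows (>= 0; `base_composition["G"] + g_enrichment` must be < 1).
#' @param p_tuorf,p_tovorf,p_sejc,p_alu Planting probabilities in \[0, 1\]
#'   for the four binary annotations.
#' @param seed Integer seed.
#' @return An object of class `sim_transcript_params`.
#' @export
sim_transcript_params <- function(n_transcripts = 600,
                                  utr5_len = 200, cds_len = 900,
                                  utr3_len = 300,
                                  base_composition = c(A = 0.27, C = 0.24,
                                                       G = 0.18, T = 0.31),
                                  g_enrichment = 0,
                                  p_tuorf = 0.10, p_tovorf = 0.05,
                                  p_sejc = 0.05, p_alu = 0.15,
                                  seed = 1L) {
  n_transcripts <- as.integer(n_transcripts)
  if (is.na(n_transcripts) || n_transcripts < 1L)
    stop("`n_transcripts` must be a positive integer")
  if (utr5_len < 0) stop("`utr5_len` must be >= 0")
  if (cds_len < 23 || cds_len %% 3 != 0)
    stop("`cds_len` must be a positive multiple of 3 (>= 23)")
  if (utr3_len < 1)
    stop("`utr3_len` must be >= 1: 3'UTR features are undefined for an ",
         "empty 3'UTR")
  nts <- c("A", "C", "G", "T")
  if (length(base_composition) != 4L || is.null(names(base_composition)) ||
      !setequal(names(base_composition), nts))
    stop("`base_composition` must be named over A/C/G/T")
  base_composition <- base_composition[nts]
  if (any(base_composition < 0) || any(base_composition > 1) ||
      abs(sum(base_composition) - 1) > 1e-9)
    stop("`base_composition` must lie in [0, 1] and sum to 1")
  if (g_enrichment < 0 || base_composition["G"] + g_enrichment >= 1)
    stop("`g_enrichment` must be >= 0 with G + g_enrichment < 1")
  probs <- c(p_tuorf = p_tuorf, p_tovorf = p_tovorf, p_sejc = p_sejc,
             p_alu = p_alu)
  if (any(probs < 0) || any(probs > 1))
    stop("planting probabilities must lie in [0, 1]")
  if (p_tuorf > 0 && utr5_len < 9)
    stop("`utr5_len` must be >= 9 to plant uORFs strictly within the 5'UTR")
  if (p_tovorf > 0 && utr5_len < 3)
    stop("`utr5_len` must be >= 3 to plant CDS-overlapping uORFs")
  structure(list(n_transcripts = n_transcripts, utr5_len = as.integer(utr5_len),
                 cds_len = as.integer(cds_len), utr3_len = as.integer(utr3_len),
                 base_composition = base_composition,
                 g_enrichment = g_enrichment,
                 p_tuorf = p_tuorf, p_tovorf = p_tovorf, p_sejc = p_sejc,
                 p_alu = p_alu, seed = as.integer(seed)),
            class = "sim_transcript_params")
}

# additive G boost, other bases scaled so the result sums to 1
enrich_g <- function(base, g) {
  if (g == 0) return(base)
  out <- base
  out["G"] <- base["G"] + g
  others <- setdiff(names(base), "G")
  out[others] <- base[others] * (1 - out["G"]) / (1 - base["G"])
  out
}

rand_seq <- function(len, comp) {
  if (len == 0) return("")
  paste(sample(names(comp), len, replace = TRUE, prob = comp), collapse = "")
}

#' Simulate annotated transcript sequences
#'
#' Generates a cohort of transcripts under [sim_transcript_params()]:
#' random sequences with the requested region structure, a stop codon at
#' the CDS end, G enrichment in the last 20 CDS bases and along the 3'UTR,
#' and planted interval annotations for the four binary features.
#'
#' All intervals are transcript-relative, 0-based and half-open; 3'UTR
#' intron positions are distances in bases downstream of the termination
#' codon.
#'
#' @param params A [sim_transcript_params()] object.
#' @param ids Optional character vector of transcript ids to use (its
#'   length overrides `params$n_transcripts`); defaults to `TX00001`, ...
#' @return An object of class `transcript_set`: a list with `sequences`
#'   (named character), `regions` (transcript_id/region/start/end),
#'   `uorfs` (transcript_id/start/end/overlaps_cds), `introns`
#'   (transcript_id/pos, pos downstream of the stop codon), `alus`
#'   (transcript_id/start/end), `truth` (planted binary flags) and
#'   `params`.
#' @examples
#' ts <- simulate_transcripts(sim_transcript_params(n_transcripts = 5, seed = 3))
#' ts$regions[ts$regions$transcript_id == "TX00001", ]
#' @export
simulate_transcripts <- function(params, ids = NULL) {
  if (!inherits(params, "sim_transcript_params"))
    stop("`params` must come from sim_transcript_params()")
  set.seed(params$seed)
  n <- if (is.null(ids)) params$n_transcripts else length(ids)
  if (is.null(ids)) ids <- sprintf("TX%05d", seq_len(n))
  if (anyDuplicated(ids)) stop("`ids` must be unique")

  u5 <- params$utr5_len; cl <- params$cds_len; u3 <- params$utr3_len
  base <- params$base_composition
  enr <- enrich_g(base, params$g_enrichment)
  stops <- c("TAA", "TAG", "TGA")
  total <- u5 + cl + u3

  has <- data.frame(tuorf = runif(n) < params$p_tuorf,
                    tovorf = runif(n) < params$p_tovorf,
                    sejc = runif(n) < params$p_sejc,
                    deep_intron = runif(n) < params$p_sejc & u3 > 56,
                    alu = runif(n) < params$p_alu)

  seqs <- character(n)
  uorfs <- list(); introns <- list(); alus <- list()
  for (i in seq_len(n)) {
    body_plain <- rand_seq(cl - 20L, base)
    body_enr <- rand_seq(17L, enr)
    stopc <- sample(stops, 1L)
    seqs[i] <- paste0(rand_seq(u5, base), body_plain, body_enr, stopc,
                      rand_seq(u3, enr))

    if (has$tuorf[i]) {
      len <- 3L * sample(3:max(3L, min(10L, u5 %/% 3L)), 1L)
      len <- min(len, u5)
      start <- sample.int(u5 - len + 1L, 1L) - 1L
      uorfs[[length(uorfs) + 1L]] <-
        data.frame(transcript_id = ids[i], start = start, end = start + len,
                   overlaps_cds = FALSE)
    }
    if (has$tovorf[i]) {
      off <- sample.int(min(12L, u5), 1L)
      ext <- 3L * sample(2:5, 1L)
      uorfs[[length(uorfs) + 1L]] <-
        data.frame(transcript_id = ids[i], start = u5 - off,
                   end = min(u5 + ext, total), overlaps_cds = TRUE)
    }
    if (has$sejc[i])
      introns[[length(introns) + 1L]] <-
        data.frame(transcript_id = ids[i], pos = sample(0:min(54L, u3 - 1L), 1L))
    if (has$deep_intron[i])
      introns[[length(introns) + 1L]] <-
        data.frame(transcript_id = ids[i], pos = sample(55:(u3 - 1L), 1L))
    if (has$alu[i]) {
      len <- min(300L, u3)
      start <- u5 + cl + sample.int(u3 - len + 1L, 1L) - 1L
      alus[[length(alus) + 1L]] <-
        data.frame(transcript_id = ids[i], start = start, end = start + len)
    }
  }

  bind <- function(lst, cols) {
    if (length(lst) == 0)
      return(stats::setNames(
        as.data.frame(c(list(character(0)),
                        rep(list(integer(0)), length(cols) - 1L))), cols))
    do.call(rbind, lst)
  }
  regions <- data.frame(
    transcript_id = rep(ids, each = 3L),
    region = rep(c("utr5", "cds", "utr3"), n),
    start = rep(c(0L, u5, u5 + cl), n),
    end = rep(c(u5, u5 + cl, total), n),
    stringsAsFactors = FALSE)

  structure(list(sequences = stats::setNames(seqs, ids),
                 regions = regions,
                 uorfs = bind(uorfs, c("transcript_id", "start", "end",
                                       "overlaps_cds")),
                 introns = bind(introns, c("transcript_id", "pos")),
                 alus = bind(alus, c("transcript_id", "start", "end")),
                 truth = data.frame(transcript_id = ids,
                                    tuorf = has$tuorf, tovorf = has$tovorf,
                                    sejc = has$sejc, alu = has$alu,
                                    stringsAsFactors = FALSE),
                 params = params),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  p <- x$params
  cat("transcript_set:", length(x$sequences), "transcripts",
      sprintf("(5'UTR %d / CDS %d / 3'UTR %d bases)\n",
              p$utr5_len, p$cds_len, p$utr3_len))
  cat("planted: ", sum(x$truth$tuorf), " tuORF, ", sum(x$truth$tovorf),
      " tovORF, ", sum(x$truth$sejc), " sEJC, ", sum(x$truth$alu),
      " ALU\n", sep = "")
  invisible(x)
}

# region sequence helpers -----------------------------------------------

region_bounds <- function(ts, region) {
  r <- ts$regions[ts$regions$region == region, ]
  r[match(names(ts$sequences), r$transcript_id), c("start", "end")]
}

#' Extract region sequences from a transcript set
#'
#' @param ts A `transcript_set`.
#' @param region One of `"utr5"`, `"cds"`, `"utr3"`.
#' @return Named character vector of region sequences (may contain empty
#'   strings for empty regions).
#' @export
region_seqs <- function(ts, region = c("utr3", "cds", "utr5")) {
  region <- match.arg(region)
  b <- region_bounds(ts, region)
  stats::setNames(substr(ts$sequences, b$start + 1L, b$end),
                  names(ts$sequences))
}

#' Last bases of each CDS (stop codon included)
#'
#' @param ts A `transcript_set`.
#' @param k Window width in bases; a CDS shorter than `k` contributes its
#'   whole sequence.
#' @return Named character vector.
#' @export
cds_tail_seqs <- function(ts, k = 20L) {
  cds <- region_seqs(ts, "cds")
  n <- nchar(cds)
  stats::setNames(substr(cds, pmax(1L, n - k + 1L), n), names(cds))
}
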