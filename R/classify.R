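ABUNDANCE_COLS <- c("transcript_id", "condition", "replicate", "time_h",
                    "abundance")
DECAY_TIMES <- c(0, 4, 8, 12)

validate_abundance <- function(tab) {
  if (!is.data.frame(tab) || !all(ABUNDANCE_COLS %in% names(tab)))
    stop("abundance table needs columns ",
         paste(ABUNDANCE_COLS, collapse = ", "))
  if (!all(tab$condition %in% c("control", "knockdown")))
    stop("`condition` must be 'control' or 'knockdown'")
  if (!all(tab$replicate %in% c(1L, 2L)))
    stop("`replicate` must be 1 or 2")
  if (!all(tab$time_h %in% DECAY_TIMES))
    stop("`time_h` must be one of ", paste(DECAY_TIMES, collapse = ", "))
  if (!is.numeric(tab$abundance) || any(!is.finite(tab$abundance)))
    stop("`abundance` must be finite numeric")
  key <- paste(tab$transcript_id, tab$condition, tab$replicate, tab$time_h)
  if (anyDuplicated(key))
    stop("duplicated abundance cell: ", key[anyDuplicated(key)])
  invisible(tab)
}

#' Scale abundances to a stable reference transcript
#'
#' Divides every abundance by the abundance of `ref_id` in the same
#' (condition, replicate, time) cell, mirroring the scaling of pulse-chase
#' expression levels to a stable housekeeping transcript.  The reference
#' row itself is removed from the output.
#'
#' @param tab Abundance table (columns `transcript_id`, `condition`,
#'   `replicate`, `time_h`, `abundance`).
#' @param ref_id Identifier of the reference transcript; it must be present
#'   with strictly positive abundance in every cell used by the table.
#' @return The normalized table, without the reference rows.
#' @export
normalize_to_reference <- function(tab, ref_id = REF_STABLE) {
  validate_abundance(tab)
  ref <- tab[tab$transcript_id == ref_id, ]
  if (nrow(ref) == 0L)
    stop("reference transcript '", ref_id, "' not found")
  cell <- function(d) paste(d$condition, d$replicate, d$time_h, sep = "/")
  out <- tab[tab$transcript_id != ref_id, ]
  m <- match(cell(out), cell(ref))
  if (anyNA(m))
    stop("reference transcript '", ref_id, "' missing cell ",
         cell(out)[which(is.na(m))[1L]])
  rv <- ref$abundance[m]
  bad <- which(rv <= 0)
  if (length(bad))
    stop("reference abundance not positive in cell ", cell(out)[bad[1L]])
  out$abundance <- out$abundance / rv
  rownames(out) <- NULL
  out
}

#' Replicate-pair contrast with propagated error
#'
#' For replicate pairs (`a1`, `a2`) and (`b1`, `b2`) computes the mean
#' difference `d = ((a1 + a2) - (b1 + b2)) / 2` and its propagated error
#' `dd = sqrt((a1 - a2)^2 + (b1 - b2)^2) / sqrt(2)`, treating each
#' replicate pair as a mean with standard error `|x1 - x2| / sqrt(2)`.
#' The ratio `z = d / dd` is set to `+Inf`/`-Inf` when `dd = 0` and
#' `d != 0`, and to 0 when both vanish (the limit of the normal tail).
#'
#' This single contrast underlies all three curve statistics: the control
#' decay contrast (time t vs 4 h, control replicates), the knockdown decay
#' contrast (time t vs 4 h, knockdown replicates), and the
#' control-vs-knockdown contrast at a fixed time.
#'
#' @param a1,a2,b1,b2 Numeric vectors (recycled together).
#' @return A data frame with columns `d`, `dd`, `z`.
#' @examples
#' contrast_stat(8, 12, 6, 6)  # d = 4, dd = 4 / sqrt(2)
#' @export
contrast_stat <- function(a1, a2, b1, b2) {
  if (any(!is.finite(c(a1, a2, b1, b2)))) stop("inputs must be finite")
  d <- 0.5 * ((a1 + a2) - (b1 + b2))
  dd <- sqrt((a1 - a2)^2 + (b1 - b2)^2) / sqrt(2)
  z <- ifelse(dd > 0, d / dd, ifelse(d > 0, Inf, ifelse(d < 0, -Inf, 0)))
  data.frame(d = d, dd = dd, z = z)
}

# transcripts x condition x replicate x time array; NA marks missing cells
abundance_array <- function(tab) {
  validate_abundance(tab)
  ids <- unique(tab$transcript_id)
  arr <- array(NA_real_,
               dim = c(length(ids), 2L, 2L, length(DECAY_TIMES)),
               dimnames = list(ids, c("control", "knockdown"), c("1", "2"),
                               as.character(DECAY_TIMES)))
  arr[cbind(match(tab$transcript_id, ids),
            match(tab$condition, c("control", "knockdown")),
            as.integer(tab$replicate),
            match(tab$time_h, DECAY_TIMES))] <- tab$abundance
  arr
}

#' Remove transcripts whose abundance does not decay with time
#'
#' For each condition, the abundance at t in {8, 12} h is contrasted with
#' the abundance at 4 h ([contrast_stat()]).  A rising curve gives a
#' positive contrast; its one-sided p-value `1 - pnorm(z)` is
#' Benjamini-Hochberg corrected across transcripts separately per
#' condition and time point, and any transcript with a corrected value
#' below `alpha` is removed.  Transcripts with missing cells are excluded
#' up front with reason `"incomplete"`.
#'
#' @param tab Normalized abundance table.
#' @param alpha Removal level for the corrected p-values.
#' @return A list: `retained` (abundance rows of the surviving
#'   transcripts), `removed` (data frame `transcript_id`, `reason` with
#'   reasons `incomplete`, `nondecaying_control`,
#'   `nondecaying_knockdown`), and `stats` (per transcript, condition and
#'   time: contrast `d`, error `dd`, `z`, `p`, `q`).
#' @export
filter_nondecaying <- function(tab, alpha = 0.05) {
  arr <- abundance_array(tab)
  inc <- apply(is.na(arr), 1L, any)
  removed <- data.frame(transcript_id = rownames(arr)[inc],
                        reason = rep("incomplete", sum(inc)),
                        stringsAsFactors = FALSE)
  arr <- arr[!inc, , , , drop = FALSE]
  ids <- rownames(arr)

  stats_rows <- list()
  drop_ids <- character(0)
  for (cond in c("control", "knockdown")) {
    for (t in c("8", "12")) {
      cs <- contrast_stat(arr[, cond, "1", t], arr[, cond, "2", t],
                          arr[, cond, "1", "4"], arr[, cond, "2", "4"])
      p <- pnorm(-cs$z)                     # 1 - Phi(z), rising curves small
      q <- p.adjust(p, method = "BH")
      stats_rows[[paste(cond, t)]] <-
        data.frame(transcript_id = ids, condition = cond,
                   time_h = as.numeric(t), d = cs$d, dd = cs$dd, z = cs$z,
                   p = p, q = q, stringsAsFactors = FALSE)
      hit <- ids[q < alpha]
      if (length(hit))
        removed <- rbind(removed,
                         data.frame(transcript_id = hit,
                                    reason = paste0("nondecaying_", cond),
                                    stringsAsFactors = FALSE))
      drop_ids <- union(drop_ids, hit)
    }
  }
  keep <- setdiff(ids, drop_ids)
  retained <- tab[tab$transcript_id %in% keep, ]
  rownames(retained) <- NULL
  removed <- removed[!duplicated(removed[c("transcript_id", "reason")]), ]
  rownames(removed) <- NULL
  list(retained = retained, removed = removed,
       stats = do.call(rbind, c(stats_rows, list(make.row.names = FALSE))))
}

#' Classify transcripts by their response to knockdown
#'
#' At each time t in {4, 8, 12} h the control-vs-knockdown contrast
#' `delta = mean(control) - mean(knockdown)` is computed with its
#' propagated error ([contrast_stat()]).  The stabilization p-value is the
#' left tail `pnorm(z)` (small when the knockdown curve lies above the
#' control curve) and the destabilization p-value is the right tail
#' `pnorm(-z)`; each is Benjamini-Hochberg corrected across transcripts
#' separately per time point.
#'
#' Under the `standard` criterion the evaluated times are 8 and 12 h;
#' under `strict`, 4, 8 and 12 h.  A transcript is
#' \describe{
#'   \item{stabilized}{corrected stabilization p <= `alpha` and all
#'     knockdown replicates above all control replicates, at every
#'     evaluated time;}
#'   \item{destabilized}{the mirror image (corrected destabilization
#'     p <= `alpha`, all control replicates above all knockdown ones);}
#'   \item{unaffected}{both corrected p-values > `alpha` at every
#'     evaluated time;}
#'   \item{unclassified}{anything else (inconsistent behavior).}
#' }
#' The stability change `S` is the median over 4/8/12 h of the
#' knockdown-minus-control contrast (positive = stabilization), and
#' stabilized transcripts are split into tertile groups on `|S|` when at
#' least three of them exist.
#'
#' @param tab Normalized abundance table that has passed
#'   [filter_nondecaying()].
#' @param criterion `"standard"` (8, 12 h) or `"strict"` (4, 8, 12 h).
#' @param alpha Significance level applied to the corrected p-values.
#' @return A data frame with one row per transcript: `label`, per-time
#'   contrast statistics (`delta_t`, `se_t`, `p_stab_t`, `q_stab_t`,
#'   `p_dest_t`, `q_dest_t` for t = 4, 8, 12), stability change `s` and
#'   `stability_group` (`small`/`moderate`/`large` for stabilized
#'   transcripts, `not_applicable` otherwise).
#' @export
classify_transcripts <- function(tab, criterion = c("standard", "strict"),
                                 alpha = 0.05) {
  criterion <- match.arg(criterion)
  arr <- abundance_array(tab)
  inc <- apply(is.na(arr), 1L, any)
  if (any(inc)) {
    warning(sum(inc), " transcript(s) with missing cells excluded")
    arr <- arr[!inc, , , , drop = FALSE]
  }
  ids <- rownames(arr)
  n <- length(ids)
  times <- c("4", "8", "12")
  eval_times <- if (criterion == "standard") c("8", "12") else times

  delta <- se <- p_stab <- q_stab <- p_dest <- q_dest <-
    matrix(NA_real_, n, length(times), dimnames = list(ids, times))
  sep_stab <- sep_dest <- matrix(NA, n, length(times),
                                 dimnames = list(ids, times))
  for (t in times) {
    c1 <- arr[, "control", "1", t]; c2 <- arr[, "control", "2", t]
    k1 <- arr[, "knockdown", "1", t]; k2 <- arr[, "knockdown", "2", t]
    cs <- contrast_stat(c1, c2, k1, k2)
    delta[, t] <- cs$d
    se[, t] <- cs$dd
    p_stab[, t] <- pnorm(cs$z)     # knockdown above control -> z < 0
    p_dest[, t] <- pnorm(-cs$z)
    q_stab[, t] <- p.adjust(p_stab[, t], method = "BH")
    q_dest[, t] <- p.adjust(p_dest[, t], method = "BH")
    sep_stab[, t] <- pmin(k1, k2) > pmax(c1, c2)
    sep_dest[, t] <- pmin(c1, c2) > pmax(k1, k2)
  }

  all_t <- function(m) rowSums(m[, eval_times, drop = FALSE]) ==
    length(eval_times)
  is_stab <- all_t(q_stab <= alpha & sep_stab)
  is_dest <- all_t(q_dest <= alpha & sep_dest)
  is_unaf <- all_t(q_stab > alpha & q_dest > alpha)
  label <- ifelse(is_stab, "stabilized",
                  ifelse(is_dest, "destabilized",
                         ifelse(is_unaf, "unaffected", "unclassified")))

  s <- apply(-delta, 1L, median)   # knockdown minus control
  group <- rep("not_applicable", n)
  stab_idx <- which(label == "stabilized")
  if (length(stab_idx) >= 3L)
    group[stab_idx] <- stability_groups(s[stab_idx])

  out <- data.frame(transcript_id = ids, label = label,
                    stringsAsFactors = FALSE)
  for (t in times) {
    out[[paste0("delta_", t)]] <- delta[, t]
    out[[paste0("se_", t)]] <- se[, t]
    out[[paste0("p_stab_", t)]] <- p_stab[, t]
    out[[paste0("q_stab_", t)]] <- q_stab[, t]
    out[[paste0("p_dest_", t)]] <- p_dest[, t]
    out[[paste0("q_dest_", t)]] <- q_dest[, t]
  }
  out$s <- s
  out$stability_group <- group
  rownames(out) <- NULL
  out
}

#' Stability change of each transcript
#'
#' The median, over t = 4, 8 and 12 h, of the knockdown-minus-control
#' replicate-mean contrast.  Positive values mean the transcript decays
#' more slowly after knockdown (stabilization).
#'
#' @param tab Normalized abundance table.
#' @return Data frame `transcript_id`, `s`.
#' @export
stability_change <- function(tab) {
  arr <- abundance_array(tab)
  s <- vapply(rownames(arr), function(id) {
    st <- vapply(c("4", "8", "12"), function(t) {
      0.5 * ((arr[id, "knockdown", "1", t] + arr[id, "knockdown", "2", t]) -
             (arr[id, "control", "1", t] + arr[id, "control", "2", t]))
    }, numeric(1))
    median(st)
  }, numeric(1))
  data.frame(transcript_id = rownames(arr), s = unname(s),
             stringsAsFactors = FALSE)
}

#' Tertile groups of stability change magnitude
#'
#' Splits values into `small` (|S| at or below the 33rd percentile),
#' `large` (|S| at or above the 66th percentile) and `moderate`
#' (in between), with linear-interpolation percentiles.  Both boundary
#' rules are inclusive; when they overlap (heavy ties) the `small` rule
#' takes precedence.
#'
#' @param s Stability-change values of the stabilized transcripts
#'   (magnitudes are taken internally); at least 3 values required.
#' @return Character vector of group labels, same length as `s`.
#' @export
stability_groups <- function(s) {
  if (length(s) < 3L)
    stop("need at least 3 stability-change values to form tertiles")
  a <- abs(s)
  lo <- quantile(a, 0.33, names = FALSE, type = 7)
  hi <- quantile(a, 0.66, names = FALSE, type = 7)
  ifelse(a <= lo, "small", ifelse(a >= hi, "large", "moderate"))
}

#' Full decay-classification stage
#'
#' Convenience wrapper chaining [normalize_to_reference()],
#' [filter_nondecaying()] and [classify_transcripts()].
#'
#' @inheritParams classify_transcripts
#' @param tab Raw abundance table including the reference transcript.
#' @param ref_id Stable reference transcript id.
#' @return A list of class `decay_classification` with `results` (the
#'   [classify_transcripts()] frame, plus rows labelled
#'   `removed_nondecaying` for transcripts dropped by the filter),
#'   `removed` (the filter's reason table), `criterion` and `alpha`.
#' @export
classify_decay <- function(tab, ref_id = REF_STABLE,
                           criterion = c("standard", "strict"),
                           alpha = 0.05) {
  criterion <- match.arg(criterion)
  norm <- normalize_to_reference(tab, ref_id)
  flt <- filter_nondecaying(norm, alpha)
  res <- classify_transcripts(flt$retained, criterion, alpha)
  dropped <- setdiff(unique(flt$removed$transcript_id[
    flt$removed$reason != "incomplete"]), res$transcript_id)
  if (length(dropped)) {
    pad <- res[rep(NA_integer_, length(dropped)), ]
    pad$transcript_id <- dropped
    pad$label <- "removed_nondecaying"
    pad$stability_group <- "not_applicable"
    res <- rbind(res, pad)
    rownames(res) <- NULL
  }
  structure(list(results = res, removed = flt$removed,
                 criterion = criterion, alpha = alpha),
            class = "decay_classification")
}

#' @export
print.decay_classification <- function(x, ...) {
  cat("decay classification (criterion:", x$criterion,
      ", alpha:", x$alpha, ")\n")
  print(table(x$results$label))
  invisible(x)
}
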