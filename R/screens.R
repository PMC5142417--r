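#' Non-parametric common-language effect size
#'
#' The probability that a random value from the first group exceeds a
#' random value from the second, ties counted half:
#' `A = (n_greater + n_equal / 2) / (n1 * n2)` over all cross-group
#' pairs.  Computed via midranks, which reproduces the pairwise
#' enumeration exactly.
#'
#' @param x,y Numeric vectors (non-empty after `NA` removal).
#' @return `A` in \[0, 1\]; `A = 0.5` means no tendency either way, and
#'   `A(x, y) + A(y, x) = 1`.
#' @examples
#' effect_size(c(1, 2, 3), 2)  # (1 + 0.5) / 3
#' @export
effect_size <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

mw_pvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  # exact enumeration for small tie-free samples; otherwise the normal
  # approximation with tie and continuity correction
  use_exact <- !ties && max(n1, n2) <= 20L
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)$p.value)
}

#' Screen non-binary features between two transcript groups
#'
#' For every feature column: two-sided Mann-Whitney test between the two
#' groups, Benjamini-Hochberg correction across the screened features,
#' the common-language effect size `A` of group A over group B, and a
#' discrimination flag requiring both corrected significance
#' (`q < alpha`) and a material effect (`|A - 0.5| >= min_effect`).
#' Undefined cells are dropped per feature (pairwise deletion).
#'
#' @param x Data frame or matrix of numeric feature columns.
#' @param labels Group label per row of `x` (named vectors are matched by
#'   rowname).
#' @param group_a,group_b Labels of the two groups; `A > 0.5` means
#'   higher values in `group_a`.
#' @param alpha FDR level of the flag.
#' @param min_effect Minimum `|A - 0.5|` of the flag.
#' @return Data frame of class `screen_result`: `feature`, `a`, `effect`
#'   (= `|A - 0.5|`), `p`, `q`, `flag`.
#' @export
screen_nonbinary <- function(x, labels, group_a = "stabilized",
                             group_b = "unaffected", alpha = 0.05,
                             min_effect = 0.1) {
  x <- as.data.frame(x)
  if (!is.null(names(labels)) && !is.null(rownames(x)))
    labels <- labels[rownames(x)]
  if (length(labels) != nrow(x)) stop("`labels` must cover every row")
  ia <- which(labels == group_a); ib <- which(labels == group_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("both groups must be represented")

  res <- lapply(names(x), function(f) {
    xa <- x[ia, f]; xb <- x[ib, f]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L)
      return(data.frame(feature = f, a = NA_real_, p = NA_real_))
    data.frame(feature = f, a = effect_size(xa, xb), p = mw_pvalue(xa, xb))
  })
  res <- do.call(rbind, res)
  res$effect <- abs(res$a - 0.5)
  res$q <- p.adjust(res$p, method = "BH")
  res$flag <- !is.na(res$q) & res$q < alpha & res$effect >= min_effect
  res <- res[, c("feature", "a", "effect", "p", "q", "flag")]
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Screen binary features between two transcript groups
#'
#' For every 0/1 feature column: two-sided Fisher exact test of the
#' feature-by-group 2x2 table, Benjamini-Hochberg correction across the
#' screened binaries, and the effect size `A` of the 0/1 values.  The
#' flag requires corrected significance only (the `|A - 0.5|` threshold
#' applies to the non-binary screen).
#'
#' @inheritParams screen_nonbinary
#' @param x Data frame or matrix of 0/1 columns.
#' @return Data frame of class `screen_result` (same columns as
#'   [screen_nonbinary()]).
#' @export
screen_binary <- function(x, labels, group_a = "stabilized",
                          group_b = "unaffected", alpha = 0.05) {
  x <- as.data.frame(x)
  if (!is.null(names(labels)) && !is.null(rownames(x)))
    labels <- labels[rownames(x)]
  if (length(labels) != nrow(x)) stop("`labels` must cover every row")
  ia <- which(labels == group_a); ib <- which(labels == group_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("both groups must be non-empty (empty contingency margin)")

  res <- lapply(names(x), function(f) {
    xa <- x[ia, f]; xb <- x[ib, f]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) == 0L || length(xb) == 0L)
      stop("feature '", f, "': empty contingency margin")
    if (!all(c(xa, xb) %in% c(0, 1)))
      stop("feature '", f, "' is not binary")
    tab <- matrix(c(sum(xa == 1), sum(xa == 0),
                    sum(xb == 1), sum(xb == 0)), nrow = 2,
                  dimnames = list(c("present", "absent"), c("A", "B")))
    data.frame(feature = f, a = effect_size(xa, xb),
               p = fisher.test(tab)$p.value)
  })
  res <- do.call(rbind, res)
  res$effect <- abs(res$a - 0.5)
  res$q <- p.adjust(res$p, method = "BH")
  res$flag <- !is.na(res$q) & res$q < alpha
  res <- res[, c("feature", "a", "effect", "p", "q", "flag")]
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Screen a feature matrix between two transcript classes
#'
#' Applies [screen_nonbinary()] to the non-binary columns and
#' [screen_binary()] to the binary columns of a `feature_matrix`
#' (optionally restricted to a retained subset from
#' [prune_redundant()]), with separate FDR families for the two kinds.
#'
#' @inheritParams screen_nonbinary
#' @param fm A `feature_matrix`.
#' @param features Optional character vector restricting the screen.
#' @return List with elements `nonbinary` and `binary` (both
#'   `screen_result` frames; an element is `NULL` when no such features
#'   are in scope).
#' @export
screen_features <- function(fm, labels, group_a = "stabilized",
                            group_b = "unaffected", features = NULL,
                            alpha = 0.05, min_effect = 0.1) {
  meta <- attr(fm, "meta")
  if (is.null(meta)) stop("`fm` must be a feature_matrix")
  if (is.null(features)) features <- meta$feature
  unknown <- setdiff(features, meta$feature)
  if (length(unknown)) stop("unknown features: ",
                            paste(unknown, collapse = ", "))
  nb <- intersect(features, meta$feature[!meta$binary])
  bb <- intersect(features, meta$feature[meta$binary])
  list(
    nonbinary = if (length(nb))
      screen_nonbinary(fm[, nb, drop = FALSE], labels, group_a, group_b,
                       alpha, min_effect),
    binary = if (length(bb))
      screen_binary(fm[, bb, drop = FALSE], labels, group_a, group_b,
                    alpha))
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Rank-based comparison of a numeric variable across k groups:
#' tie-corrected Kruskal-Wallis H, then Dunn's pairwise Q statistics on
#' the mean ranks, each compared against a single critical value from
#' the standard-normal quantile at the chosen family correction
#' (two-sided Sidak by default, which gives 2.39 for three groups at
#' alpha = 0.05).  The pairwise common-language effect size magnitude
#' `|A - 0.5|` is attached to every comparison.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @param alpha Family significance level.
#' @param correction `"sidak"`, `"bonferroni"` or `"none"`.
#' @return List of class `three_group_result`: `H`, `p`, `critical_q`,
#'   and `pairs` (data frame `group1`, `group2`, `q`, `critical_q`,
#'   `reject`, `a`, `effect`).
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05,
                         correction = c("sidak", "bonferroni", "none")) {
  correction <- match.arg(correction)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least two non-empty groups")
  if (any(table(groups) == 0L)) stop("every group must be non-empty")

  kw <- kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tabulate(groups)
  tie_tab <- table(values)
  sigma2 <- N * (N + 1) / 12 - sum(tie_tab^3 - tie_tab) / (12 * (N - 1))

  cmb <- combn(levels(groups), 2)
  k <- ncol(cmb)
  critical_q <- switch(correction,
    sidak = qnorm(1 - (1 - (1 - alpha)^(1 / k)) / 2),
    bonferroni = qnorm(1 - alpha / (2 * k)),
    none = qnorm(1 - alpha / 2))

  pairs <- do.call(rbind, lapply(seq_len(k), function(j) {
    g1 <- cmb[1, j]; g2 <- cmb[2, j]
    q_stat <- (mean_rank[[g1]] - mean_rank[[g2]]) /
      sqrt(sigma2 * (1 / n_g[match(g1, levels(groups))] +
                     1 / n_g[match(g2, levels(groups))]))
    a <- effect_size(values[groups == g1], values[groups == g2])
    data.frame(group1 = g1, group2 = g2, q = q_stat,
               critical_q = critical_q, reject = abs(q_stat) > critical_q,
               a = a, effect = abs(a - 0.5), stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  structure(list(H = unname(kw$statistic), p = kw$p.value,
                 critical_q = critical_q, correction = correction,
                 pairs = pairs),
            class = "three_group_result")
}

#' @export
print.three_group_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, p = %.3g (critical Q = %.2f, %s)\n",
              x$H, x$p, x$critical_q, x$correction))
  print(x$pairs, digits = 3)
  invisible(x)
}

#' Compare two externally supplied feature cohorts
#'
#' Runs the binary and non-binary screens between a target cohort and a
#' background cohort supplied as two feature matrices with identical
#' columns (e.g. an independent validation set of decay targets against
#' insensitive transcripts).  No cohort construction logic is applied;
#' the matrices are taken as given.
#'
#' @param fm_target,fm_background Two `feature_matrix` objects with
#'   identical feature columns.
#' @inheritParams screen_nonbinary
#' @return As [screen_features()]; `A > 0.5` means higher values in the
#'   target cohort.
#' @export
validation_compare <- function(fm_target, fm_background, alpha = 0.05,
                               min_effect = 0.1) {
  meta_t <- attr(fm_target, "meta"); meta_b <- attr(fm_background, "meta")
  if (is.null(meta_t) || is.null(meta_b))
    stop("inputs must be feature_matrix objects")
  if (!identical(names(fm_target), names(fm_background)))
    stop("feature columns of the two cohorts do not match")
  combined <- rbind(as.data.frame(fm_target), as.data.frame(fm_background))
  rownames(combined) <- NULL
  attr(combined, "meta") <- meta_t
  class(combined) <- c("feature_matrix", "data.frame")
  labels <- c(rep("target", nrow(fm_target)),
              rep("background", nrow(fm_background)))
  screen_features(combined, labels, group_a = "target",
                  group_b = "background", alpha = alpha,
                  min_effect = min_effect)
}
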