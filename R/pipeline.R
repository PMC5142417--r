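#' Configuration of the end-to-end synthetic analysis
#'
#' Collects every tunable choice of the workflow in one validated object:
#' the decay- and sequence-simulation settings, the classification
#' criterion and level, the screening thresholds, the fold engine and
#' upstream window, and the Dunn family correction.  All stage outputs
#' are pure functions of this configuration (a single seed governs every
#' random draw), so a pipeline run is reproducible bit for bit.
#'
#' `g_enrichment_by_class` ties the sequence simulator to the planted
#' decay classes: transcripts of each class receive the given additive G
#' boost in the last 20 CDS bases and along the 3'UTR.  The default
#' plants a strong boost in the stabilized class and a weak one in the
#' destabilized class, emulating the compositional gradient the screens
#' are designed to detect.
#'
#' @param seed Integer seed for the whole run.
#' @param n_transcripts,class_proportions,base_decay_rate,effect_ratio,noise_cv,initial_abundance
#'   Decay-simulation settings, see [sim_decay_params()].
#' @param utr5_len,cds_len,utr3_len,base_composition,p_tuorf,p_tovorf,p_sejc,p_alu
#'   Sequence-simulation settings, see [sim_transcript_params()].
#' @param g_enrichment_by_class Named additive G boosts per planted class.
#' @param criterion,alpha Classification settings, see
#'   [classify_transcripts()].
#' @param min_effect Effect-size threshold of the screens.
#' @param upstream_window,engine MFE settings, see [tc_region_mfe()].
#' @param dunn_correction Family correction of [kruskal_dunn()].
#' @param out_dir Optional directory; when set, [run_pipeline()] writes
#'   every intermediate table there as TSV.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_transcripts = 600,
                            class_proportions = c(stabilized = 0.10,
                                                  destabilized = 0.10,
                                                  unaffected = 0.80),
                            base_decay_rate = 0.15,
                            effect_ratio = c(stabilized = 0.3,
                                             destabilized = 3.0),
                            noise_cv = 0.05,
                            initial_abundance = 100,
                            utr5_len = 200, cds_len = 900, utr3_len = 300,
                            base_composition = c(A = 0.27, C = 0.24,
                                                 G = 0.18, T = 0.31),
                            g_enrichment_by_class = c(stabilized = 0.10,
                                                      destabilized = 0.03,
                                                      unaffected = 0),
                            p_tuorf = 0.10, p_tovorf = 0.05,
                            p_sejc = 0.05, p_alu = 0.15,
                            criterion = "standard", alpha = 0.05,
                            min_effect = 0.1,
                            upstream_window = 60L, engine = "fallback",
                            dunn_correction = "sidak",
                            out_dir = NULL) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer")
  cls <- c("stabilized", "destabilized", "unaffected")
  if (is.null(names(g_enrichment_by_class)) ||
      !setequal(names(g_enrichment_by_class), cls))
    stop("`g_enrichment_by_class` must be named over ",
         paste(cls, collapse = "/"))
  # delegate detailed validation to the parameter constructors
  decay <- sim_decay_params(n_transcripts = n_transcripts,
                            class_proportions = class_proportions,
                            base_decay_rate = base_decay_rate,
                            effect_ratio = effect_ratio,
                            noise_cv = noise_cv,
                            initial_abundance = initial_abundance,
                            seed = seed)
  for (g in g_enrichment_by_class)
    sim_transcript_params(n_transcripts = 1, utr5_len = utr5_len,
                          cds_len = cds_len, utr3_len = utr3_len,
                          base_composition = base_composition,
                          g_enrichment = g, p_tuorf = p_tuorf,
                          p_tovorf = p_tovorf, p_sejc = p_sejc,
                          p_alu = p_alu, seed = seed)
  criterion <- match.arg(criterion, c("standard", "strict"))
  engine <- match.arg(engine, c("fallback", "rnafold"))
  dunn_correction <- match.arg(dunn_correction,
                               c("sidak", "bonferroni", "none"))
  if (upstream_window < 1 || upstream_window > cds_len)
    stop("`upstream_window` must lie in [1, cds_len]")
  structure(list(seed = seed, decay = decay,
                 utr5_len = utr5_len, cds_len = cds_len,
                 utr3_len = utr3_len, base_composition = base_composition,
                 g_enrichment_by_class = g_enrichment_by_class[cls],
                 p_tuorf = p_tuorf, p_tovorf = p_tovorf, p_sejc = p_sejc,
                 p_alu = p_alu,
                 criterion = criterion, alpha = alpha,
                 min_effect = min_effect,
                 upstream_window = as.integer(upstream_window),
                 engine = engine, dunn_correction = dunn_correction,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Simulate the full synthetic cohort of a pipeline configuration
#'
#' Stage one of [run_pipeline()]: draws the decay time courses with
#' planted classes, then simulates one sequence cohort per planted class
#' with the class-specific G enrichment of
#' `config$g_enrichment_by_class`, merged back into a single
#' `transcript_set` in truth order.
#'
#' @param config A [pipeline_config()].
#' @return List with `abundance`, `truth` (planted decay classes),
#'   `ts` (the merged `transcript_set`) and `ref_id`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must come from pipeline_config()")
  sim <- simulate_decay_dataset(config$decay)
  truth <- sim$truth
  cls <- c("stabilized", "destabilized", "unaffected")
  ts_parts <- lapply(seq_along(cls), function(i) {
    ids <- truth$transcript_id[truth$class == cls[i]]
    if (length(ids) == 0L) return(NULL)
    simulate_transcripts(
      sim_transcript_params(n_transcripts = length(ids),
                            utr5_len = config$utr5_len,
                            cds_len = config$cds_len,
                            utr3_len = config$utr3_len,
                            base_composition = config$base_composition,
                            g_enrichment = config$g_enrichment_by_class[[cls[i]]],
                            p_tuorf = config$p_tuorf,
                            p_tovorf = config$p_tovorf,
                            p_sejc = config$p_sejc, p_alu = config$p_alu,
                            seed = config$seed + i),
      ids = ids)
  })
  ts <- merge_transcript_sets(ts_parts[!vapply(ts_parts, is.null,
                                               logical(1))],
                              order_ids = truth$transcript_id)
  list(abundance = sim$abundance, truth = truth, ts = ts,
       ref_id = sim$ref_id)
}

#' Run the end-to-end synthetic analysis
#'
#' Executes every stage in order: simulate decay courses with planted
#' classes; simulate class-linked transcript sequences; normalize to the
#' stable reference, filter non-decaying transcripts and classify;
#' build the 63-feature catalog and prune it to a non-redundant set;
#' screen the retained features between all three class pairs; fold the
#' stop-codon-proximal regions and compare absolute MFE across the three
#' classes and across the stability tertiles of the stabilized class.
#' All intermediate tables are written to `config$out_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `analysis_report`: `config`, `truth`,
#'   `classification` (a `decay_classification`), `label_counts`,
#'   `feature_matrix`, `nonredundant` (retained feature names),
#'   `screens` (one [screen_features()] result per class pair),
#'   `mfe` (the [tc_region_mfe()] table), `mfe_three_group` and
#'   `mfe_tertiles` (per-region [kruskal_dunn()] results).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must come from pipeline_config()")

  sim <- simulate_cohort(config)
  truth <- sim$truth
  ts <- sim$ts

  classification <- classify_decay(sim$abundance, ref_id = sim$ref_id,
                                   criterion = config$criterion,
                                   alpha = config$alpha)
  res <- classification$results
  labels <- stats::setNames(res$label, res$transcript_id)
  label_counts <- table(factor(res$label,
                               levels = c("stabilized", "destabilized",
                                          "unaffected", "unclassified",
                                          "removed_nondecaying")))

  fm <- build_feature_matrix(ts)
  nonredundant <- prune_redundant(fm, labels)

  pairs <- list(stabilized_vs_unaffected = c("stabilized", "unaffected"),
                destabilized_vs_unaffected = c("destabilized", "unaffected"),
                stabilized_vs_destabilized = c("stabilized", "destabilized"))
  screens <- lapply(pairs, function(p)
    screen_features(fm, labels, group_a = p[1], group_b = p[2],
                    features = nonredundant, alpha = config$alpha,
                    min_effect = config$min_effect))

  mfe <- tc_region_mfe(ts, upstream_window = config$upstream_window,
                       engine = fold_engine(config$engine))
  mfe_by_region <- split(mfe, mfe$region)
  three_group <- lapply(mfe_by_region, function(d) {
    lab <- labels[d$transcript_id]
    keep <- lab %in% c("stabilized", "destabilized", "unaffected")
    kruskal_dunn(d$abs_mfe[keep], lab[keep], alpha = config$alpha,
                 correction = config$dunn_correction)
  })
  stab <- res[res$label == "stabilized", ]
  tertiles <- NULL
  if (nrow(stab) >= 3L &&
      length(unique(stab$stability_group)) >= 2L) {
    tert_groups <- stats::setNames(stab$stability_group, stab$transcript_id)
    tertiles <- lapply(mfe_by_region, function(d) {
      g <- tert_groups[d$transcript_id]
      keep <- !is.na(g)
      kruskal_dunn(d$abs_mfe[keep], g[keep], alpha = config$alpha,
                   correction = config$dunn_correction)
    })
  }

  report <- structure(list(config = config, truth = truth,
                           classification = classification,
                           label_counts = label_counts,
                           feature_matrix = fm,
                           nonredundant = nonredundant,
                           screens = screens, mfe = mfe,
                           mfe_three_group = three_group,
                           mfe_tertiles = tertiles),
                      class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

merge_transcript_sets <- function(parts, order_ids) {
  stopifnot(length(parts) >= 1L)
  seqs <- do.call(c, lapply(parts, `[[`, "sequences"))
  cat_df <- function(field) {
    do.call(rbind, c(lapply(parts, `[[`, field),
                     list(make.row.names = FALSE)))
  }
  out <- structure(list(sequences = seqs[order_ids],
                        regions = cat_df("regions"),
                        uorfs = cat_df("uorfs"),
                        introns = cat_df("introns"),
                        alus = cat_df("alus"),
                        truth = cat_df("truth"),
                        params = parts[[1]]$params),
                   class = "transcript_set")
  out
}

write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(report$truth, file.path(dir, "truth.tsv"))
  write_tsv(report$classification$results, file.path(dir,
                                                     "classification.tsv"))
  write_tsv(report$classification$removed, file.path(dir, "removed.tsv"))
  write_feature_matrix(report$feature_matrix,
                       file.path(dir, "features.tsv"),
                       file.path(dir, "features_meta.tsv"))
  writeLines(report$nonredundant, file.path(dir, "nonredundant.txt"))
  for (nm in names(report$screens)) {
    s <- report$screens[[nm]]
    write_tsv(rbind(s$nonbinary, s$binary),
              file.path(dir, paste0("screen_", nm, ".tsv")))
  }
  write_tsv(report$mfe, file.path(dir, "mfe.tsv"))
  tg <- do.call(rbind, lapply(names(report$mfe_three_group), function(rg) {
    cbind(region = rg, report$mfe_three_group[[rg]]$pairs)
  }))
  write_tsv(tg, file.path(dir, "mfe_three_group.tsv"))
  if (!is.null(report$mfe_tertiles)) {
    tt <- do.call(rbind, lapply(names(report$mfe_tertiles), function(rg) {
      cbind(region = rg, report$mfe_tertiles[[rg]]$pairs)
    }))
    write_tsv(tt, file.path(dir, "mfe_tertiles.tsv"))
  }
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report (seed", x$config$seed, ")\n")
  cat("label counts:\n")
  print(x$label_counts)
  cat("non-redundant features:", length(x$nonredundant), "\n")
  flagged <- x$screens$stabilized_vs_unaffected$nonbinary
  if (!is.null(flagged))
    cat("flagged (stabilized vs unaffected):",
        paste(flagged$feature[flagged$flag], collapse = ", "), "\n")
  invisible(x)
}
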