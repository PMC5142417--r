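test_that("decay parameters are validated", {
  expect_error(sim_decay_params(class_proportions =
    c(stabilized = 0.5, destabilized = 0.6, unaffected = -0.1)),
    "sum to 1")
  expect_error(sim_decay_params(class_proportions =
    c(stabilized = 0.2, destabilized = 0.2, unaffected = 0.2)), "sum to 1")
  expect_error(sim_decay_params(base_decay_rate = 0), "base_decay_rate")
  expect_error(sim_decay_params(effect_ratio =
    c(stabilized = -1, destabilized = 3)), "effect_ratio")
  expect_error(sim_decay_params(noise_cv = -0.1), "noise_cv")
})

test_that("noise-free decay follows the exponential model exactly", {
  p <- sim_decay_params(n_transcripts = 6,
    class_proportions = c(stabilized = 0, destabilized = 0, unaffected = 1),
    base_decay_rate = 0.2, noise_cv = 0, initial_abundance = 10, seed = 2)
  sim <- simulate_decay_dataset(p)
  tab <- sim$abundance
  ctrl4 <- tab$abundance[tab$transcript_id == "TX00001" &
                         tab$condition == "control" & tab$time_h == 4]
  expect_equal(ctrl4, rep(10 * exp(-0.8), 2))
  # unaffected transcripts: control and knockdown curves coincide
  ctl <- tab[tab$condition == "control", ]
  kd <- tab[tab$condition == "knockdown", ]
  expect_equal(ctl$abundance, kd$abundance)
  # positivity and monotone decay without noise
  expect_true(all(tab$abundance > 0))
  one <- tab[tab$transcript_id == "TX00002" & tab$condition == "control" &
             tab$replicate == 1, ]
  expect_true(all(diff(one$abundance[order(one$time_h)]) <= 0))
  # stable reference present, decay rate zero
  ref <- tab[tab$transcript_id == REF_STABLE, ]
  expect_equal(nrow(ref), 16L)
  expect_equal(ref$abundance, rep(10, 16))
})

test_that("effect ratios rescale the knockdown decay rate per planted class", {
  p <- sim_decay_params(n_transcripts = 9,
    class_proportions = c(stabilized = 1/3, destabilized = 1/3,
                          unaffected = 1/3),
    base_decay_rate = 0.1, effect_ratio = c(stabilized = 0.5,
                                            destabilized = 2),
    noise_cv = 0, initial_abundance = 1, seed = 4)
  sim <- simulate_decay_dataset(p)
  kd12 <- function(id) sim$abundance$abundance[
    sim$abundance$transcript_id == id &
    sim$abundance$condition == "knockdown" &
    sim$abundance$time_h == 12 & sim$abundance$replicate == 1]
  by_class <- split(sim$truth$transcript_id, sim$truth$class)
  expect_equal(kd12(by_class$stabilized[1]), exp(-0.05 * 12))
  expect_equal(kd12(by_class$destabilized[1]), exp(-0.2 * 12))
  expect_equal(kd12(by_class$unaffected[1]), exp(-0.1 * 12))
})

test_that("the same seed reproduces the decay table exactly", {
  p <- sim_decay_params(n_transcripts = 25, noise_cv = 0.2, seed = 11)
  expect_identical(simulate_decay_dataset(p), simulate_decay_dataset(p))
  p2 <- sim_decay_params(n_transcripts = 25, noise_cv = 0.2, seed = 12)
  expect_false(identical(simulate_decay_dataset(p)$abundance,
                         simulate_decay_dataset(p2)$abundance))
})

test_that("transcript parameters are validated", {
  expect_error(sim_transcript_params(cds_len = 100), "multiple of 3")
  expect_error(sim_transcript_params(utr3_len = 0), "3'UTR")
  expect_error(sim_transcript_params(base_composition =
    c(A = 0.5, C = 0.5, G = 0.2, T = -0.2)), "sum to 1")
  expect_error(sim_transcript_params(g_enrichment = 0.9,
    base_composition = c(A = 0.2, C = 0.2, G = 0.3, T = 0.3)),
    "g_enrichment")
  expect_error(sim_transcript_params(p_tuorf = 1.3), "probabilities")
})

test_that("simulated transcripts have the requested structure", {
  p <- sim_transcript_params(n_transcripts = 30, utr5_len = 50,
                             cds_len = 120, utr3_len = 80, seed = 5)
  ts <- simulate_transcripts(p)
  expect_length(ts$sequences, 30)
  expect_true(all(nchar(ts$sequences) == 250))
  expect_false(any(grepl("[^ACGT]", ts$sequences)))
  cds <- region_seqs(ts, "cds")
  expect_true(all(substr(cds, 118, 120) %in% c("TAA", "TAG", "TGA")))
  b <- ts$regions
  expect_true(all(b$end[b$region == "utr5"] == 50))
  expect_true(all(b$start[b$region == "utr3"] == 170))
})

test_that("without enrichment the realized 3'UTR G density matches the base rate", {
  p <- sim_transcript_params(n_transcripts = 40, utr3_len = 300,
                             g_enrichment = 0, seed = 6)
  ts <- simulate_transcripts(p)
  g <- mean(vapply(region_seqs(ts, "utr3"), mono_density,
                   numeric(1), nt = "G"))
  p_g <- 0.18
  sigma <- sqrt(p_g * (1 - p_g) / (40 * 300))
  expect_lt(abs(g - p_g), 3 * sigma)
})

test_that("G enrichment boosts the realized 3'UTR G density additively", {
  p <- sim_transcript_params(n_transcripts = 40, utr3_len = 300,
                             g_enrichment = 0.10, seed = 6)
  ts <- simulate_transcripts(p)
  g <- mean(vapply(region_seqs(ts, "utr3"), mono_density,
                   numeric(1), nt = "G"))
  sigma <- sqrt(0.28 * 0.72 / (40 * 300))
  expect_lt(abs(g - 0.28), 3 * sigma)
})

test_that("planting probabilities are honoured at their extremes", {
  p <- sim_transcript_params(n_transcripts = 20, p_tuorf = 1, p_tovorf = 1,
                             p_sejc = 1, p_alu = 1, seed = 7)
  ts <- simulate_transcripts(p)
  expect_true(all(ts$truth$tuorf & ts$truth$tovorf & ts$truth$sejc &
                  ts$truth$alu))
  # every transcript has a 3'UTR intron closer than 55 bases to the stop
  shallow <- ts$introns$transcript_id[ts$introns$pos < 55]
  expect_setequal(unique(shallow), names(ts$sequences))
  # planted flags agree with the interval-derived binary features
  bf <- binary_features(ts)
  expect_true(all(bf$tuorf == 1 & bf$tovorf == 1 & bf$sejc == 1 &
                  bf$alu == 1))
  p0 <- sim_transcript_params(n_transcripts = 20, p_tuorf = 0, p_tovorf = 0,
                              p_sejc = 0, p_alu = 0, seed = 7)
  bf0 <- binary_features(simulate_transcripts(p0))
  expect_true(all(bf0[, c("tuorf", "tovorf", "sejc", "alu")] == 0))
})

test_that("transcript simulation is reproducible and id-overridable", {
  p <- sim_transcript_params(n_transcripts = 8, seed = 9)
  expect_identical(simulate_transcripts(p), simulate_transcripts(p))
  ts <- simulate_transcripts(p, ids = paste0("G", 1:5))
  expect_identical(names(ts$sequences), paste0("G", 1:5))
})

test_that("transcript sets round-trip through FASTA and interval tables", {
  dir <- withr::local_tempdir()
  ts <- simulate_transcripts(sim_transcript_params(n_transcripts = 6,
    p_tuorf = 0.5, p_sejc = 0.5, p_alu = 0.5, seed = 10))
  write_transcript_set(ts, dir)
  back <- read_transcript_set(
    file.path(dir, "transcripts.fasta"), file.path(dir, "regions.tsv"),
    uorfs = file.path(dir, "uorfs.tsv"),
    introns = file.path(dir, "introns.tsv"),
    alus = file.path(dir, "alus.tsv"))
  expect_identical(back$sequences, ts$sequences)
  expect_equal(build_feature_matrix(back), build_feature_matrix(ts),
               ignore_attr = TRUE)
})

test_that("abundance tables round-trip through TSV", {
  dir <- withr::local_tempdir()
  sim <- simulate_decay_dataset(sim_decay_params(n_transcripts = 5, seed = 3))
  path <- file.path(dir, "abundance.tsv")
  write_abundance(sim$abundance, path)
  back <- read_abundance(path)
  expect_equal(back$abundance, sim$abundance$abundance)
  expect_identical(back$transcript_id, sim$abundance$transcript_id)
})
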