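test_that("replicate contrasts follow the error-propagation formulas", {
  cs <- contrast_stat(8, 12, 6, 6)
  expect_equal(cs$d, 4)
  expect_equal(cs$dd, 4 / sqrt(2))
  # symmetric inputs give a zero contrast with zero error
  expect_equal(contrast_stat(10, 10, 10, 10), data.frame(d = 0, dd = 0, z = 0))
  # swapping the pairs negates d and preserves dd
  a <- contrast_stat(3.2, 5.9, 1.1, 0.4)
  b <- contrast_stat(1.1, 0.4, 3.2, 5.9)
  expect_identical(b$d, -a$d)
  expect_identical(b$dd, a$dd)
  # degenerate-error conventions: z = +/-Inf when d != 0, 0 when d = 0
  expect_equal(contrast_stat(2, 2, 1, 1)$z, Inf)
  expect_equal(contrast_stat(1, 1, 2, 2)$z, -Inf)
  expect_error(contrast_stat(NA, 1, 1, 1), "finite")
})

test_that("normalization scales by the reference cell and drops the reference", {
  tab <- make_abundance(list(A = flat_curves(25), REF_STABLE = flat_curves(50)))
  out <- normalize_to_reference(tab)
  expect_false(REF_STABLE %in% out$transcript_id)
  expect_equal(out$abundance, rep(0.5, 16))
  # unit reference leaves the table unchanged
  tab1 <- make_abundance(list(A = flat_curves(3), REF_STABLE = flat_curves(1)))
  out1 <- normalize_to_reference(tab1)
  expect_equal(out1$abundance,
               tab1$abundance[tab1$transcript_id == "A"])
  # zero or missing reference cells are reported by name
  bad <- tab
  bad$abundance[bad$transcript_id == REF_STABLE][3] <- 0
  expect_error(normalize_to_reference(bad), "not positive in cell")
  expect_error(normalize_to_reference(tab, ref_id = "nope"), "not found")
  expect_error(
    normalize_to_reference(tab[-which(tab$transcript_id == REF_STABLE)[1], ]),
    "missing cell")
})

test_that("non-decaying transcripts are removed, flat and decaying ones kept", {
  decaying <- function(rate, eps = 0) {
    m <- rbind(exp(-rate * c(0, 4, 8, 12)),
               exp(-rate * c(0, 4, 8, 12)) + eps)
    list(control = m, knockdown = m)
  }
  rising <- list(control = rbind(c(1, 1, 10, 10), c(1, 1.01, 10.05, 10.02)),
                 knockdown = rbind(exp(-0.2 * c(0, 4, 8, 12)),
                                   exp(-0.2 * c(0, 4, 8, 12))))
  tab <- make_abundance(list(D1 = decaying(0.1, 0.01),
                             D2 = decaying(0.2, 0.02),
                             FLAT = flat_curves(1),
                             UP = rising))
  flt <- filter_nondecaying(tab)
  expect_setequal(unique(flt$retained$transcript_id), c("D1", "D2", "FLAT"))
  expect_true("UP" %in% flt$removed$transcript_id)
  expect_equal(flt$removed$reason[flt$removed$transcript_id == "UP"],
               "nondecaying_control")
  # flat curves with zero spread: tau = 0, p = 0.5
  fs <- flt$stats[flt$stats$transcript_id == "FLAT", ]
  expect_equal(fs$p, rep(0.5, 4))
  # zero-error rising curve: z = +Inf, p = 0, always removed
  tab2 <- make_abundance(list(
    Z = list(control = rbind(c(1, 1, 2, 0.5), c(1, 1, 2, 0.5)),
             knockdown = flat_curves(1)$knockdown)))
  flt2 <- filter_nondecaying(tab2)
  expect_true("Z" %in% flt2$removed$transcript_id)
  expect_equal(
    flt2$stats$z[flt2$stats$transcript_id == "Z" &
                 flt2$stats$condition == "control" & flt2$stats$time_h == 8],
    Inf)
})

test_that("incomplete transcripts are excluded with a reason", {
  tab <- make_abundance(list(A = flat_curves(1), B = flat_curves(2)))
  tab <- tab[!(tab$transcript_id == "B" & tab$time_h == 8 &
               tab$replicate == 2 & tab$condition == "control"), ]
  flt <- filter_nondecaying(tab)
  expect_equal(flt$removed,
               data.frame(transcript_id = "B", reason = "incomplete"))
  expect_setequal(unique(flt$retained$transcript_id), "A")
})

test_that("identical control and knockdown curves are unaffected", {
  tab <- make_abundance(list(A = flat_curves(2), B = flat_curves(0.7)))
  res <- classify_transcripts(tab)
  expect_equal(res$label, c("unaffected", "unaffected"))
  expect_equal(res$delta_8, c(0, 0))
  expect_equal(res$p_stab_8, c(0.5, 0.5))
  expect_equal(res$s, c(0, 0))
})

test_that("a noise-free planted effect is recovered under both criteria", {
  p <- sim_decay_params(n_transcripts = 10,
    class_proportions = c(stabilized = 0.5, destabilized = 0.3,
                          unaffected = 0.2),
    effect_ratio = c(stabilized = 0.3, destabilized = 3),
    noise_cv = 0, seed = 8)
  sim <- simulate_decay_dataset(p)
  for (crit in c("standard", "strict")) {
    cl <- classify_decay(sim$abundance, criterion = crit)
    m <- merge(cl$results[c("transcript_id", "label")], sim$truth,
               by = "transcript_id")
    expect_identical(m$label, m$class)
  }
})

test_that("significance without replicate separation leaves a transcript unclassified", {
  # knockdown clearly above control at 8 h, but replicate ranges overlap
  # at 12 h: the min/max clause fails there, and the 8 h significance
  # forbids the unaffected label
  tr <- list(control = rbind(c(5, 4, 1.00, 1.00), c(5, 4, 1.01, 1.50)),
             knockdown = rbind(c(5, 4.5, 2.00, 1.20), c(5, 4.5, 2.01, 1.40)))
  tab <- make_abundance(list(X = tr))
  res <- classify_transcripts(tab)
  expect_equal(res$label, "unclassified")
  expect_lte(res$q_stab_8, 0.05)
  expect_gt(res$q_stab_12, 0.05)
})

test_that("every transcript receives exactly one valid label", {
  sim <- simulate_decay_dataset(sim_decay_params(n_transcripts = 150,
    noise_cv = 0.3, seed = 13))
  cl <- classify_decay(sim$abundance)
  expect_setequal(cl$results$transcript_id, sim$truth$transcript_id)
  expect_true(all(cl$results$label %in%
    c("stabilized", "destabilized", "unaffected", "unclassified",
      "removed_nondecaying")))
  expect_false(anyNA(cl$results$label))
})

test_that("stability change is the median knockdown-minus-control contrast", {
  # knockdown exceeds control by exactly 2 everywhere
  up2 <- list(control = flat_curves(1)$control,
              knockdown = flat_curves(3)$knockdown)
  s <- stability_change(make_abundance(list(A = up2)))
  expect_equal(s$s, 2)
  # median semantics across the three times
  tr <- list(control = matrix(0, 2, 4),
             knockdown = rbind(c(0, 1, 5, 100), c(0, 1, 5, 100)))
  expect_equal(stability_change(make_abundance(list(B = tr)))$s, 5)
  expect_equal(stability_change(make_abundance(list(C = flat_curves(4))))$s, 0)
})

test_that("stability tertiles follow the inclusive percentile rules", {
  g <- stability_groups(1:9)
  expect_equal(g[1:3], rep("small", 3))
  expect_equal(g[4:6], rep("moderate", 3))
  expect_equal(g[7:9], rep("large", 3))
  # grouping uses |S|
  expect_equal(stability_groups(-(1:9)), g)
  # a single extreme outlier does not change the bottom tertile
  g2 <- stability_groups(c(1:8, 1e6))
  expect_equal(g2[1:3], rep("small", 3))
  # heavy ties: both inclusive rules hold; 'small' takes precedence
  expect_equal(stability_groups(rep(2, 5)), rep("small", 5))
  expect_error(stability_groups(c(1, 2)), "at least 3")
})

test_that("swapping condition labels exactly exchanges the two affected classes", {
  for (sd in 1:3) {
    sim <- simulate_decay_dataset(sim_decay_params(n_transcripts = 120,
      class_proportions = c(stabilized = 0.2, destabilized = 0.2,
                            unaffected = 0.6),
      noise_cv = 0.1, seed = sd))
    a <- classify_decay(sim$abundance)$results
    b <- classify_decay(swap_conditions(sim$abundance))$results
    m <- merge(a[c("transcript_id", "label")], b[c("transcript_id", "label")],
               by = "transcript_id")
    expect_identical(unname(label_swap_map[m$label.x]), m$label.y)
  }
})

test_that("noisier data never yields more affected calls on average", {
  mean_calls <- vapply(c(0.02, 0.1, 0.3), function(cv) {
    mean(vapply(1:20, function(sd) {
      sim <- simulate_decay_dataset(sim_decay_params(n_transcripts = 60,
        class_proportions = c(stabilized = 1/3, destabilized = 1/3,
                              unaffected = 1/3),
        noise_cv = cv, seed = sd))
      sum(classify_decay(sim$abundance)$results$label %in%
            c("stabilized", "destabilized"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_calls) <= 0))
})

test_that("raw stabilization p-values are near-uniform under the null", {
  # the propagated-error z is a ratio of a normal to a scaled chi, i.e.
  # t-like with 2 df, so the normal-tail p deviates from exact
  # uniformity by a small bounded amount (max CDF distance ~0.05)
  sim <- simulate_decay_dataset(sim_decay_params(n_transcripts = 1000,
    class_proportions = c(stabilized = 0, destabilized = 0, unaffected = 1),
    noise_cv = 0.1, seed = 1))
  tab <- sim$abundance[sim$abundance$transcript_id != REF_STABLE, ]
  res <- classify_transcripts(tab)
  for (p in list(res$p_stab_8, res$p_dest_12)) {
    D <- suppressWarnings(ks.test(p, "punif"))$statistic
    expect_lt(unname(D), 0.10)
    expect_lt(abs(mean(p) - 0.5), 0.05)
  }
})
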