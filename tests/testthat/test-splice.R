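test_that("percent skipped follows the peak-area ratio and its symmetries", {
  expect_equal(percent_exon3_skipped(3, 1), 75)
  expect_equal(percent_exon3_skipped(0, 5), 0)
  expect_equal(percent_exon3_skipped(7, 7), 50)
  # complementarity and rescaling invariance over a grid of area pairs
  set.seed(31)
  a <- runif(50, 0, 100); t <- runif(50, 0.01, 100)
  expect_equal(percent_exon3_skipped(a, t) + percent_exon3_skipped(t, a),
               rep(100, 50))
  for (g in c(0.01, 3.7, 1e4)) {
    expect_equal(percent_exon3_skipped(g * a, g * t),
                 percent_exon3_skipped(a, t))
  }
  expect_error(percent_exon3_skipped(0, 0), "both extension-product areas")
  expect_error(percent_exon3_skipped(-1, 2), "non-negative")
})

test_that("replicate summaries average per-replicate percentages", {
  m <- data.frame(haplotype = "AACGGTGG", replicate = 1:2,
                  auc_a = c(10, 14), auc_t = c(90, 86))
  s <- summarize_haplotype(m)
  expect_equal(s$percent_skipped, 12)
  expect_equal(s$n_replicates, 2L)
  one <- summarize_haplotype(data.frame(haplotype = "GCGGGCAT",
                                        replicate = 1, auc_a = 7,
                                        auc_t = 93))
  expect_equal(one$percent_skipped, 7)
  mixed <- rbind(m, data.frame(haplotype = "GCGGGCAT", replicate = 1,
                               auc_a = 1, auc_t = 99))
  expect_error(summarize_haplotype(mixed), "mixed haplotypes")
})

test_that("duplicate-replicate means concentrate as the assay noise implies", {
  # with replicate SD 1.5 around a true 16%, the mean of two replicates
  # should fall within 1.96 * 1.5 / sqrt(2) of truth in about 95% of draws
  set.seed(160)
  hw <- 1.96 * 1.5 / sqrt(2)
  hits <- replicate(400, {
    pct <- rnorm(2, 16, 1.5)
    s <- summarize_haplotype(data.frame(haplotype = "AACGGTGG",
                                        replicate = 1:2, auc_a = pct,
                                        auc_t = 100 - pct))
    abs(s$percent_skipped - 16) <= hw
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("snp_effect separates constructed allele groups", {
  haps <- enumerate_minigene_haplotypes()
  g_at_7 <- allele_at(haps, "rs145009674") == "G"
  # every G haplotype is exactly 10x its A partner, with distinct values
  partner <- haps; substr(partner, 7, 7) <- "A"
  base <- (match(partner, haps) %% 64 + 1) / 10
  tab <- data.frame(haplotype = haps,
                    percent_skipped = ifelse(g_at_7, 10, 1) * base)
  eff <- snp_effect(tab, "rs145009674")
  expect_equal(eff$n_pairs, 64L)
  expect_equal(eff$fold, 10, tolerance = 1e-12)
  expect_lt(eff$p_adjusted, 0.05)
  expect_true(eff$significant)
  # pair-ratio fold agrees when every ratio is identical
  expect_equal(snp_effect(tab, "rs145009674",
                          fold_method = "pair_ratios")$fold, 10)
})

test_that("snp_effect on identical allele groups is null", {
  haps <- enumerate_minigene_haplotypes()
  tab <- data.frame(haplotype = haps, percent_skipped = 5)
  eff <- snp_effect(tab, "rs713")
  expect_equal(eff$fold, 1)
  expect_gt(eff$p_raw, 0.9)
  expect_false(eff$significant)
})

test_that("every unconstrained SNP pairs the 128 design into 64 pairs", {
  haps <- enumerate_minigene_haplotypes()
  set.seed(8)
  tab <- data.frame(haplotype = haps, percent_skipped = runif(128, 0, 30))
  for (snp in c("rs94930", "rs713", "rs731614", "rs149897670",
                "rs145009674", "rs155715655", "rs5986963/rs5986964")) {
    expect_equal(snp_effect(tab, snp)$n_pairs, 64L)
  }
})

test_that("fold is reciprocal under allele-group value exchange", {
  haps <- enumerate_minigene_haplotypes()
  set.seed(77)
  tab <- data.frame(haplotype = haps, percent_skipped = runif(128, 1, 40))
  f1 <- snp_effect(tab, "rs155715655")$fold
  # swap each pair's values: allele-1 members take allele-2 values and back
  pos8 <- substr(haps, 8, 8)
  partner <- haps
  substr(partner, 8, 8) <- ifelse(pos8 == "G", "T", "G")
  swapped <- tab
  swapped$percent_skipped <- tab$percent_skipped[match(partner,
                                                       tab$haplotype)]
  f2 <- snp_effect(swapped, "rs155715655")$fold
  expect_equal(f1 * f2, 1, tolerance = 1e-12)
})

test_that("snp_effect rejects impossible pairings", {
  haps <- enumerate_minigene_haplotypes()
  tab <- data.frame(haplotype = haps, percent_skipped = 1)
  expect_error(snp_effect(tab, "rs5986963"), "one unit")
  expect_error(snp_effect(tab, "rs5986964"), "one unit")
  expect_error(snp_effect(tab[-1, ], "rs713"), "unpaired")
})

test_that("the default synthetic assay recovers the configured allele effects", {
  a <- generate_assay(seed = 4)
  s <- summarize_assay(a)
  expect_equal(nrow(s), 128L)
  eff <- snp_effect(s, "rs145009674")
  # generating fold is 12.7; replicate noise and [0,100] truncation pull
  # the small-value allele group upward, so allow a wide stochastic band
  expect_gt(eff$fold, 9)
  expect_lt(eff$fold, 16)
  expect_true(eff$significant)
  # the weaker configured effects remain detectable before correction
  expect_lt(snp_effect(s, "rs155715655")$p_raw, 0.05)
})

test_that("a faithful assay passes the standard-curve calibration check", {
  known <- seq(0, 100, by = 10)
  sc <- standard_curve_check(known, percent_exon3_skipped(known, 100 - known))
  expect_equal(sc$slope, 1, tolerance = 1e-12)
  expect_equal(sc$intercept, 0, tolerance = 1e-9)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)
})
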