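test_that("inclusion filters drop flagged subjects, then small groups", {
  s <- subjects_df(rep(c("AACGGTGG", "GCGGGCAT"), c(5, 3)),
                   ser = rnorm(8))
  s$european[1] <- FALSE        # drops one AACGGTGG
  s$surgery[6] <- TRUE          # drops one GCGGGCAT -> group of 2
  out <- filter_cohort(s, min_group_size = 4)
  expect_identical(unique(out$opn1lw_hap), "AACGGTGG")
  expect_equal(nrow(out), 4L)
  log <- attr(out, "exclusion_log")
  expect_equal(sum(log$n_excluded), 4L)
  expect_true(any(grepl("shared by < 4", log$criterion)))
})

test_that("a haplotype shared by only 3 flag-passing subjects is excluded", {
  s <- subjects_df(rep(c("AACGGCAT", "GCGATCAT"), c(4, 3)), ser = rnorm(7))
  out <- filter_cohort(s)
  expect_false("GCGATCAT" %in% out$opn1lw_hap)
  expect_equal(nrow(out), 4L)
})

test_that("filtering is the identity on an all-passing cohort, and idempotent", {
  s <- subjects_df(rep("AACGGTGG", 6), ser = rnorm(6))
  out <- filter_cohort(s)
  expect_equal(nrow(out), 6L)
  co <- generate_cohort(seed = 12)
  f1 <- filter_cohort(co)
  f2 <- filter_cohort(f1)
  expect_equal(nrow(f1), 413L)
  expect_identical(f1$subject_id, f2$subject_id)
})

test_that("an emptied cohort warns rather than errors", {
  s <- subjects_df(rep("AACGGTGG", 3), ser = rnorm(3))
  s$european <- FALSE
  expect_warning(out <- filter_cohort(s), "empty cohort")
  expect_equal(nrow(out), 0L)
})

test_that("group summaries report n, median and mean per haplotype", {
  sp <- cohort_spec(within_group_sd = 0)
  co <- generate_cohort(sp, seed = 3)
  sm <- summarize_groups(co)
  t1 <- table1_fixture()
  expect_equal(sum(sm$n), 413L)
  expect_equal(nrow(sm), 11L)
  i <- match(sm$haplotype, t1$haplotype)
  expect_equal(sm$mean_ser, t1$mean_ser_os[i], tolerance = 1e-10)
  expect_identical(sm$amino, t1$amino_acids[i])
  one <- summarize_groups(subjects_df("AACGGTGG", -2.5))
  expect_equal(one$median_ser, -2.5)
  expect_equal(one$mean_ser, -2.5)
})

test_that("Kruskal-Wallis matches its closed form and handles degeneracy", {
  # complete separation of two groups of 10 distinct values
  kt <- kruskal_wallis(list(a = 1:10, b = 11:20))
  expect_equal(kt$statistic, 100 / 7, tolerance = 1e-10)  # 14.2857
  expect_lt(kt$p_value, 0.001)
  # all values tied: tie-corrected 0/0 resolved to H = 0, p = 1
  tied <- kruskal_wallis(list(a = rep(2, 5), b = rep(2, 7)))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
  expect_error(kruskal_wallis(list(a = 1:5)), "two groups")
  expect_error(kruskal_wallis(list(a = 1:5, b = numeric())), "empty group")
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(9)
  g <- list(a = rnorm(12, -1), b = rnorm(15, 0), c = rnorm(9, 0.5))
  h0 <- kruskal_wallis(g)$statistic
  for (f in list(exp, function(x) x^3, function(x) 5 * x - 2)) {
    expect_equal(kruskal_wallis(lapply(g, f))$statistic, h0,
                 tolerance = 1e-12)
  }
})

test_that("allele dichotomy isolates the rs145009674 G carriers", {
  co <- generate_cohort(seed = 21)
  res <- allele_dichotomy(co, "rs145009674", "G")
  # only AACGGTGG (the MVVVA group, n = 12) carries G at position 7
  expect_equal(unname(res$group_ns), c(12L, 401L))
  expect_identical(sort(unique(co$opn1lw_hap[
    allele_at(co$opn1lw_hap, "rs145009674") == "G"])), "AACGGTGG")
  expect_equal(sum(res$group_ns), nrow(co))
})

test_that("allele dichotomy recovers a configured mean shift", {
  t1 <- table1_fixture()
  means <- setNames(rep(-1.1486, 11), t1$haplotype)
  means["AACGGTGG"] <- -2.504
  sp <- cohort_spec(group_mean_ser = means, within_group_sd = 0.1,
                    cone_ratio_effect = 0, opn1mw_mvvva_effect = 0)
  co <- generate_cohort(sp, seed = 31)
  res <- allele_dichotomy(co, "rs145009674", "G")
  expect_equal(res$effect, 1.3554, tolerance = 0.05)
  expect_lt(res$p_value, 0.01)
})

test_that("identical allele groups give a null dichotomy", {
  s <- subjects_df(rep(c("AACGGTGG", "GCGGGCAT"), each = 10),
                   ser = rep(seq(-2, 0, length.out = 10), 2))
  res <- allele_dichotomy(s, "rs145009674", "G")
  expect_equal(res$effect, 0)
  expect_gt(res$p_value, 0.9)
  expect_error(allele_dichotomy(s, "rs713", "G"), "empty group")
})

test_that("cone-ratio classification rounds half-up before the thresholds", {
  s <- subjects_df(rep("AACGGTGG", 8), ser = c(-1, -2, -3, -1, -2, -3, -1, -2),
                   percent_l = c(67.0, 66.4, 66.6, 33.4, 33.0, 32.6, 50.0, 34.0))
  # half-up rounding first, then thresholds: 67.0 -> 67 skewed;
  # 66.4 -> 66 balanced; 66.6 -> 67 skewed; 33.4 -> 33 skewed;
  # 33.0 -> 33 skewed; 32.6 -> 33 skewed; 50 and 34 -> balanced
  cls <- c("skewed", "balanced", "skewed", "skewed", "skewed", "skewed",
           "balanced", "balanced")
  res <- cone_ratio_split(s)
  expect_equal(unname(res$group_ns["balanced"]), sum(cls == "balanced"))
  expect_equal(unname(res$group_ns["skewed"]), sum(cls == "skewed"))
})

test_that("cone-ratio split reports the balanced-minus-skewed difference", {
  set.seed(64)
  n <- 400
  pl <- runif(n, 20, 90)
  skewed <- floor(pl + 0.5) >= 67 | floor(pl + 0.5) <= 33
  ser <- rnorm(n, -1, 0.3) - 0.61 * (!skewed)
  s <- subjects_df(rep("AACGGTGG", n), ser = ser, percent_l = pl)
  res <- cone_ratio_split(s)
  expect_equal(res$effect, -0.61, tolerance = 0.15)
  expect_lt(res$p_value, 0.001)
  mw <- cone_ratio_split(s, test = "mann_whitney")
  expect_lt(mw$p_value, 0.001)
  expect_equal(mw$effect, res$effect)
})

test_that("degenerate cone-ratio inputs are rejected", {
  s <- subjects_df(rep("AACGGTGG", 4), ser = rnorm(4), percent_l = 50)
  expect_error(cone_ratio_split(s), "empty group")
  s$percent_l <- NA_real_
  expect_error(cone_ratio_split(s), "no percent_l")
})
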