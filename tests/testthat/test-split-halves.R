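test_that("well-separated groups rank identically in every half", {
  s <- two_group_cohort(n_per = 8, mean1 = -3, mean2 = 0, sd = 0.1)
  rk <- split_halves_rank(s, n_iterations = 50, seed = 5,
                          keep_iterations = TRUE)
  expect_equal(unname(rk$final_ranks["AACGGTGG"]), 1)
  expect_equal(unname(rk$final_ranks["GCGGGCAT"]), 2)
  expect_true(all(rk$per_iteration_ranks[, "AACGGTGG"] == 1))
})

test_that("every half-ranking and the final ranks sum to k(k+1)/2", {
  co <- generate_cohort(seed = 14)
  rk <- split_halves_rank(co, n_iterations = 40, seed = 2,
                          keep_iterations = TRUE)
  k <- length(rk$final_ranks)
  expect_equal(unname(rowSums(rk$per_iteration_ranks)),
               rep(k * (k + 1) / 2, 2 * 40))
  expect_equal(sum(rk$final_ranks), k * (k + 1) / 2, tolerance = 1e-10)
})

test_that("results are reproducible from the seed and leave the RNG alone", {
  co <- generate_cohort(seed = 14)
  set.seed(1234); before <- runif(5)
  set.seed(1234)
  r1 <- split_halves_rank(co, n_iterations = 30, seed = 7)
  after <- runif(5)
  expect_identical(before, after)  # caller's stream untouched
  r2 <- split_halves_rank(co, n_iterations = 30, seed = 7)
  expect_identical(r1$final_ranks, r2$final_ranks)
  r3 <- split_halves_rank(co, n_iterations = 30, seed = 8)
  expect_false(identical(r1$final_ranks, r3$final_ranks))
})

test_that("final ranks are equivariant under haplotype relabelling", {
  # deterministic ranking regime so label names are the only thing moving
  t1 <- table1_fixture()
  haps <- t1$haplotype[1:4]
  s <- subjects_df(rep(haps, each = 5),
                   ser = rep(c(-4, -2, 0, 2), each = 5))
  rk <- split_halves_rank(s, n_iterations = 20, seed = 1)
  perm <- rev(haps)
  s2 <- s
  s2$opn1lw_hap <- setNames(perm, haps)[s$opn1lw_hap]
  rk2 <- split_halves_rank(s2, n_iterations = 20, seed = 1)
  # each group keeps its rank under its new name
  expect_equal(unname(rk$final_ranks[haps]), as.numeric(1:4))
  expect_equal(unname(rk2$final_ranks[perm]), as.numeric(1:4))
  expect_equal(unname(rk2$final_ranks[setNames(perm, haps)[haps]]),
               unname(rk$final_ranks[haps]))
})

test_that("scrambled labels give mean final ranks near the centre", {
  co <- generate_cohort(seed = 44)
  acc <- NULL
  for (i in 1:60) {
    scr <- co
    set.seed(1000 + i)
    scr$opn1lw_hap <- sample(scr$opn1lw_hap)
    rk <- split_halves_rank(scr, n_iterations = 15, seed = i)
    acc <- rbind(acc, rk$final_ranks[sort(names(rk$final_ranks))])
  }
  # expectation under exchangeability is (k+1)/2 = 6 for every haplotype
  expect_true(all(abs(colMeans(acc) - 6) < 1.2))
})

test_that("the study-calibrated cohort reproduces the published ordering", {
  co <- generate_cohort(seed = 7)
  rk <- split_halves_rank(co, n_iterations = 1000, seed = 17)
  t1 <- table1_fixture()
  rho <- cor(rk$final_ranks[t1$haplotype], t1$split_halves_rank,
             method = "spearman")
  expect_gt(rho, 0.8)
  # MVVVA most myopic, GCCGGCAG least, as in the published ranking
  expect_equal(names(which.min(rk$final_ranks)), "AACGGTGG")
  expect_gt(rk$final_ranks["GCCGGCAG"], 9)
})

test_that("non-stratified halving still averages over available rankings", {
  s <- two_group_cohort(n_per = 4, sd = 0.05)
  rk <- split_halves_rank(s, n_iterations = 200, seed = 9,
                          stratified = FALSE)
  expect_equal(sort(unname(rk$final_ranks)), c(1, 2), tolerance = 0.2)
  expect_true(all(rk$n_half_rankings <= 400))
})

test_that("rank/mean correlation behaves on exact, printed, and degenerate input", {
  # exact linear relation
  m <- c(-3, -2, -1, 0); r <- 2 * m + 7
  expect_equal(rank_mean_correlation(m, r)$r, 1, tolerance = 1e-12)
  # the printed 11-haplotype summary columns
  t1 <- table1_fixture()
  ct <- rank_mean_correlation(
    data.frame(haplotype = t1$haplotype, mean_ser = t1$mean_ser_os),
    setNames(t1$split_halves_rank, t1$haplotype))
  expect_equal(ct$r, 0.9331943, tolerance = 1e-6)
  expect_equal(ct$r_squared, 0.8708517, tolerance = 1e-6)
  expect_equal(ct$n, 11L)
  expect_error(rank_mean_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(rank_mean_correlation(1:2, 1:2), "length >= 3")
})

test_that("variance explained is 1 for rank-determined SER and grows with OPN1MW", {
  co <- generate_cohort(seed = 3)
  rk <- split_halves_rank(co, n_iterations = 150, seed = 6)
  lin <- co
  lin$calculated_ser <- 0.4 * rk$final_ranks[lin$opn1lw_hap] - 3
  expect_equal(variance_explained(lin, rk)$r_squared, 1, tolerance = 1e-10)
  v1 <- variance_explained(co, rk)
  v2 <- variance_explained(co, rk, opn1mw_indicator = "opn1mw_mvvva_only")
  expect_gte(v2$r_squared, v1$r_squared)
  expect_lt(v1$p_value, 0.001)
  bad <- co; bad$opn1lw_hap[1] <- "AACGTTGG"
  expect_error(variance_explained(bad, rk), "no final rank")
})

test_that("scrambling the labels destroys the rank-mean correlation", {
  co <- generate_cohort(seed = 25)
  true_r2 <- rank_mean_correlation(
    summarize_groups(co),
    split_halves_rank(co, n_iterations = 150, seed = 1))$r_squared
  nulls <- vapply(1:25, function(i) {
    scrambled_null(co, n_iterations = 60, seed = i)$r_squared
  }, numeric(1))
  expect_gt(true_r2, 0.8)
  expect_lt(median(nulls), 0.3)
})
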