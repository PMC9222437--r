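#' Split-halves haplotype risk ranking
#'
#' The cohort is repeatedly randomized into two halves; within each half,
#' haplotypes are ranked by their mean calculated SER, ascending, so rank 1
#' is the most myopic haplotype and rank k the least (fractional mid-ranks
#' on ties). The final rank of each haplotype is the average of its ranks
#' over all half-rankings (both halves of every iteration, i.e. 2 x
#' `n_iterations` rankings for the default 1000 iterations).
#'
#' By default the halving is stratified within haplotype group — a group of
#' size n contributes floor(n/2) subjects to one half and ceiling(n/2) to
#' the other, with the side chosen at random — which guarantees every
#' haplotype is ranked in every half. In non-stratified mode a haplotype
#' can be absent from a half; it then simply receives no rank for that
#' half, and its final rank averages over the half-rankings in which it
#' appeared.
#'
#' @param subjects Filtered subject table.
#' @param n_iterations Number of random halvings (default 1000).
#' @param seed Optional integer; when given, the result is fully
#'   reproducible and the caller's RNG state is left untouched.
#' @param stratified Stratify the halving within haplotype groups
#'   (default `TRUE`).
#' @param keep_iterations Retain the per-half rank matrix (2 x
#'   `n_iterations` rows, one column per haplotype).
#' @param ser_col,hap_col Column names for calculated SER and the
#'   *OPN1LW* haplotype.
#' @return An object of class `split_halves`: `final_ranks` (named numeric,
#'   most myopic haplotype has the smallest rank), `n_iterations`,
#'   `stratified`, `seed`, and optionally `per_iteration_ranks`.
#' @export
split_halves_rank <- function(subjects, n_iterations = 1000, seed = NULL,
                              stratified = TRUE, keep_iterations = FALSE,
                              ser_col = "calculated_ser",
                              hap_col = "opn1lw_hap") {
  ser <- subjects[[ser_col]]
  f <- factor(subjects[[hap_col]])
  k <- nlevels(f)
  if (k < 2) stop("need at least 2 haplotype groups to rank", call. = FALSE)
  n <- length(ser)
  stopifnot(n_iterations >= 1)
  idx_by_g <- split(seq_len(n), f)
  if (stratified && any(lengths(idx_by_g) < 2)) {
    stop("stratified halving needs every haplotype group to have >= 2 ",
         "subjects", call. = FALSE)
  }
  with_seed(seed, {
    rank_sum <- stats::setNames(numeric(k), levels(f))
    rank_cnt <- stats::setNames(numeric(k), levels(f))
    kept <- if (keep_iterations)
      matrix(NA_real_, 2L * n_iterations, k,
             dimnames = list(NULL, levels(f)))
    half_a <- logical(n)
    for (it in seq_len(n_iterations)) {
      if (stratified) {
        half_a[] <- FALSE
        for (g in idx_by_g) {
          m <- length(g)
          take <- if (m %% 2L == 0L || stats::runif(1) < 0.5) m %/% 2L
                  else m %/% 2L + 1L
          half_a[g[sample.int(m, take)]] <- TRUE
        }
      } else {
        half_a[] <- FALSE
        half_a[sample.int(n, n %/% 2L)] <- TRUE
      }
      for (h in 1:2) {
        sel <- if (h == 1L) half_a else !half_a
        mg <- tapply(ser[sel], f[sel], mean)
        present <- which(!is.na(mg))
        r <- rank(mg[present], ties.method = "average")
        rank_sum[present] <- rank_sum[present] + r
        rank_cnt[present] <- rank_cnt[present] + 1
        if (keep_iterations) kept[2L * (it - 1L) + h, present] <- r
      }
    }
    structure(list(final_ranks = rank_sum / rank_cnt,
                   n_iterations = n_iterations,
                   n_half_rankings = unname(rank_cnt),
                   stratified = stratified, seed = seed,
                   per_iteration_ranks = kept),
              class = "split_halves")
  })
}

#' @export
print.split_halves <- function(x, ...) {
  cat(sprintf("Split-halves haplotype ranking (%d iterations, %s)\n",
              x$n_iterations,
              if (x$stratified) "stratified" else "non-stratified"))
  r <- sort(x$final_ranks)
  for (i in seq_along(r)) {
    cat(sprintf("  %-10s %6.2f%s\n", names(r)[i], r[i],
                if (i == 1) "  (most myopic)" else ""))
  }
  invisible(x)
}

.correlation_result <- function(r, p, n, method) {
  structure(list(r = r, r_squared = r^2, p_value = p, n = n,
                 method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  r = %.4f, r^2 = %.4f, p = %.4g (n = %d)\n",
              x$r, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Correlation between haplotype mean SER and final rank
#'
#' Pearson correlation between the per-haplotype mean calculated SER and
#' the split-halves final ranks, with the two-sided p-value from the t
#' distribution on k - 2 df. A strong positive correlation indicates the
#' ranking orders haplotypes consistently with their mean refraction.
#'
#' @param means Either a numeric vector of group mean SERs, or a data
#'   frame from [summarize_groups()] (columns `haplotype`, `mean_ser`).
#' @param ranks Either a numeric vector aligned with `means`, a named
#'   numeric vector of final ranks, or a `split_halves` object.
#' @return A `correlation_result` (`r`, `r_squared`, `p_value`, `n`).
#' @export
rank_mean_correlation <- function(means, ranks) {
  if (inherits(ranks, "split_halves")) ranks <- ranks$final_ranks
  if (is.data.frame(means)) {
    if (!all(c("haplotype", "mean_ser") %in% names(means))) {
      stop("summary data frame needs columns 'haplotype' and 'mean_ser'",
           call. = FALSE)
    }
    if (!is.null(names(ranks))) {
      if (!all(means$haplotype %in% names(ranks))) {
        stop("ranks missing for haplotype(s): ",
             paste(setdiff(means$haplotype, names(ranks)), collapse = ", "),
             call. = FALSE)
      }
      ranks <- ranks[means$haplotype]
    }
    means <- means$mean_ser
  }
  if (length(means) != length(ranks) || length(means) < 3) {
    stop("need matched mean/rank vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(means) == 0 || stats::sd(ranks) == 0) {
    stop("zero variance in means or ranks: correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(means, as.numeric(ranks), method = "pearson")
  .correlation_result(unname(ct$estimate), ct$p.value, length(means),
                      "Pearson correlation, haplotype mean SER vs final rank")
}

#' Variance in SER explained by haplotype rank
#'
#' Scores every subject with the final rank of their haplotype and
#' correlates the score with calculated SER across subjects; the squared
#' Pearson coefficient estimates the fraction of SER variance attributable
#' to the ranked *OPN1LW* haplotypes. Optionally a 0/1 indicator for
#' "*OPN1MW* genes encoding only MVVVA" is added as a second predictor in
#' an ordinary least-squares fit, and the two-predictor R-squared is
#' reported (with the overall F-test p-value).
#'
#' @param subjects Filtered subject table.
#' @param ranks A `split_halves` object or named rank vector covering every
#'   haplotype present.
#' @param opn1mw_indicator Optional: a logical vector (one per subject) or
#'   the name of a logical column flagging subjects whose *OPN1MW* genes
#'   encode only MVVVA.
#' @param ser_col,hap_col Column names.
#' @return A `correlation_result`; for the two-predictor fit, `r` is the
#'   square root of the model R-squared.
#' @export
variance_explained <- function(subjects, ranks, opn1mw_indicator = NULL,
                               ser_col = "calculated_ser",
                               hap_col = "opn1lw_hap") {
  if (inherits(ranks, "split_halves")) ranks <- ranks$final_ranks
  hap <- subjects[[hap_col]]
  if (!all(hap %in% names(ranks))) {
    stop("no final rank for haplotype(s): ",
         paste(unique(setdiff(hap, names(ranks))), collapse = ", "),
         call. = FALSE)
  }
  score <- unname(ranks[hap])
  ser <- subjects[[ser_col]]
  if (is.null(opn1mw_indicator)) {
    ct <- stats::cor.test(score, ser, method = "pearson")
    return(.correlation_result(unname(ct$estimate), ct$p.value, length(ser),
      "Pearson correlation, per-subject haplotype rank vs calculated SER"))
  }
  ind <- if (is.character(opn1mw_indicator))
    as.logical(subjects[[opn1mw_indicator]]) else as.logical(opn1mw_indicator)
  fit <- stats::lm(ser ~ score + ind)
  sm <- summary(fit)
  p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                 lower.tail = FALSE)
  res <- .correlation_result(sqrt(sm$r.squared), unname(p), length(ser),
    "OLS R-squared, SER on haplotype rank + OPN1MW MVVVA-only indicator")
  res$r_squared <- sm$r.squared
  res
}

#' Scrambled-label validation null
#'
#' Permutes the subject-to-haplotype assignments (preserving group sizes)
#' and reruns the split-halves ranking on the scrambled cohort. The
#' resulting final ranks are correlated with the haplotypes' original
#' (unscrambled) mean SERs: scrambling severs the subject-haplotype link,
#' so a sound ranking procedure must show no significant correlation with
#' the real haplotype means. (Correlating against the scrambled groups'
#' own sample means would not test this — ranks derived from a sample
#' always track that same sample's means, association or not.)
#'
#' @inheritParams split_halves_rank
#' @return A `correlation_result` for the scrambled cohort.
#' @export
scrambled_null <- function(subjects, n_iterations = 1000, seed = NULL,
                           stratified = TRUE, ser_col = "calculated_ser",
                           hap_col = "opn1lw_hap") {
  orig_means <- tapply(subjects[[ser_col]], subjects[[hap_col]], mean)
  with_seed(seed, {
    scr <- subjects
    scr[[hap_col]] <- sample(scr[[hap_col]])
    rk <- split_halves_rank(scr, n_iterations = n_iterations, seed = NULL,
                            stratified = stratified, ser_col = ser_col,
                            hap_col = hap_col)
    res <- rank_mean_correlation(as.numeric(orig_means),
                                 rk$final_ranks[names(orig_means)])
    res$method <- "Pearson correlation under scrambled haplotype labels"
    res
  })
}
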