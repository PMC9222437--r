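#' Apply the study inclusion filters to a subject table
#'
#' Retains subjects who reported European ancestry, have normal
#' trichromatic color vision, have no prior eye surgery or injury, and
#' carry a single *OPN1LW* gene sequence; then, among the flag-passing
#' subjects, keeps only those whose *OPN1LW* exon-3 haplotype is shared by
#' at least `min_group_size` of them. The group-size filter is applied once
#' on the flag-passing set (flags first, then group size).
#'
#' @param subjects Data frame with logical columns `european`, `cv_normal`,
#'   `surgery`, `single_opn1lw` and a haplotype column `opn1lw_hap`.
#' @param min_group_size Minimum haplotype group size (default 4).
#' @return The retained rows, with an `exclusion_log` attribute: a data
#'   frame of per-criterion exclusion counts. An empty result is returned
#'   with a warning, not an error.
#' @export
filter_cohort <- function(subjects, min_group_size = 4) {
  need <- c("european", "cv_normal", "surgery", "single_opn1lw", "opn1lw_hap")
  if (!all(need %in% names(subjects))) {
    stop("subjects must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(subjects))
  log <- data.frame(criterion = character(), n_excluded = integer(),
                    stringsAsFactors = FALSE)
  note <- function(log, what, dropped) {
    rbind(log, data.frame(criterion = what, n_excluded = sum(dropped),
                          stringsAsFactors = FALSE))
  }
  for (flag in list(c("european", "non-European ancestry"),
                    c("cv_normal", "abnormal color vision"))) {
    dropped <- keep & !as.logical(subjects[[flag[1]]])
    log <- note(log, flag[2], dropped)
    keep <- keep & !dropped
  }
  dropped <- keep & as.logical(subjects$surgery)
  log <- note(log, "prior eye surgery or injury", dropped)
  keep <- keep & !dropped
  dropped <- keep & !as.logical(subjects$single_opn1lw)
  log <- note(log, "multiple OPN1LW sequences", dropped)
  keep <- keep & !dropped

  counts <- table(subjects$opn1lw_hap[keep])
  small <- keep & counts[subjects$opn1lw_hap] < min_group_size
  small[is.na(small)] <- FALSE
  log <- note(log, sprintf("haplotype shared by < %d subjects", min_group_size),
              small)
  keep <- keep & !small

  out <- subjects[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("all subjects excluded: empty cohort", call. = FALSE)
  attr(out, "exclusion_log") <- log
  out
}

#' Per-haplotype SER summaries
#'
#' @param subjects Filtered subject table with columns `opn1lw_hap` and the
#'   SER column named by `ser_col`.
#' @param ser_col Name of the calculated-SER column (default
#'   `"calculated_ser"`).
#' @return Data frame with one row per haplotype: `haplotype`, `amino`,
#'   `n`, `median_ser`, `mean_ser`, sorted by `mean_ser` ascending (most
#'   myopic first).
#' @export
summarize_groups <- function(subjects, ser_col = "calculated_ser") {
  if (!ser_col %in% names(subjects)) {
    stop("no column '", ser_col, "' in subjects", call. = FALSE)
  }
  ser <- subjects[[ser_col]]
  hap <- subjects$opn1lw_hap
  out <- data.frame(
    haplotype = sort(unique(hap)),
    stringsAsFactors = FALSE)
  out$amino <- translate_haplotype(out$haplotype)
  out$n <- as.integer(table(hap)[out$haplotype])
  out$median_ser <- as.numeric(tapply(ser, hap, stats::median)[out$haplotype])
  out$mean_ser <- as.numeric(tapply(ser, hap, mean)[out$haplotype])
  out <- out[order(out$mean_ser), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.group_test <- function(statistic, p_value, group_medians, group_means,
                        effect, method, extra = list()) {
  structure(c(list(statistic = statistic, p_value = p_value,
                   group_medians = group_medians, group_means = group_means,
                   effect = effect, method = method), extra),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$group_ns)) {
    cat("  n:      ", paste(sprintf("%s=%d", names(x$group_ns), x$group_ns),
                            collapse = "  "), "\n")
  }
  cat("  medians:", paste(sprintf("%s=%.4g", names(x$group_medians),
                                  x$group_medians), collapse = "  "), "\n")
  cat("  means:  ", paste(sprintf("%s=%.4g", names(x$group_means),
                                  x$group_means), collapse = "  "), "\n")
  if (!is.null(x$effect) && !is.na(x$effect)) {
    cat(sprintf("  effect (mean difference): %.4g D\n", x$effect))
  }
  cat(sprintf("  statistic = %.5g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Kruskal-Wallis test across haplotype groups
#'
#' Nonparametric one-way comparison of SER across haplotype groups, used
#' because group SER distributions are skewed with unequal spread. The H
#' statistic is tie-corrected; with every observation tied the 0/0 tie
#' correction is resolved by convention to H = 0, p = 1.
#'
#' @param groups Named list of numeric vectors (one per haplotype group,
#'   each non-empty; at least two groups).
#' @return A `group_test` object (`statistic` = H, `p_value` from the
#'   chi-squared distribution with k-1 df).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(!lengths(groups))) stop("empty group supplied", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  v <- unlist(groups, use.names = FALSE)
  f <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  meds <- vapply(groups, stats::median, numeric(1))
  mns <- vapply(groups, mean, numeric(1))
  if (stats::var(v) == 0) {
    return(.group_test(0, 1, meds, mns, NULL,
                       "Kruskal-Wallis rank sum test (all values tied)"))
  }
  kt <- stats::kruskal.test(v, f)
  .group_test(unname(kt$statistic), kt$p.value, meds, mns, NULL,
              "Kruskal-Wallis rank sum test")
}

#' Dichotomize the cohort by the allele at one SNP
#'
#' Splits subjects into carriers of `allele` at `snp_id` versus all others
#' and compares calculated SER between the two groups with a two-sided
#' Mann-Whitney U test (exact for small tie-free groups, such as the 12
#' rs145009674-G carriers). The reported effect is the mean SER of the
#' non-carrier group minus that of the carrier group, so a positive effect
#' means carriers are more myopic.
#'
#' @param subjects Filtered subject table (`opn1lw_hap` + SER column).
#' @param snp_id Panel SNP identifier.
#' @param allele Single nucleotide defining the carrier group.
#' @param ser_col Name of the SER column (default `"calculated_ser"`).
#' @return A `group_test` object with groups named `"with_<allele>"` and
#'   `"without_<allele>"`, plus `group_ns`.
#' @export
allele_dichotomy <- function(subjects, snp_id, allele,
                             ser_col = "calculated_ser") {
  ser <- subjects[[ser_col]]
  carrier <- allele_at(subjects$opn1lw_hap, snp_id) == toupper(allele)
  if (!any(carrier) || all(carrier)) {
    stop("allele dichotomy at ", snp_id, " leaves an empty group (",
         sum(carrier), " carriers of ", allele, ")", call. = FALSE)
  }
  g <- list(ser[carrier], ser[!carrier])
  names(g) <- c(paste0("with_", allele), paste0("without_", allele))
  mw <- mann_whitney_u(g[[1]], g[[2]])
  .group_test(mw$u, mw$p,
              vapply(g, stats::median, numeric(1)),
              vapply(g, mean, numeric(1)),
              mean(g[[2]]) - mean(g[[1]]),
              sprintf("Mann-Whitney U (%s), %s vs %s at %s",
                      if (mw$exact) "exact" else "normal approximation",
                      names(g)[1], names(g)[2], snp_id),
              extra = list(group_ns = lengths(g)))
}

#' Compare skewed versus balanced L:M cone-ratio groups
#'
#' Each subject's percent-L value is rounded to the nearest integer
#' (half-up) and classified: skewed if >= 67 or <= 33, balanced if 34-66.
#' SER is then compared between the classes. The reported effect is the
#' balanced-group mean minus the skewed-group mean (negative when balanced
#' cone ratios carry more myopia).
#'
#' @param subjects Subject table with `percent_l` and the SER column.
#' @param test `"welch"` (default, two-sided Welch t) or `"mann_whitney"`.
#' @param ser_col Name of the SER column (default `"calculated_ser"`).
#' @return A `group_test` object with groups `balanced` and `skewed` and
#'   `group_ns`.
#' @export
cone_ratio_split <- function(subjects, test = c("welch", "mann_whitney"),
                             ser_col = "calculated_ser") {
  test <- match.arg(test)
  if (is.null(subjects$percent_l) || all(is.na(subjects$percent_l))) {
    stop("no percent_l values available", call. = FALSE)
  }
  ok <- !is.na(subjects$percent_l)
  pl <- round_half_up(subjects$percent_l[ok])
  ser <- subjects[[ser_col]][ok]
  skewed <- pl >= 67 | pl <= 33
  if (!any(skewed) || all(skewed)) {
    stop("cone-ratio split leaves an empty group (", sum(skewed),
         " skewed of ", length(skewed), ")", call. = FALSE)
  }
  g <- list(balanced = ser[!skewed], skewed = ser[skewed])
  if (test == "welch") {
    tt <- stats::t.test(g$balanced, g$skewed)
    stat <- unname(tt$statistic); p <- tt$p.value
    method <- "Welch two-sample t-test, balanced vs skewed L:M cone ratio"
  } else {
    mw <- mann_whitney_u(g$balanced, g$skewed)
    stat <- mw$u; p <- mw$p
    method <- "Mann-Whitney U, balanced vs skewed L:M cone ratio"
  }
  .group_test(stat, p,
              vapply(g, stats::median, numeric(1)),
              vapply(g, mean, numeric(1)),
              mean(g$balanced) - mean(g$skewed),
              method, extra = list(group_ns = lengths(g)))
}
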