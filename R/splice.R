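#' Percent exon-3 skipping from primer-extension peak areas
#'
#' The single-base primer-extension assay yields two mass-spec products: an
#' A-extension product when exon 4 is spliced directly to exon 2 (exon 3
#' skipped) and a T-extension product when exon 4 is spliced to exon 3
#' (exon 3 included). Skipping is quantified as
#' \deqn{100 \times AUC_A / (AUC_A + AUC_T)}
#' which is invariant to any common rescaling of the two peak areas.
#'
#' @param auc_a Area under the A-extension (exon-3-skipped) product, >= 0.
#' @param auc_t Area under the T-extension (exon-3-included) product, >= 0.
#' @return Numeric vector of percentages in \[0, 100\].
#' @export
#' @examples
#' percent_exon3_skipped(3, 1)  # 75
percent_exon3_skipped <- function(auc_a, auc_t) {
  if (any(auc_a < 0) || any(auc_t < 0)) {
    stop("peak areas must be non-negative", call. = FALSE)
  }
  tot <- auc_a + auc_t
  if (any(tot == 0)) {
    stop("undefined measurement: both extension-product areas are zero",
         call. = FALSE)
  }
  100 * auc_a / tot
}

#' Average replicate skipping measurements for one haplotype
#'
#' Per-replicate percentages are computed with [percent_exon3_skipped()]
#' and averaged arithmetically (biological replicates, typically two, with
#' within-assay SD of about 1.5 percentage points or less).
#'
#' @param measurements Data frame with columns `haplotype`, `replicate`,
#'   `auc_a`, `auc_t`, all rows for a single haplotype.
#' @return One-row data frame: `haplotype`, `n_replicates`,
#'   `percent_skipped`.
#' @seealso [summarize_assay()] for a whole assay table at once.
#' @export
summarize_haplotype <- function(measurements) {
  need <- c("haplotype", "auc_a", "auc_t")
  if (!all(need %in% names(measurements)) || nrow(measurements) < 1) {
    stop("measurements must be a non-empty data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  haps <- unique(measurements$haplotype)
  if (length(haps) != 1) {
    stop("mixed haplotypes in one summary group: ",
         paste(haps, collapse = ", "), call. = FALSE)
  }
  pct <- percent_exon3_skipped(measurements$auc_a, measurements$auc_t)
  data.frame(haplotype = haps, n_replicates = nrow(measurements),
             percent_skipped = mean(pct), stringsAsFactors = FALSE)
}

#' Summarize a full splicing assay table
#'
#' @param measurements Data frame with columns `haplotype`, `replicate`,
#'   `auc_a`, `auc_t` covering any number of haplotypes.
#' @return Data frame with one row per haplotype (`haplotype`,
#'   `n_replicates`, `percent_skipped`), in haplotype order.
#' @export
summarize_assay <- function(measurements) {
  parts <- split(measurements, measurements$haplotype)
  out <- do.call(rbind, lapply(parts, summarize_haplotype))
  rownames(out) <- NULL
  out[order(out$haplotype), , drop = FALSE]
}

.joint_snp_id <- "rs5986963/rs5986964"

#' Per-SNP allele effect on exon-3 skipping across matched minigene pairs
#'
#' Partitions the summarized haplotypes into pairs that differ only at
#' `snp_id` (64 pairs in the full 128-minigene design) and compares the two
#' allele groups: group medians, a fold change, a two-sided Mann-Whitney U
#' test, and a Bonferroni-adjusted p-value over `n_comparisons` tests
#' (default 7: the six unconstrained SNPs plus the constrained
#' rs5986963/rs5986964 pair treated as one unit).
#'
#' Because rs5986963 and rs5986964 co-vary in the minigene design, neither
#' can be tested alone; pass `snp_id = "rs5986963/rs5986964"` to compare
#' the joint states (A,T) versus (G,G).
#'
#' @param table Data frame from [summarize_assay()] (`haplotype`,
#'   `percent_skipped`).
#' @param snp_id One unconstrained panel SNP id, or
#'   `"rs5986963/rs5986964"` for the constrained pair.
#' @param n_comparisons Bonferroni divisor (default 7).
#' @param fold_method `"group_means"` (default): ratio of the allele-2
#'   group mean to the allele-1 group mean; `"pair_ratios"`: mean of the
#'   per-pair allele-2/allele-1 ratios (undefined if any allele-1 member
#'   is 0).
#' @param test `"mann_whitney"` (default, independent allele groups, the
#'   study's named test) or `"wilcoxon_paired"` (signed-rank on the matched
#'   pairs).
#' @return An object of class `snp_effect` with fields `snp_id`, `alleles`,
#'   `n_pairs`, `median1`, `median2`, `fold`, `u_statistic`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
snp_effect <- function(table, snp_id, n_comparisons = 7,
                       fold_method = c("group_means", "pair_ratios"),
                       test = c("mann_whitney", "wilcoxon_paired")) {
  fold_method <- match.arg(fold_method)
  test <- match.arg(test)
  if (!all(c("haplotype", "percent_skipped") %in% names(table))) {
    stop("table must have columns 'haplotype' and 'percent_skipped'",
         call. = FALSE)
  }
  haps <- parse_haplotype(table$haplotype)
  pct <- stats::setNames(table$percent_skipped, haps)

  if (snp_id %in% c("rs5986963", "rs5986964")) {
    stop("rs5986963 and rs5986964 co-vary in the minigene design and ",
         "cannot be tested singly; use snp_id = \"", .joint_snp_id, "\" ",
         "to treat the pair as one unit", call. = FALSE)
  }
  if (snp_id %in% c(.joint_snp_id, "rs5986963+rs5986964")) {
    state <- substr(haps, 4, 5)
    in1 <- state == "AT"; in2 <- state == "GG"
    if (any(!in1 & !in2)) {
      stop("haplotype(s) outside the constrained (A,T)/(G,G) joint states: ",
           paste(haps[!in1 & !in2], collapse = ", "), call. = FALSE)
    }
    partner <- haps
    substr(partner, 4, 5) <- ifelse(in1, "GG", "AT")
    alleles <- c("AT", "GG")
    label <- .joint_snp_id
  } else {
    i <- .snp_index(snp_id)
    p <- snp_panel()
    a1 <- p$allele1[i]; a2 <- p$allele2[i]
    a <- substr(haps, i, i)
    in1 <- a == a1; in2 <- a == a2
    partner <- haps
    substr(partner, i, i) <- ifelse(in1, a2, a1)
    alleles <- c(a1, a2)
    label <- p$snp_id[i]
  }

  orphans <- haps[!partner %in% haps]
  if (length(orphans)) {
    stop("unpaired haplotype(s) for ", label, ": ",
         paste(utils::head(orphans, 8), collapse = ", "),
         if (length(orphans) > 8) ", ...", call. = FALSE)
  }
  g1 <- sort(haps[in1])
  g2 <- g1
  if (label == .joint_snp_id) {
    substr(g2, 4, 5) <- "GG"
  } else {
    substr(g2, i, i) <- alleles[2]
  }
  v1 <- unname(pct[g1])
  v2 <- unname(pct[g2])

  fold <- switch(fold_method,
    group_means = mean(v2) / mean(v1),
    pair_ratios = {
      if (any(v1 == 0)) stop("pair_ratios fold undefined: allele-1 member with 0% skipping",
                             call. = FALSE)
      mean(v2 / v1)
    })
  if (test == "mann_whitney") {
    mw <- mann_whitney_u(v1, v2)
    u <- mw$u; p_raw <- mw$p
  } else {
    wt <- suppressWarnings(stats::wilcox.test(v2, v1, paired = TRUE,
                                              alternative = "two.sided"))
    u <- unname(wt$statistic); p_raw <- wt$p.value
  }
  p_adj <- min(1, p_raw * n_comparisons)
  structure(list(snp_id = label, alleles = alleles, n_pairs = length(g1),
                 median1 = stats::median(v1), median2 = stats::median(v2),
                 fold = fold, u_statistic = u, p_raw = p_raw,
                 p_adjusted = p_adj, significant = p_adj < 0.05,
                 test = test, fold_method = fold_method,
                 n_comparisons = n_comparisons),
            class = "snp_effect")
}

#' @export
print.snp_effect <- function(x, ...) {
  cat("Allele effect on exon-3 skipping at ", x$snp_id, "\n", sep = "")
  cat(sprintf("  %d matched pairs; medians %s=%.3g%%, %s=%.3g%%\n",
              x$n_pairs, x$alleles[1], x$median1, x$alleles[2], x$median2))
  cat(sprintf("  fold (%s -> %s, %s): %.3g\n",
              x$alleles[1], x$alleles[2], x$fold_method, x$fold))
  cat(sprintf("  %s: U = %.4g, p = %.3g (Bonferroni x%d: %.3g)%s\n",
              if (x$test == "mann_whitney") "Mann-Whitney" else "Wilcoxon signed-rank",
              x$u_statistic, x$p_raw, x$n_comparisons, x$p_adjusted,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Standard-curve linear calibration check
#'
#' The assay was validated against known mixtures of exon-3-included and
#' exon-3-excluded templates. Given known mix fractions and the
#' percentages the assay computed for them, this fits the calibration line
#' and reports slope, intercept and R-squared (ideal: 1, 0, 1).
#'
#' @param known_percent Known percent-skipped of each calibration mix.
#' @param measured_percent Assay-computed percent-skipped.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
standard_curve_check <- function(known_percent, measured_percent) {
  stopifnot(length(known_percent) == length(measured_percent),
            length(known_percent) >= 3)
  fit <- stats::lm(measured_percent ~ known_percent)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = length(known_percent))
}
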