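#' Table 1 reference fixture
#'
#' The bundled per-haplotype summary of the 413-subject cohort: the 11
#' *OPN1LW* exon-3 haplotypes shared by at least four subjects, their
#' amino-acid translations, group sizes, median and mean calculated SER
#' (left eye), percent exon-3 skipping, and the split-halves ranks. The
#' `printed_haplotype` column preserves the originally printed nucleotide
#' spelling where it differs from the validated `haplotype` (one row: the
#' published "GCGGGGAT" carries an off-panel G at rs149897670 and is
#' stored corrected to "GCGGGTAT", consistent with its printed LVVIS
#' residues; the `note` column records this).
#'
#' @return Data frame with columns `haplotype`, `printed_haplotype`,
#'   `amino_acids`, `n`, `median_ser_os`, `mean_ser_os`,
#'   `pct_exon3_skipping`, `split_halves_rank`, `note`.
#' @export
read_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cohort.tsv", package = "opsinmyopia",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Specification for a synthetic cohort
#'
#' Defaults reproduce the study conditions: the 11 haplotype groups with
#' the fixture's group sizes (summing to 413 subjects) and group mean
#' SERs; within-group SER SD of 2.0 D (a typical adult refraction spread;
#' not printed in the source summaries); corneal power around 43.5 +/- 1.4
#' D; percent-L cones around 67 +/- 12 (the ~2L:1M European average); a
#' 0.61 D extra-myopia effect for balanced cone ratios; and an *OPN1MW*
#' MVVVA-only subgroup at frequency 64/413 with a 0.39 D effect.
#'
#' @param group_sizes Named integer vector, haplotype -> n.
#' @param group_mean_ser Named numeric vector, haplotype -> mean SER (D).
#' @param within_group_sd Within-haplotype SER SD, diopters.
#' @param cc_mean,cc_sd Corneal curvature distribution, diopters.
#' @param percent_l_mean,percent_l_sd Percent-L cone distribution
#'   (truncated to \[0, 100\] when drawn).
#' @param cone_ratio_effect Extra myopia (D) in the balanced cone-ratio
#'   class relative to the skewed class.
#' @param opn1mw_mvvva_freq Proportion of subjects whose *OPN1MW* genes
#'   encode only MVVVA.
#' @param opn1mw_mvvva_effect Extra myopia (D) for that subgroup.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = NULL, group_mean_ser = NULL,
                        within_group_sd = 2.0,
                        cc_mean = 43.5, cc_sd = 1.4,
                        percent_l_mean = 67, percent_l_sd = 12,
                        cone_ratio_effect = 0.61,
                        opn1mw_mvvva_freq = 64 / 413,
                        opn1mw_mvvva_effect = 0.39) {
  if (is.null(group_sizes) || is.null(group_mean_ser)) {
    t1 <- read_table1_fixture()
    if (is.null(group_sizes)) {
      group_sizes <- stats::setNames(t1$n, t1$haplotype)
    }
    if (is.null(group_mean_ser)) {
      group_mean_ser <- stats::setNames(t1$mean_ser_os, t1$haplotype)
    }
  }
  stopifnot(all(group_sizes >= 1), within_group_sd >= 0, cc_sd > 0,
            percent_l_sd > 0,
            setequal(names(group_sizes), names(group_mean_ser)))
  parse_haplotype(names(group_sizes))  # strict validation of spec haplotypes
  structure(list(group_sizes = group_sizes,
                 group_mean_ser = group_mean_ser[names(group_sizes)],
                 within_group_sd = within_group_sd,
                 cc_mean = cc_mean, cc_sd = cc_sd,
                 percent_l_mean = percent_l_mean,
                 percent_l_sd = percent_l_sd,
                 cone_ratio_effect = cone_ratio_effect,
                 opn1mw_mvvva_freq = opn1mw_mvvva_freq,
                 opn1mw_mvvva_effect = opn1mw_mvvva_effect),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws one subject table with the statistical structure the association
#' analyses assume. Within each haplotype group, SER is Normal(group mean
#' + subject-level offsets, within-group SD); the cone-ratio and *OPN1MW*
#' offsets are centred within each group so group means stay at their
#' configured values (exactly so when `within_group_sd = 0`). Corneal
#' curvature is drawn and axial length is then solved from the SER formula,
#' so [estimate_ser()] on the generated biometry reproduces the drawn SER
#' to machine precision. All inclusion flags are set true.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the output is reproducible from it.
#' @param formula [ser_formula()] used for the AL back-solve.
#' @return Subject data frame with columns `subject_id`, `sex`,
#'   `european`, `cv_normal`, `surgery`, `single_opn1lw`, `opn1lw_hap`,
#'   `opn1mw_haps`, `opn1mw_mvvva_only`, `percent_l`, `cc_d`, `al_mm`,
#'   `calculated_ser`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1,
                            formula = ser_formula()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n_tot <- sum(spec$group_sizes)
    hap <- rep(names(spec$group_sizes), spec$group_sizes)
    percent_l <- rtruncnorm(n_tot, spec$percent_l_mean, spec$percent_l_sd,
                            0, 100)
    balanced <- {
      pl <- round_half_up(percent_l)
      !(pl >= 67 | pl <= 33)
    }
    mvvva <- stats::runif(n_tot) < spec$opn1mw_mvvva_freq
    offset <- -spec$cone_ratio_effect * balanced -
      spec$opn1mw_mvvva_effect * mvvva
    offset <- offset - stats::ave(offset, hap)  # centre within group
    ser <- rep(spec$group_mean_ser[names(spec$group_sizes)],
               spec$group_sizes) + offset +
      stats::rnorm(n_tot, 0, spec$within_group_sd)
    cc <- stats::rnorm(n_tot, spec$cc_mean, spec$cc_sd)
    al <- (formula$intercept - formula$cc_coefficient * cc - ser) /
      formula$al_coefficient
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n_tot)),
      sex = "M",
      european = TRUE, cv_normal = TRUE, surgery = FALSE,
      single_opn1lw = TRUE,
      opn1lw_hap = hap,
      opn1mw_haps = ifelse(mvvva, "MVVVA", "MVAIS"),
      opn1mw_mvvva_only = mvvva,
      percent_l = percent_l,
      cc_d = cc, al_mm = al,
      calculated_ser = unname(ser),
      stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Specification for a synthetic splicing assay
#'
#' Defaults encode the minigene findings: a 1% baseline skip level,
#' a 12.7-fold increase for G at rs145009674, and smaller 3-fold and
#' 2-fold increases for the G alleles of rs155715655 and rs5986963;
#' replicate noise SD 1.5 percentage points, two biological replicates.
#' The factor magnitudes for the two lesser SNPs are generator
#' configuration, not measured values.
#'
#' @param baseline_skip Baseline percent skipped for haplotypes with no
#'   effect allele.
#' @param snp_effects Named numeric vector of multiplicative factors.
#' @param effect_alleles Named character vector giving the allele that
#'   carries each factor (same names as `snp_effects`).
#' @param replicate_sd Replicate noise SD, percentage points.
#' @param n_replicates Biological replicates per haplotype.
#' @param gain_range Length-2 range for a uniform random per-measurement
#'   gain applied to both peak areas (the percentage is invariant to it);
#'   `c(1, 1)` disables it.
#' @return A list of class `assay_spec`.
#' @export
assay_spec <- function(baseline_skip = 1.0,
                       snp_effects = c(rs145009674 = 12.7,
                                       rs155715655 = 3,
                                       rs5986963 = 2),
                       effect_alleles = c(rs145009674 = "G",
                                          rs155715655 = "G",
                                          rs5986963 = "G"),
                       replicate_sd = 1.5, n_replicates = 2,
                       gain_range = c(1, 1)) {
  stopifnot(baseline_skip > 0, all(snp_effects > 0), replicate_sd >= 0,
            n_replicates >= 1, length(gain_range) == 2,
            all(gain_range > 0),
            setequal(names(snp_effects), names(effect_alleles)))
  structure(list(baseline_skip = baseline_skip, snp_effects = snp_effects,
                 effect_alleles = effect_alleles[names(snp_effects)],
                 replicate_sd = replicate_sd, n_replicates = n_replicates,
                 gain_range = gain_range),
            class = "assay_spec")
}

#' Generate a synthetic minigene splicing assay
#'
#' For each of the 128 enumerated minigene haplotypes, the true percent
#' skipped is the baseline multiplied by the factor of every effect allele
#' carried, clipped to \[0, 100\]. Replicates are drawn from a Normal
#' around the true value truncated to \[0, 100\] and emitted as AUC pairs
#' (`auc_a` = skipped signal, `auc_t` = included signal, both scaled by a
#' common random gain), so [percent_exon3_skipped()] inverts the generator
#' exactly when the noise is off.
#'
#' @param spec An [assay_spec()].
#' @param seed Integer seed.
#' @return Data frame with columns `haplotype`, `replicate`, `auc_a`,
#'   `auc_t` (128 x `n_replicates` rows) and attribute `true_skip`
#'   (named vector of generating values).
#' @export
generate_assay <- function(spec = assay_spec(), seed = 1) {
  stopifnot(inherits(spec, "assay_spec"))
  haps <- enumerate_minigene_haplotypes()
  truth <- rep(spec$baseline_skip, length(haps))
  for (snp in names(spec$snp_effects)) {
    carried <- allele_at(haps, snp) == spec$effect_alleles[[snp]]
    truth[carried] <- truth[carried] * spec$snp_effects[[snp]]
  }
  truth <- pmin(pmax(truth, 0), 100)
  names(truth) <- haps
  with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(spec$n_replicates),
                        haplotype = haps, stringsAsFactors = FALSE)
    rows <- rows[, c("haplotype", "replicate")]
    pct <- rtruncnorm(nrow(rows), truth[rows$haplotype],
                      spec$replicate_sd, 0, 100)
    gain <- stats::runif(nrow(rows), spec$gain_range[1], spec$gain_range[2])
    rows$auc_a <- pct * gain
    rows$auc_t <- (100 - pct) * gain
    rownames(rows) <- NULL
    attr(rows, "true_skip") <- truth
    rows
  })
}

#' Specification for a synthetic paired-eye lens trial
#'
#' Defaults match the pilot crossover design: 13 subjects for a first
#' 3-month period (experimental lens on the dominant eye), of whom 7
#' re-enroll for a second period with the arms swapped; biweekly visits
#' over 90 days; arm growth rates 0.063 (experimental) and 1.43 (control)
#' um/day. The between-eye rate SD (1.2 um/day) and per-point measurement
#' noise (10 um) are sized so simulated arm standard errors land near the
#' reported +/-0.33 and +/-0.24 um/day at 20 eyes per arm.
#'
#' @param n_subjects Subjects in period 1.
#' @param n_reenroll Subjects re-enrolling for period 2 (<= `n_subjects`).
#' @param rate_experimental,rate_control True arm growth rates, um/day.
#' @param visit_days Visit schedule, days from period start.
#' @param point_noise_sd Per-measurement noise, um.
#' @param between_eye_rate_sd SD of true per-eye rates around the arm
#'   rate, um/day.
#' @param baseline_mean,baseline_sd Baseline axial length distribution, mm.
#' @return A list of class `trial_spec`.
#' @export
trial_spec <- function(n_subjects = 13, n_reenroll = 7,
                       rate_experimental = 0.063, rate_control = 1.43,
                       visit_days = seq(0, 90, by = 14),
                       point_noise_sd = 10, between_eye_rate_sd = 1.2,
                       baseline_mean = 24.5, baseline_sd = 1.0) {
  stopifnot(n_subjects >= 1, n_reenroll >= 0, n_reenroll <= n_subjects,
            length(visit_days) >= 3, visit_days[1] == 0,
            !is.unsorted(visit_days, strictly = TRUE),
            point_noise_sd >= 0, between_eye_rate_sd >= 0)
  structure(list(n_subjects = n_subjects, n_reenroll = n_reenroll,
                 rate_experimental = rate_experimental,
                 rate_control = rate_control, visit_days = visit_days,
                 point_noise_sd = point_noise_sd,
                 between_eye_rate_sd = between_eye_rate_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "trial_spec")
}

#' Generate synthetic paired-eye trial trajectories
#'
#' Per subject-period, both eyes are simulated: a true per-eye slope drawn
#' Normal(arm rate, between-eye SD), measurements slope x day + Normal
#' point noise, reported as axial length in mm around a subject baseline.
#' In period 1 the dominant eye wears the experimental lens; re-enrolled
#' subjects swap arms in period 2.
#'
#' @param spec A [trial_spec()].
#' @param seed Integer seed.
#' @return Trajectory data frame (`subject_id`, `eye`, `arm`, `period`,
#'   `day`, `al_mm`, `true_slope_um_day`).
#' @export
generate_trial <- function(spec = trial_spec(), seed = 1) {
  stopifnot(inherits(spec, "trial_spec"))
  with_seed(seed, {
    out <- list()
    for (s in seq_len(spec$n_subjects)) {
      base <- stats::rnorm(1, spec$baseline_mean, spec$baseline_sd)
      periods <- if (s <= spec$n_reenroll) 1:2 else 1L
      for (per in periods) {
        # period 1: dominant eye experimental; period 2: arms swapped
        arms <- if (per == 1L) {
          c(dominant = "experimental", non_dominant = "control")
        } else {
          c(dominant = "control", non_dominant = "experimental")
        }
        for (eye in names(arms)) {
          rate <- if (arms[[eye]] == "experimental") {
            spec$rate_experimental
          } else {
            spec$rate_control
          }
          slope <- stats::rnorm(1, rate, spec$between_eye_rate_sd)
          delta <- slope * spec$visit_days +
            stats::rnorm(length(spec$visit_days), 0, spec$point_noise_sd)
          out[[length(out) + 1L]] <- data.frame(
            subject_id = sprintf("P%02d", s), eye = eye,
            arm = unname(arms[[eye]]), period = per,
            day = spec$visit_days,
            al_mm = base + delta / 1000,
            true_slope_um_day = slope,
            stringsAsFactors = FALSE)
        }
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
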