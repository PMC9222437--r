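#' Normalize axial-length trajectories to change from baseline
#'
#' Re-expresses each eye's axial-length series as micrometres of change
#' from its first (baseline) visit within a trial period. Trajectories are
#' grouped by subject, eye and period; the earliest day in each group is
#' the baseline and maps to 0 um.
#'
#' @param traj Data frame with columns `subject_id`, `eye`, `arm`,
#'   `period`, `day`, `al_mm`.
#' @return The input with an added `delta_um` column.
#' @export
normalize_trajectory <- function(traj) {
  need <- c("subject_id", "eye", "period", "day", "al_mm")
  if (!all(need %in% names(traj))) {
    stop("trajectory table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(traj$subject_id, traj$eye, traj$period, drop = TRUE)
  traj$delta_um <- NA_real_
  for (g in split(seq_len(nrow(traj)), key)) {
    g <- g[order(traj$day[g])]
    base <- traj$al_mm[g[1L]]
    traj$delta_um[g] <- (traj$al_mm[g] - base) * 1000
  }
  traj
}

#' Fit an axial growth rate to one eye's trajectory
#'
#' Ordinary least-squares slope of normalized axial length (um) against
#' day, giving the eye's growth rate in um/day.
#'
#' @param days Visit days from period start (>= 3 distinct values).
#' @param delta_um Normalized axial length, micrometres from baseline.
#' @return List of class `growth_rate`: `slope` (um/day), `intercept`
#'   (um), `residual_sd` (um), `n_points`.
#' @export
#' @examples
#' fit_growth_rate(seq(0, 84, 14), 1.43 * seq(0, 84, 14))
fit_growth_rate <- function(days, delta_um) {
  if (length(days) != length(delta_um) || length(days) < 3) {
    stop("need >= 3 matched (day, length) points to fit a growth rate",
         call. = FALSE)
  }
  if (length(unique(days)) < 2) {
    stop("zero time-span: all measurements on the same day", call. = FALSE)
  }
  fit <- stats::lm(delta_um ~ days)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = suppressWarnings(summary(fit)$sigma),
                 n_points = length(days)),
            class = "growth_rate")
}

#' Per-eye growth rates for a whole trial table
#'
#' @param traj Trajectory table; normalized with [normalize_trajectory()]
#'   first if it has no `delta_um` column.
#' @return Data frame with one row per subject/eye/period:
#'   `subject_id`, `eye`, `arm`, `period`, `slope_um_day`, `residual_sd`,
#'   `n_points`.
#' @export
fit_growth_rates <- function(traj) {
  if (is.null(traj$delta_um)) traj <- normalize_trajectory(traj)
  key <- interaction(traj$subject_id, traj$eye, traj$period, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(traj)), key), function(g) {
    arm <- unique(traj$arm[g])
    if (length(arm) != 1) {
      stop("inconsistent arm label within one eye-period", call. = FALSE)
    }
    gr <- fit_growth_rate(traj$day[g], traj$delta_um[g])
    data.frame(subject_id = traj$subject_id[g[1]], eye = traj$eye[g[1]],
               arm = arm, period = traj$period[g[1]],
               slope_um_day = gr$slope, residual_sd = gr$residual_sd,
               n_points = gr$n_points, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare experimental versus control arms of the paired-eye trial
#'
#' In the crossover design each subject wears the experimental lens on one
#' eye and the control lens on the other, so eyes pair within
#' subject-period. Per-eye growth rates are fitted, each arm is summarized
#' (mean rate, SE = SD/sqrt(n)), and the experimental-minus-control slope
#' differences — one per subject-period, pooled across periods (13 + 7
#' pairs in the study design) — enter a two-sided paired test. Per-period
#' analyses are also returned.
#'
#' @param traj Trajectory table (`subject_id`, `eye`, `arm`, `period`,
#'   `day`, `al_mm`), arms labelled `"experimental"` and `"control"`.
#' @param test `"paired_t"` (default) or `"wilcoxon"` (signed-rank).
#' @return An object of class `arm_comparison`: `arms` (per-arm summary
#'   data frame), `diffs` (experimental - control, um/day),
#'   `mean_difference`, `p_paired`, `per_period` (list of per-period
#'   results), `test`, `rates` (the per-eye rate table).
#' @export
compare_arms <- function(traj, test = c("paired_t", "wilcoxon")) {
  test <- match.arg(test)
  rates <- fit_growth_rates(traj)
  if (!all(rates$arm %in% c("experimental", "control"))) {
    stop("arm labels must be 'experimental' or 'control'", call. = FALSE)
  }
  pair_key <- interaction(rates$subject_id, rates$period, drop = TRUE)
  diffs <- vapply(split(seq_len(nrow(rates)), pair_key), function(g) {
    if (length(g) != 2 || !setequal(rates$arm[g], c("experimental", "control"))) {
      stop("subject-period ", pair_key[g[1]], " does not contribute exactly ",
           "one experimental and one control eye", call. = FALSE)
    }
    rates$slope_um_day[g[rates$arm[g] == "experimental"]] -
      rates$slope_um_day[g[rates$arm[g] == "control"]]
  }, numeric(1))

  arm_summary <- function(r) {
    do.call(rbind, lapply(c("experimental", "control"), function(a) {
      s <- r$slope_um_day[r$arm == a]
      data.frame(arm = a, n_eyes = length(s), mean_rate = mean(s),
                 se_rate = stats::sd(s) / sqrt(length(s)),
                 stringsAsFactors = FALSE)
    }))
  }
  paired_p <- function(d) {
    # degenerate spreads: identical eyes -> no effect; a constant nonzero
    # difference has no within-pair variability to test against
    if (all(d == 0)) return(1)
    if (length(d) < 2 || stats::sd(d) == 0) return(NA_real_)
    if (test == "paired_t") stats::t.test(d)$p.value
    else suppressWarnings(stats::wilcox.test(d)$p.value)
  }

  per_period <- lapply(split(rates, rates$period), function(r) {
    pk <- interaction(r$subject_id, r$period, drop = TRUE)
    d <- vapply(split(seq_len(nrow(r)), pk), function(g) {
      r$slope_um_day[g[r$arm[g] == "experimental"]] -
        r$slope_um_day[g[r$arm[g] == "control"]]
    }, numeric(1))
    list(arms = arm_summary(r), diffs = d, mean_difference = mean(d),
         p_paired = paired_p(d))
  })

  structure(list(arms = arm_summary(rates), diffs = diffs,
                 mean_difference = mean(diffs), p_paired = paired_p(diffs),
                 per_period = per_period, test = test, rates = rates),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat("Paired-eye lens trial, per-eye axial growth rates (um/day)\n")
  for (i in seq_len(nrow(x$arms))) {
    cat(sprintf("  %-12s %5.3f +/- %.3f (mean +/- SE, n = %d eyes)\n",
                x$arms$arm[i], x$arms$mean_rate[i], x$arms$se_rate[i],
                x$arms$n_eyes[i]))
  }
  cat(sprintf("  experimental - control: %.3f um/day over %d pairs, %s p = %.4g\n",
              x$mean_difference, length(x$diffs),
              if (x$test == "paired_t") "paired t" else "Wilcoxon signed-rank",
              x$p_paired))
  invisible(x)
}

#' @export
plot.arm_comparison <- function(x, ...) {
  graphics::boxplot(slope_um_day ~ arm, data = x$rates,
                    ylab = "axial growth rate (um/day)", ...)
  invisible(x)
}
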