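# Shared statistical helpers. These wrap stats:: routines with the
# conventions used throughout the package (exact-vs-approximate policy,
# degenerate-input handling); they are not re-implementations.

# Evaluate expr with the RNG seeded from `seed`, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Two-sided Mann-Whitney U. Exact enumeration for small tie-free samples
# (min n <= 12 and max n <= 20, covering the 12-carrier dichotomy), normal
# approximation with continuity and tie correction otherwise.
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  if (stats::var(c(x, y)) == 0) {
    # every observation tied: no evidence of a shift by convention
    return(list(u = length(x) * length(y) / 2, p = 1, exact = FALSE))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 12 &&
    max(length(x), length(y)) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(u = unname(wt$statistic), p = min(wt$p.value, 1), exact = exact)
}

# Inverse-CDF sampler for the truncated normal.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(pmin(pmax(rep_len(mean, n), lower), upper))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# Round half away from zero (deterministic, unlike banker's rounding).
round_half_up <- function(x) floor(x + 0.5)
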