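#' Spherical equivalent refraction formula
#'
#' Container for the linear conversion from ocular biometry to calculated
#' spherical equivalent refraction (SER, diopters):
#' \deqn{SER = -(AL \times a + b \times CC) + c}
#' where AL is axial length in mm, CC is corneal curvature (keratometry
#' mean) in diopters, and the defaults are the calibration coefficients
#' derived from 373 subjects with observed refractions
#' (a = 2.03 D/mm, b = 0.94, c = 88.58 D).
#'
#' @param al_coefficient Diopters of SER per mm of axial length
#'   (non-negative).
#' @param cc_coefficient Dimensionless weight on corneal power.
#' @param intercept Intercept, diopters.
#' @param r_squared Optional R-squared of the calibration fit.
#' @return An object of class `ser_formula`.
#' @seealso [estimate_ser()], [fit_ser_formula()]
#' @export
ser_formula <- function(al_coefficient = 2.03, cc_coefficient = 0.94,
                        intercept = 88.58, r_squared = NULL) {
  stopifnot(is.numeric(al_coefficient), length(al_coefficient) == 1,
            al_coefficient >= 0,
            is.numeric(cc_coefficient), length(cc_coefficient) == 1,
            is.numeric(intercept), length(intercept) == 1)
  structure(list(al_coefficient = al_coefficient,
                 cc_coefficient = cc_coefficient,
                 intercept = intercept,
                 r_squared = r_squared),
            class = "ser_formula")
}

#' @export
print.ser_formula <- function(x, ...) {
  cat(sprintf("SER = -(AL x %.4g + %.4g x CC) + %.4g\n",
              x$al_coefficient, x$cc_coefficient, x$intercept))
  if (!is.null(x$r_squared)) cat(sprintf("  calibration R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Calculated spherical equivalent refraction from biometry
#'
#' Evaluates the SER formula on axial length and corneal curvature.
#' Negative results are myopic. The function is vectorized and affine in
#' its inputs; SER decreases by `al_coefficient` diopters per mm of axial
#' length at fixed corneal power.
#'
#' @param al_mm Axial length, millimetres. Plausible adult range (15, 35).
#' @param cc_d Corneal curvature, diopters (keratometry mean). Plausible
#'   range (35, 52).
#' @param formula A [ser_formula()]; defaults to the published calibration.
#' @param check How to treat out-of-range biometry: `"warn"` (default),
#'   `"error"`, or `"none"`.
#' @return Numeric vector of calculated SER, diopters.
#' @export
#' @examples
#' estimate_ser(24.0, 43.0)  # -0.56 D
estimate_ser <- function(al_mm, cc_d, formula = ser_formula(),
                         check = c("warn", "error", "none")) {
  check <- match.arg(check)
  stopifnot(inherits(formula, "ser_formula"))
  if (missing(al_mm) || missing(cc_d) || anyNA(al_mm) || anyNA(cc_d)) {
    stop("both 'al_mm' and 'cc_d' must be supplied with no missing values",
         call. = FALSE)
  }
  if (length(al_mm) != length(cc_d)) {
    stop("'al_mm' and 'cc_d' must have equal length", call. = FALSE)
  }
  if (check != "none") {
    out_al <- al_mm <= 15 | al_mm >= 35
    out_cc <- cc_d <= 35 | cc_d >= 52
    if (any(out_al | out_cc)) {
      msg <- sprintf("%d value(s) outside plausible biometry ranges (AL 15-35 mm, CC 35-52 D)",
                     sum(out_al | out_cc))
      if (check == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  -(al_mm * formula$al_coefficient + formula$cc_coefficient * cc_d) +
    formula$intercept
}

#' Derive an SER formula from calibration records
#'
#' Ordinary least-squares regression of observed SER on axial length and
#' corneal curvature, returned in the sign convention of [ser_formula()].
#' The published coefficients came from 373 calibration subjects; this
#' function re-derives a formula from any such table, fitting one record
#' per row.
#'
#' @param records Data frame with numeric columns `al_mm`, `cc_d` and
#'   `observed_ser_d` (at least 3 complete rows, non-collinear AL/CC).
#' @return A [ser_formula()] carrying the fit's `r_squared`.
#' @export
fit_ser_formula <- function(records) {
  need <- c("al_mm", "cc_d", "observed_ser_d")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records <- records[stats::complete.cases(records[, need]), ]
  if (nrow(records) < 3) stop("need at least 3 complete records", call. = FALSE)
  fit <- stats::lm(observed_ser_d ~ al_mm + cc_d, data = records)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("rank-deficient design: AL and CC are collinear", call. = FALSE)
  cf[abs(cf) < 1e-10] <- 0  # constant-response fits leave numeric dust
  ser_formula(al_coefficient = -cf[["al_mm"]],
              cc_coefficient = -cf[["cc_d"]],
              intercept = cf[["(Intercept)"]],
              r_squared = suppressWarnings(summary(fit)$r.squared))
}
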