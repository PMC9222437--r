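#' X-linked Hardy-Weinberg carrier probabilities
#'
#' For an X-linked allele at frequency q, hemizygous males carry it with
#' probability q, while females carry one copy with probability 2q(1-q)
#' and two copies with probability q^2 under Hardy-Weinberg proportions.
#' At the rs145009674-G frequency of 2.1%, this gives a 4.1% one-copy and
#' 0.044% two-copy chance for females.
#'
#' @param q Allele frequency in \[0, 1\].
#' @return An object of class `carrier_probs`: `q`, `male_carrier`,
#'   `female_one_copy`, `female_two_copies` (full precision; the print
#'   method displays 2 significant figures as percentages).
#' @export
#' @examples
#' x_linked_carrier_probs(0.021)
x_linked_carrier_probs <- function(q) {
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0 || q > 1) {
    stop("'q' must be a single allele frequency in [0, 1]", call. = FALSE)
  }
  structure(list(q = q,
                 male_carrier = q,
                 female_one_copy = 2 * q * (1 - q),
                 female_two_copies = q^2),
            class = "carrier_probs")
}

#' @export
print.carrier_probs <- function(x, ...) {
  cat(sprintf("X-linked carrier probabilities at allele frequency q = %g\n",
              x$q))
  cat(sprintf("  male hemizygous carrier: %s%%\n",
              signif(100 * x$male_carrier, 2)))
  cat(sprintf("  female, one copy:        %s%%\n",
              signif(100 * x$female_one_copy, 2)))
  cat(sprintf("  female, two copies:      %s%%\n",
              signif(100 * x$female_two_copies, 2)))
  invisible(x)
}

#' Attribution of myopia to a risk allele
#'
#' Given the number of allele carriers per 100 people, the penetrance
#' (the empirical proportion of carriers whose calculated SER is worse
#' than -0.75 D), and the number of myopes per 100 people, computes the
#' expected number of myopic carriers per 100 and the fraction of all
#' myopes they represent. With 2.07 carriers per 100, penetrance 0.82 and
#' 30 myopes per 100, about 1.7 carriers per 100 are myopic, i.e. about 6%
#' of myopes.
#'
#' @param carriers_per_100 Allele carriers per 100 people (>= 0).
#' @param penetrance Proportion of carriers who are myopic, in \[0, 1\].
#' @param myopes_per_100 Myopes per 100 people (> 0).
#' @return An object of class `attribution`: `carriers_per_100`,
#'   `penetrance`, `expected_myopic_carriers_per_100`,
#'   `fraction_of_myopes`.
#' @export
#' @examples
#' myope_attribution(2.07, 0.82, 30)
myope_attribution <- function(carriers_per_100, penetrance, myopes_per_100) {
  if (carriers_per_100 < 0 || penetrance < 0 || penetrance > 1) {
    stop("carriers_per_100 must be >= 0 and penetrance in [0, 1]",
         call. = FALSE)
  }
  if (!isTRUE(myopes_per_100 > 0)) {
    stop("myopes_per_100 must be positive", call. = FALSE)
  }
  expected <- carriers_per_100 * penetrance
  structure(list(carriers_per_100 = carriers_per_100,
                 penetrance = penetrance,
                 myopes_per_100 = myopes_per_100,
                 expected_myopic_carriers_per_100 = expected,
                 fraction_of_myopes = expected / myopes_per_100),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf(
    "%s carriers per 100 x penetrance %.2g -> %s expected myopic carriers\n",
    signif(x$carriers_per_100, 3), x$penetrance,
    signif(x$expected_myopic_carriers_per_100, 2)))
  cat(sprintf("  = %s%% of the %g myopes per 100\n",
              signif(100 * x$fraction_of_myopes, 2), x$myopes_per_100))
  invisible(x)
}
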