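#' Normal quantile for a two-sided confidence level
#'
#' @param level confidence level in (0, 1), e.g. 0.95.
#' @return the critical value: the customary 1.96 at the 95% level (the
#'   convention of the standard sample-size formulas, which write CIW/(2 x
#'   1.96)), and the exact (1 - (1 - level)/2) normal quantile otherwise.
#' @keywords internal
#' @noRd
z_level <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  if (abs(level - 0.95) < 1e-12) 1.96 else stats::qnorm(1 - (1 - level) / 2)
}

#' Convert a confidence-interval width to the implied standard error
#'
#' A two-sided normal (Wald) interval has width `2 * z * SE`, so a target
#' width translates to a target standard error of `ciw / (2 * z)`.
#'
#' @param ciw target confidence-interval width, in (0, 2) on the proportion
#'   scale.
#' @param level confidence level (default 0.95, for which the conventional
#'   critical value 1.96 is used; other levels use the exact normal
#'   quantile).
#' @return the implied standard error.
#' @export
#' @examples
#' ciw_to_se(0.1) # approx 0.0255
ciw_to_se <- function(ciw, level = 0.95) {
  stopifnot(is.numeric(ciw), all(ciw > 0))
  ciw / (2 * z_level(level))
}

#' @rdname ciw_to_se
#' @param se standard error to convert back to a width.
#' @export
se_to_ciw <- function(se, level = 0.95) {
  stopifnot(is.numeric(se), all(se >= 0))
  2 * z_level(level) * se
}

#' Wald confidence interval
#'
#' @param estimate point estimate.
#' @param se standard error.
#' @param level confidence level.
#' @return named numeric vector with `lower` and `upper`.
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  z <- z_level(level)
  c(lower = estimate - z * se, upper = estimate + z * se)
}

# logit / inverse logit; stats::qlogis and plogis are used directly where the
# intent is clear, these aliases keep formulas readable in the model code.
logit <- stats::qlogis
expit <- stats::plogis

#' Names of the six threshold-based performance measures
#' @keywords internal
#' @noRd
MEASURES <- c("accuracy", "specificity", "sensitivity", "ppv", "npv", "f1")

match_measure <- function(measure) {
  match.arg(measure, MEASURES)
}
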