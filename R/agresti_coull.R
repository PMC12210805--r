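#' Agresti-Coull adjusted interval for a proportion
#'
#' Adds two successes and two failures to the observed counts before
#' centring the normal interval: `prop_adj = (x + 2) / (n + 4)`, with
#' half-width `z * sqrt(prop_adj * (1 - prop_adj) / n)`. The default
#' variance denominator is `n`; `adjusted_denominator = TRUE` switches to
#' the textbook `n + 4` variant. Bounds are not truncated to \[0, 1\]
#' unless requested.
#'
#' @param x numerator (non-negative, possibly fractional expected count).
#' @param n denominator (positive, possibly fractional).
#' @param level confidence level (default 0.95).
#' @param adjusted_denominator use `n + 4` in the variance instead of `n`.
#' @param truncate clip the interval to \[0, 1\].
#' @return an object of class `adjusted_proportion`: list with `x`, `n`,
#'   `prop_adj`, `ci_low`, `ci_high`, `ciw`.
#' @export
#' @examples
#' ac_interval(50, 100) # 0.5 +/- 0.098
ac_interval <- function(x, n, level = 0.95,
                        adjusted_denominator = FALSE, truncate = FALSE) {
  stopifnot(is.numeric(x), is.numeric(n), n > 0, x >= 0)
  if (x > n) stop("numerator exceeds denominator.", call. = FALSE)
  prop_adj <- (x + 2) / (n + 4)
  den <- if (adjusted_denominator) n + 4 else n
  hw <- z_level(level) * sqrt(prop_adj * (1 - prop_adj) / den)
  lo <- prop_adj - hw
  hi <- prop_adj + hw
  if (truncate) {
    lo <- max(0, lo)
    hi <- min(1, hi)
  }
  structure(list(x = x, n = n, prop_adj = prop_adj,
                 ci_low = lo, ci_high = hi, ciw = hi - lo),
            class = "adjusted_proportion")
}

#' @export
print.adjusted_proportion <- function(x, ...) {
  cat(sprintf("adjusted proportion %.4f (%.4f, %.4f); width %.4f\n",
              x$prop_adj, x$ci_low, x$ci_high, x$ciw))
  invisible(x)
}

#' Iterative sample size targeting an Agresti-Coull interval width
#'
#' No closed form exists for the adjusted interval, so the minimum N is
#' found by search: at each candidate N the expected measure denominator is
#' `N * denominator_fraction(measure, profile)` and the expected numerator
#' is the anticipated measure value times that denominator (real-valued;
#' rounding expected counts to integers would induce spurious
#' non-monotonicity in the width). The returned N is the smallest whose
#' expected Agresti-Coull width meets the target; the width is strictly
#' decreasing in N so bisection and the scan agree.
#'
#' @param measure one of the five proportion measures.
#' @param profile a [perf_profile()].
#' @param target a [precision_target()] (interpreted as a width target;
#'   an `se` target is converted to a width `2 z SE`).
#' @param n_max search bound (default 1,000,000).
#' @param adjusted_denominator passed to [ac_interval()].
#' @param search `"bisect"` (default) or `"scan"`.
#' @return a [samplesize_result()]; the achieved width is recorded in
#'   `assumptions$ciw_at_n`.
#' @export
#' @examples
#' prof <- perf_profile(0.1, phi = 0.432, sensitivity = 0.988,
#'                      specificity = 0.147)
#' n_measure_ac("accuracy", prof, precision_target("acc", ciw = 0.1))
n_measure_ac <- function(measure, profile, target, n_max = 1e6,
                         adjusted_denominator = FALSE,
                         search = c("bisect", "scan")) {
  measure <- match.arg(measure, setdiff(MEASURES, "f1"))
  stopifnot(inherits(profile, "perf_profile"),
            inherits(target, "precision_target"))
  search <- match.arg(search)
  value <- profile[[measure]]
  frac <- denominator_fraction(measure, profile)
  target_ciw <- if (!is.na(target$ciw)) target$ciw
                else se_to_ciw(target$se, target$level)
  width <- function(N) {
    n <- N * frac
    ac_interval(value * n, n, level = target$level,
                adjusted_denominator = adjusted_denominator)$ciw
  }
  if (width(n_max) > target_ciw) {
    stop(sprintf(paste0("target CI width %.5g for %s not achievable by ",
                        "N = %d (width at n_max: %.5g)."),
                 target_ciw, measure, as.integer(n_max), width(n_max)),
         call. = FALSE)
  }
  if (search == "scan") {
    n <- 1L
    while (width(n) > target_ciw) n <- n + 1L
  } else {
    lo <- 1L; hi <- as.integer(n_max)
    if (width(lo) <= target_ciw) {
      n <- lo
    } else {
      while (hi - lo > 1L) {
        mid <- (lo + hi) %/% 2L
        if (width(mid) <= target_ciw) hi <- mid else lo <- mid
      }
      n <- hi
    }
  }
  samplesize_result(measure, n, profile$phi, target,
                    assumptions = list(value = value,
                                       denominator_fraction = frac,
                                       interval = "agresti_coull",
                                       ciw_at_n = width(n)))
}
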