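#' Sample size for a precise observed/expected ratio
#'
#' Criterion: `N = (1 - phi) / (phi * SE(ln(O/E))^2)`. A target
#' confidence-interval width on the O/E scale is converted to a target
#' standard error of `ln(O/E)` under the planning assumption that the model
#' is calibrated in the large (anticipated O/E = 1): the interval
#' `exp(±z * SE)` then has width `exp(z*SE) - exp(-z*SE)`, so
#' `SE = asinh(CIW / 2) / z`.
#'
#' @param phi anticipated outcome prevalence in (0, 1).
#' @param target a [precision_target()]; a `ciw` is interpreted on the O/E
#'   scale (assuming O/E = 1), an `se` directly as `SE(ln(O/E))`.
#' @return a [samplesize_result()].
#' @export
#' @examples
#' n_oe(0.43, precision_target("oe", ciw = 0.22)) # N = 423
n_oe <- function(phi, target) {
  stopifnot(phi > 0, phi < 1, inherits(target, "precision_target"))
  se <- if (!is.na(target$ciw)) {
    asinh(target$ciw / 2) / z_level(target$level)
  } else {
    target$se
  }
  n_real <- (1 - phi) / (phi * se^2)
  samplesize_result("oe", n_real, phi, target,
                    assumptions = list(se_ln_oe = se))
}

#' Fisher information elements for the calibration slope
#'
#' For a logistic recalibration model `logit P(Y=1) = alpha + beta * LP`,
#' the per-individual information contributions are
#' `a_i = e / (1+e)^2`, `b_i = LP_i * e / (1+e)^2`,
#' `c_i = LP_i^2 * e / (1+e)^2` with `e = exp(alpha + beta * LP_i)`; the
#' information elements are their sample means over the anticipated
#' linear-predictor distribution. Defaults `alpha = 0`, `beta = 1` encode
#' the well-calibrated planning assumption.
#'
#' @param lp numeric vector of linear predictors (log-odds scale).
#' @param alpha,beta assumed calibration intercept and slope.
#' @return an object of class `calibration_information`: list with
#'   `I_alpha`, `I_alpha_beta`, `I_beta`.
#' @export
#' @examples
#' fisher_information(rep(0, 5)) # I_alpha = 0.25
fisher_information <- function(lp, alpha = 0, beta = 1) {
  stopifnot(is.numeric(lp), length(lp) > 0, all(is.finite(lp)))
  w <- stats::dlogis(alpha + beta * lp) # exp(x)/(1+exp(x))^2, overflow-safe
  structure(list(I_alpha = mean(w),
                 I_alpha_beta = mean(lp * w),
                 I_beta = mean(lp^2 * w)),
            class = "calibration_information")
}

#' @export
print.calibration_information <- function(x, ...) {
  cat(sprintf("I_alpha = %.6g, I_alpha_beta = %.6g, I_beta = %.6g\n",
              x$I_alpha, x$I_alpha_beta, x$I_beta))
  invisible(x)
}

#' Sample size for a precise calibration slope
#'
#' Criterion: `N = I_alpha / (SE(beta)^2 * (I_alpha * I_beta -
#' I_alpha_beta^2))`, with the information elements from
#' [fisher_information()].
#'
#' @param info a `calibration_information` object.
#' @param target a [precision_target()] for the slope (a `ciw` converts as
#'   `SE = CIW / (2z)`).
#' @param phi prevalence used only to report the event count.
#' @return a [samplesize_result()].
#' @export
n_calibration_slope <- function(info, target, phi) {
  stopifnot(inherits(info, "calibration_information"),
            inherits(target, "precision_target"), phi > 0, phi < 1)
  det <- info$I_alpha * info$I_beta - info$I_alpha_beta^2
  # a constant LP gives a determinant that is zero only up to rounding
  if (det <= 1e-8 * info$I_alpha * info$I_beta || info$I_beta == 0) {
    stop("Fisher information is not positive definite; the linear-predictor ",
         "distribution is degenerate.", call. = FALSE)
  }
  n_real <- info$I_alpha / (target$se^2 * det)
  samplesize_result("calibration_slope", n_real, phi, target,
                    assumptions = unclass(info))
}

#' Newcombe standard error of the c-statistic
#'
#' Distribution-free approximation to the standard error of the c-statistic
#' (area under the ROC curve) at sample size `N` and prevalence `phi`:
#' \deqn{SE(C) = \sqrt{\frac{C(1-C)\left[1 + (\frac{N}{2}-1)\frac{1-C}{2-C}
#'   + \frac{(\frac{N}{2}-1)C}{1+C}\right]}{N^2 \phi (1-\phi)}}.}
#'
#' @param C anticipated c-statistic in (0, 1).
#' @param N sample size (vectorised).
#' @param phi prevalence in (0, 1).
#' @return standard error(s).
#' @export
se_cstatistic <- function(C, N, phi) {
  stopifnot(C > 0, C < 1, phi > 0, phi < 1, all(N >= 2))
  num <- C * (1 - C) *
    (1 + (N / 2 - 1) * ((1 - C) / (2 - C)) + ((N / 2 - 1) * C) / (1 + C))
  sqrt(num / (N^2 * phi * (1 - phi)))
}

#' Sample size for a precise c-statistic
#'
#' Iterates [se_cstatistic()] to find the smallest N whose standard error
#' meets the target. `SE(C)` is strictly decreasing in N, so bisection and
#' the linear scan agree; both are provided.
#'
#' @param C anticipated c-statistic.
#' @param phi prevalence in (0, 1).
#' @param target a [precision_target()].
#' @param n_max search bound (default 1,000,000).
#' @param search `"scan"` or `"bisect"`.
#' @return a [samplesize_result()].
#' @export
#' @examples
#' n_cstatistic(0.77, 0.43, precision_target("c", ciw = 0.1)) # N = 347
n_cstatistic <- function(C, phi, target, n_max = 1e6,
                         search = c("scan", "bisect")) {
  stopifnot(inherits(target, "precision_target"))
  if (C <= 0 || C >= 1) {
    stop("the Newcombe expression degenerates at C = 0 or 1.", call. = FALSE)
  }
  search <- match.arg(search)
  f <- function(N) se_cstatistic(C, N, phi)
  if (f(n_max) > target$se) {
    stop(sprintf("target SE %.5g for the c-statistic not achievable by N = %d.",
                 target$se, as.integer(n_max)), call. = FALSE)
  }
  if (search == "scan") {
    n <- which(f(2:n_max) <= target$se)[1] + 1L
  } else {
    lo <- 2L; hi <- as.integer(n_max)
    if (f(lo) <= target$se) {
      n <- lo
    } else {
      while (hi - lo > 1L) {
        mid <- (lo + hi) %/% 2L
        if (f(mid) <= target$se) hi <- mid else lo <- mid
      }
      n <- hi
    }
  }
  samplesize_result("c_statistic", n, phi, target,
                    assumptions = list(C = C, se_at_n = f(n)))
}

#' Sample size for a precise standardised net benefit
#'
#' At a clinically chosen probability threshold `p`, with
#' `w = ((1 - phi)/phi) * (p/(1 - p))`:
#' \deqn{N = \frac{1}{SE(sNB)^2}\left[\frac{sens(1-sens)}{\phi}
#'   + \frac{w^2 spec(1-spec)}{1-\phi}
#'   + \frac{w^2 (1-spec)^2}{\phi(1-\phi)}\right].}
#' Sensitivity and specificity are taken from the supplied profile at that
#' threshold; the implied `sNB = sens - w * (1 - spec)` and the net benefit
#' `NB = phi * sNB` are recorded in the assumptions for reporting.
#'
#' @param profile a [perf_profile()] at threshold `p`.
#' @param p probability threshold in (0, 1).
#' @param target a [precision_target()] for sNB.
#' @return a [samplesize_result()].
#' @export
n_snb <- function(profile, p, target) {
  stopifnot(inherits(profile, "perf_profile"),
            inherits(target, "precision_target"), p > 0, p < 1)
  phi <- profile$phi
  if (phi <= 0 || phi >= 1) {
    stop("sNB sample size undefined at prevalence 0 or 1.", call. = FALSE)
  }
  sens <- profile$sensitivity; spec <- profile$specificity
  w <- ((1 - phi) / phi) * (p / (1 - p))
  n_real <- (1 / target$se^2) *
    (sens * (1 - sens) / phi +
       w^2 * spec * (1 - spec) / (1 - phi) +
       w^2 * (1 - spec)^2 / (phi * (1 - phi)))
  snb <- sens - w * (1 - spec)
  samplesize_result("snb", n_real, phi, target,
                    assumptions = list(threshold = p, w = w,
                                       sensitivity = sens,
                                       specificity = spec,
                                       snb = snb, nb = phi * snb))
}
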