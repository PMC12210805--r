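#' Standard error of a proportion-type performance measure
#'
#' Accuracy, specificity, sensitivity, PPV and NPV are all proportions
#' `X / n`, so their large-sample standard error is
#' `sqrt(value * (1 - value) / n)` with `n` the measure-specific
#' denominator: `N` for accuracy, `TN + FP` for specificity, `TP + FN` for
#' sensitivity, `TP + FP` for PPV and `TN + FN` for NPV.
#'
#' @param value the proportion, in \[0, 1\].
#' @param denominator the measure-specific denominator, positive.
#' @return the standard error (0 at value 0 or 1).
#' @export
#' @examples
#' se_proportion(0.5, 100) # 0.05
se_proportion <- function(value, denominator) {
  stopifnot(all(value >= 0), all(value <= 1), all(denominator > 0))
  sqrt(value * (1 - value) / denominator)
}

#' Expected fraction of the sample in a measure's denominator
#'
#' For a population with performance profile at a threshold, the expected
#' measure denominator is this fraction times the total sample size N:
#' 1 for accuracy, `1 - phi` for specificity, `phi` for sensitivity,
#' `phi * sens / ppv` (the predicted-positive fraction) for PPV and
#' `spec * (1 - phi) + phi * (1 - sens)` (the predicted-negative fraction)
#' for NPV.
#'
#' @param measure one of `"accuracy"`, `"specificity"`, `"sensitivity"`,
#'   `"ppv"`, `"npv"`.
#' @param profile a [perf_profile()].
#' @return fraction in (0, 1\].
#' @export
denominator_fraction <- function(measure, profile) {
  stopifnot(inherits(profile, "perf_profile"))
  measure <- match.arg(measure, setdiff(MEASURES, "f1"))
  phi <- profile$phi
  switch(measure,
    accuracy = 1,
    specificity = 1 - phi,
    sensitivity = phi,
    ppv = phi * profile$sensitivity / profile$ppv,
    npv = profile$specificity * (1 - phi) + phi * (1 - profile$sensitivity))
}

#' Covariance of precision and recall
#'
#' Precision (PPV) and recall (sensitivity) are positively correlated
#' through their shared numerator TP. The covariance convention used by the
#' F1 sample-size procedure admits two equivalent forms — a cell-count form
#' and a closed form in the measure values — which agree on any valid
#' matrix. The closed form is
#' \deqn{cov(P, R) = \frac{P(1-P)(1-R)/\phi + P(1-P)\,spec/(1-\phi)}{N}.}
#'
#' Note that under simple multinomial sampling of the four cells the exact
#' large-sample (delta-method) covariance is the first term alone,
#' `P(1-P)(1-R)/(phi*N)`; the two-term convention is therefore conservative
#' — it never understates the F1 standard error (see the methods vignette).
#'
#' @param P precision (PPV) in (0, 1).
#' @param R recall (sensitivity) in (0, 1).
#' @param specificity specificity in (0, 1).
#' @param phi prevalence in (0, 1).
#' @param N total sample size, positive.
#' @return the covariance.
#' @export
#' @examples
#' cov_precision_recall(0.6, 0.75, 2 / 3, 0.4, 100)
cov_precision_recall <- function(P, R, specificity, phi, N) {
  stopifnot(P > 0, P < 1, R > 0, R < 1,
            specificity >= 0, specificity <= 1, N > 0)
  if (phi <= 0 || phi >= 1) {
    stop("covariance undefined for prevalence 0 or 1.", call. = FALSE)
  }
  (P * (1 - P) * (1 - R) / phi + P * (1 - P) * specificity / (1 - phi)) / N
}

#' @rdname cov_precision_recall
#' @param cm a [confusion_matrix()]; the cell-count form
#'   `FP*TP*FN / ((TP+FP)^2 (TP+FN)^2) + FP*TP*TN / ((TP+FP)^2 (TN+FP)^2)`.
#' @export
cov_precision_recall_cells <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  with(cm, {
    fp * tp * fn / ((tp + fp)^2 * (tp + fn)^2) +
      fp * tp * tn / ((tp + fp)^2 * (tn + fp)^2)
  })
}

#' Standard error of the F1-score
#'
#' Delta-method standard error of the F1-score (harmonic mean of precision
#' and recall), adapted from the variance of a macro-averaged F1 to the
#' binary case:
#' \deqn{SE_{F1} = \sqrt{4 \, \frac{R^4 SE_P^2 + 2 P^2 R^2 cov(P,R)
#'   + P^4 SE_R^2}{(P+R)^4}}.}
#' `SE_P` and `SE_R` are evaluated internally at sample size `N` via the
#' proportion formula with denominators `N * phi * R / P` (predicted
#' positives) and `N * phi` (actual positives) respectively, and the
#' covariance via [cov_precision_recall()]. Scales as `1/sqrt(N)`.
#'
#' @inheritParams cov_precision_recall
#' @return the standard error.
#' @export
se_f1 <- function(P, R, specificity, phi, N) {
  stopifnot(P > 0, P <= 1, R > 0, R <= 1)
  if (P + R == 0) stop("SE of F1 undefined when P + R = 0.", call. = FALSE)
  se_p2 <- P * (1 - P) / (N * phi * R / P)
  se_r2 <- R * (1 - R) / (N * phi)
  cv <- if (P < 1 && R < 1) cov_precision_recall(P, R, specificity, phi, N)
        else 0
  sqrt(4 * (R^4 * se_p2 + 2 * P^2 * R^2 * cv + P^4 * se_r2) / (P + R)^4)
}

#' @rdname se_f1
#' @param cm a [confusion_matrix()]; evaluates the same expression with
#'   `SE_P`, `SE_R` and the covariance taken from the observed cells.
#' @export
se_f1_from_matrix <- function(cm) {
  m <- measures_from_matrix(cm)
  P <- m[["ppv"]]; R <- m[["sensitivity"]]
  if (is.na(P) || is.na(R) || P + R == 0) return(NA_real_)
  se_p2 <- P * (1 - P) / (cm$tp + cm$fp)
  se_r2 <- R * (1 - R) / (cm$tp + cm$fn)
  cv <- cov_precision_recall_cells(cm)
  sqrt(4 * (R^4 * se_p2 + 2 * P^2 * R^2 * cv + P^4 * se_r2) / (P + R)^4)
}
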