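#' Confusion matrix at a probability threshold
#'
#' Cell counts of the 2x2 classification table. Counts are integers for
#' observed binary data but fractional values are permitted: the
#' time-to-event extension aggregates jackknife pseudo-values into expected
#' cell counts, and the iterative sample-size searches evaluate expected
#' (real-valued) cells at candidate sample sizes.
#'
#' @param tp,fp,tn,fn cell values; each must be non-negative (pseudo-value
#'   matrices may carry small negative cells when pseudo-values fall outside
#'   \[0, 1\]; set `allow_negative = TRUE` for those).
#' @param allow_negative permit (slightly) negative cells from pseudo-value
#'   aggregation.
#' @return an object of class `confusion_matrix`.
#' @export
#' @examples
#' cm <- confusion_matrix(tp = 30, fp = 20, tn = 40, fn = 10)
#' prevalence(cm) # 0.4
confusion_matrix <- function(tp, fp, tn, fn, allow_negative = FALSE) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(is.numeric(cells), length(cells) == 4L, all(is.finite(cells)))
  if (!allow_negative && any(cells < 0)) {
    stop("confusion-matrix cells must be non-negative.", call. = FALSE)
  }
  n <- sum(cells)
  if (n <= 0) stop("confusion matrix must have positive total.", call. = FALSE)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = n),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(c("Prob > t", "Prob <= t"),
                              c("Outcome", "No outcome")))
  cat(sprintf("Confusion matrix (N = %g, prevalence = %.4g)\n",
              x$n, prevalence(x)))
  print(m)
  invisible(x)
}

#' Outcome proportion of a confusion matrix
#'
#' The outcome proportion (prevalence) is `(TP + FN) / N`.
#'
#' @param cm a [confusion_matrix()].
#' @return prevalence in \[0, 1\].
#' @export
prevalence <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  (cm$tp + cm$fn) / cm$n
}

#' Point estimates of the six performance measures from a confusion matrix
#'
#' Computes accuracy `(TP+TN)/N`, specificity `TN/(TN+FP)`, sensitivity
#' `TP/(TP+FN)`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)` and the F1-score
#' `2 / (1/PPV + 1/sensitivity)`. A measure whose denominator is zero is
#' returned as `NA` (undefined) rather than zero, so that the absence of,
#' say, any predicted positives is distinguishable from zero performance.
#' The F1-score is 0 when `TP = 0` with some positives present, and `NA`
#' when both PPV and sensitivity are undefined.
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector over the six measures; undefined entries
#'   are `NA`.
#' @export
#' @examples
#' measures_from_matrix(confusion_matrix(40, 10, 40, 10)) # all 0.8
measures_from_matrix <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(cm$tp, cm$tp + cm$fn)
  spec <- ratio(cm$tn, cm$tn + cm$fp)
  ppv <- ratio(cm$tp, cm$tp + cm$fp)
  npv <- ratio(cm$tn, cm$tn + cm$fn)
  f1 <- if (is.na(ppv) || is.na(sens)) {
    NA_real_
  } else if (ppv + sens == 0) {
    0
  } else {
    2 * ppv * sens / (ppv + sens)
  }
  c(accuracy = ratio(cm$tp + cm$tn, cm$n),
    specificity = spec, sensitivity = sens, ppv = ppv, npv = npv, f1 = f1)
}

#' Read or write a confusion matrix as CSV
#'
#' The layout mirrors the conventional 2x2 table: rows `Prob > t` and
#' `Prob <= t`, columns `Outcome` and `No outcome`.
#'
#' @param cm a [confusion_matrix()].
#' @param path file path.
#' @return `read_confusion_csv()` returns a [confusion_matrix()].
#' @export
write_confusion_csv <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  df <- data.frame(row = c("Prob > t", "Prob <= t"),
                   Outcome = c(cm$tp, cm$fn),
                   No.outcome = c(cm$fp, cm$tn))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) != 2L || ncol(df) < 3L) {
    stop("expected a 2-row, 3-column confusion-matrix CSV.", call. = FALSE)
  }
  confusion_matrix(tp = df[1, 2], fp = df[1, 3], fn = df[2, 2], tn = df[2, 3],
                   allow_negative = TRUE)
}
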