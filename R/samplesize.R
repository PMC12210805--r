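#' Precision target for one performance measure
#'
#' Either a target confidence-interval width or a target standard error,
#' with a confidence level. A width is converted internally to
#' `SE = CIW / (2 * z)`.
#'
#' @param measure measure or criterion name the target applies to.
#' @param ciw target confidence-interval width in (0, 2); exactly one of
#'   `ciw`/`se` must be given.
#' @param se target standard error, positive.
#' @param level confidence level (default 0.95).
#' @return an object of class `precision_target` with elements `measure`,
#'   `ciw` (possibly `NA`), `se`, `level`.
#' @export
#' @examples
#' precision_target("npv", ciw = 0.1)
precision_target <- function(measure, ciw = NULL, se = NULL, level = 0.95) {
  if (is.null(ciw) == is.null(se)) {
    stop("supply exactly one of `ciw` or `se`.", call. = FALSE)
  }
  if (!is.null(ciw)) {
    stopifnot(is.numeric(ciw), length(ciw) == 1L, ciw > 0, ciw < 2)
    se <- ciw_to_se(ciw, level)
  } else {
    stopifnot(is.numeric(se), length(se) == 1L, se > 0)
    ciw <- NA_real_
  }
  structure(list(measure = measure, ciw = ciw, se = se, level = level),
            class = "precision_target")
}

#' Minimum-sample-size result for one criterion
#'
#' @param criterion name of the measure or criterion.
#' @param n_required minimum total participants (already rounded up).
#' @param phi prevalence used to derive the event count.
#' @param target the [precision_target()] used.
#' @param assumptions named list snapshot of the inputs (profile values
#'   etc.) for auditability.
#' @return an object of class `samplesize_result` with `criterion`,
#'   `n_required`, `events_required = ceiling(n_required * phi)`, `target`,
#'   `assumptions`.
#' @export
samplesize_result <- function(criterion, n_required, phi, target,
                              assumptions = list()) {
  stopifnot(is.numeric(n_required), length(n_required) == 1L, n_required >= 1)
  n <- as.integer(ceiling(n_required - 1e-9))
  structure(list(criterion = criterion,
                 n_required = n,
                 events_required = as.integer(ceiling(n * phi)),
                 phi = phi,
                 target = target,
                 assumptions = assumptions),
            class = "samplesize_result")
}

#' @export
print.samplesize_result <- function(x, ...) {
  tgt <- if (!is.na(x$target$ciw)) {
    sprintf("%g%% CI width %g", 100 * x$target$level, x$target$ciw)
  } else {
    sprintf("SE %g", x$target$se)
  }
  cat(sprintf("%s: N = %d (%d events) to target %s\n",
              x$criterion, x$n_required, x$events_required, tgt))
  invisible(x)
}

#' @export
format.samplesize_result <- function(x, ...) {
  sprintf("%d (%d)", x$n_required, x$events_required)
}

#' Closed-form minimum sample size for a proportion-type measure
#'
#' Inverts the Wald standard error of the measure at its anticipated true
#' value: `N = value * (1 - value) / (SE^2 * denominator fraction)`, where
#' the denominator fraction is given by [denominator_fraction()]. For PPV
#' this is algebraically the printed form
#' `PPV^2 (1 - PPV) / (SE^2 * phi * sensitivity)`. The result is rounded up
#' ("minimum required" semantics); events are `ceiling(N * phi)`.
#'
#' @param measure one of the five proportion measures.
#' @param profile a [perf_profile()] carrying the anticipated true values.
#' @param target a [precision_target()].
#' @return a [samplesize_result()].
#' @export
#' @examples
#' prof <- perf_profile(0.1, phi = 0.43, sensitivity = 0.988,
#'                      specificity = 0.147)
#' n_threshold_measure("sensitivity", prof, precision_target("sens", ciw = 0.1))
n_threshold_measure <- function(measure, profile, target) {
  measure <- match.arg(measure, setdiff(MEASURES, "f1"))
  stopifnot(inherits(profile, "perf_profile"),
            inherits(target, "precision_target"))
  value <- profile[[measure]]
  if (is.na(value)) {
    stop("anticipated value for ", measure, " is undefined in this profile.",
         call. = FALSE)
  }
  if (value <= 0 || value >= 1) {
    stop("the Wald-based closed form degenerates at a measure value of ",
         "exactly 0 or 1; consider the Agresti-Coull search ",
         "(n_measure_ac()).", call. = FALSE)
  }
  frac <- denominator_fraction(measure, profile)
  n_real <- value * (1 - value) / (target$se^2 * frac)
  samplesize_result(measure, n_real, profile$phi, target,
                    assumptions = list(value = value,
                                       denominator_fraction = frac,
                                       threshold = profile$threshold))
}

#' Iterative minimum sample size for the F1-score
#'
#' The F1 standard error depends on the standard errors of precision and
#' recall at the candidate sample size, so no closed form exists in terms of
#' a pre-specified target alone; the minimum N is the smallest sample size
#' whose implied [se_f1()] meets the target. `SE_F1` is strictly decreasing
#' in N (every variance term is proportional to 1/N), so a bisection search
#' returns the same answer as the linear scan; both are provided and the
#' linear scan is the default reference behaviour.
#'
#' @param profile a [perf_profile()] with ppv (precision), sensitivity
#'   (recall), specificity and prevalence all strictly inside (0, 1).
#' @param target a [precision_target()].
#' @param n_max largest sample size considered (default 100,000).
#' @param search `"scan"` or `"bisect"`.
#' @return a [samplesize_result()]; the achieved `se_f1` at the returned N
#'   is recorded in `assumptions$se_at_n`.
#' @export
n_f1 <- function(profile, target, n_max = 1e5, search = c("scan", "bisect")) {
  stopifnot(inherits(profile, "perf_profile"),
            inherits(target, "precision_target"))
  search <- match.arg(search)
  P <- profile$ppv; R <- profile$sensitivity
  spec <- profile$specificity; phi <- profile$phi
  if (any(is.na(c(P, R))) || P <= 0 || P >= 1 || R <= 0 || R >= 1 ||
      spec <= 0 || spec >= 1 || phi <= 0 || phi >= 1) {
    stop("n_f1() requires precision, recall, specificity and prevalence ",
         "strictly inside (0, 1).", call. = FALSE)
  }
  f <- function(N) se_f1(P, R, spec, phi, N)
  if (f(n_max) > target$se) {
    stop(sprintf(paste0("target SE %.5g for the F1-score is not achievable ",
                        "by N = %d (SE at n_max: %.5g)."),
                 target$se, as.integer(n_max), f(n_max)), call. = FALSE)
  }
  if (search == "scan") {
    n <- which(f(seq_len(n_max)) <= target$se)[1]
  } else {
    lo <- 1L; hi <- as.integer(n_max)
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
  samplesize_result("f1", n, phi, target,
                    assumptions = list(ppv = P, sensitivity = R,
                                       specificity = spec,
                                       threshold = profile$threshold,
                                       se_at_n = f(n)))
}

#' Binding criterion across a set of sample-size results
#'
#' The overall minimum required sample size is the maximum over criteria.
#' Ties are broken deterministically by criterion-name order.
#'
#' @param results non-empty list of [samplesize_result()] objects.
#' @return the binding [samplesize_result()].
#' @export
binding_criterion <- function(results) {
  if (length(results) == 0L) {
    stop("binding_criterion() needs at least one result.", call. = FALSE)
  }
  stopifnot(all(vapply(results, inherits, logical(1), "samplesize_result")))
  ns <- vapply(results, `[[`, numeric(1), "n_required")
  nms <- vapply(results, `[[`, character(1), "criterion")
  idx <- which(ns == max(ns))
  results[[idx[order(nms[idx])[1]]]]
}
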