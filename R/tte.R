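#' Predicted absolute risk at a time horizon
#'
#' For a proportional-hazards model with baseline survival `S0(t)` at the
#' horizon, an individual's event probability by the horizon is
#' `1 - S0(t)^exp(LP)`.
#'
#' @param baseline_survival baseline survival probability at the horizon,
#'   in (0, 1\].
#' @param lp linear predictor(s).
#' @return predicted risk(s) in \[0, 1).
#' @export
#' @examples
#' risk_at_horizon(0.9, log(2)) # 1 - 0.9^2 = 0.19
risk_at_horizon <- function(baseline_survival, lp) {
  stopifnot(baseline_survival > 0, baseline_survival <= 1, is.numeric(lp))
  1 - baseline_survival^exp(lp)
}

#' Kaplan-Meier cumulative incidence at a horizon
#'
#' Product-limit estimate of `F(t*) = 1 - S(t*)`, right-continuous, with
#' events preceding censorings at tied times (the standard risk-set
#' convention). Computed via [survival::survfit()].
#'
#' @param time follow-up times (positive).
#' @param event event indicators (1 = event, 0 = censored).
#' @param horizon time horizon `t*`.
#' @return cumulative incidence in \[0, 1\].
#' @export
#' @examples
#' km_cuminc(c(1, 2, 3, 4), c(1, 1, 0, 1), 3) # 0.5
km_cuminc <- function(time, event, horizon) {
  stopifnot(length(time) == length(event), all(time > 0), horizon > 0,
            all(event %in% c(0, 1)))
  if (!any(event == 1 & time <= horizon)) {
    warning("no events observed by the horizon; cumulative incidence is 0.")
    return(0)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, times = horizon, extend = TRUE)$surv
  1 - s
}

#' Jackknife pseudo-observations of the cumulative incidence
#'
#' Per-individual pseudo-values
#' `N * F_KM(t*) - (N - 1) * F_KM(-i)(t*)`, where `F_KM(-i)` is the
#' Kaplan-Meier cumulative incidence recomputed without individual `i`.
#' Without censoring before the horizon the pseudo-value reduces exactly to
#' the event indicator `1(time_i <= t*, event)`; under censoring values may
#' fall outside \[0, 1\]. The jackknife identity
#' `mean(values) = F_KM(t*)` holds on any sample.
#'
#' Two computation paths are available: `"jackknife"` recomputes the
#' estimator `N` times (O(N^2), transparent, used as the oracle in the test
#' suite) and `"fast"` obtains all leave-one-out estimates in a single pass
#' from prefix sums of the log survival factors (O(N log N)); they agree to
#' numerical tolerance. `"auto"` uses the fast path above 500 individuals.
#'
#' @param time follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param horizon time horizon `t*`.
#' @param method `"auto"`, `"fast"` or `"jackknife"`.
#' @return an object of class `pseudo_value_set`: list with `horizon`,
#'   `values` (one per individual) and `km_cuminc`.
#' @export
pseudo_values <- function(time, event, horizon,
                          method = c("auto", "fast", "jackknife")) {
  method <- match.arg(method)
  n <- length(time)
  if (n < 2L) stop("pseudo-values need at least 2 individuals.", call. = FALSE)
  stopifnot(length(event) == n, all(time > 0), all(event %in% c(0, 1)))
  if (method == "auto") method <- if (n > 500L) "fast" else "jackknife"
  f_full <- suppressWarnings(km_cuminc(time, event, horizon))
  vals <- if (method == "fast") {
    pseudo_fast(time, event, horizon, f_full)
  } else {
    f_loo <- vapply(seq_len(n), function(i) {
      suppressWarnings(km_cuminc(time[-i], event[-i], horizon))
    }, numeric(1))
    n * f_full - (n - 1) * f_loo
  }
  structure(list(horizon = horizon, values = vals, km_cuminc = f_full),
            class = "pseudo_value_set")
}

#' @export
print.pseudo_value_set <- function(x, ...) {
  cat(sprintf("pseudo-values at t* = %g: n = %d, F_KM = %.4f, range [%.3f, %.3f]\n",
              x$horizon, length(x$values), x$km_cuminc,
              min(x$values), max(x$values)))
  invisible(x)
}

# Single-pass leave-one-out Kaplan-Meier via prefix sums.
#
# At each distinct event time t_j let d_j be the events and n_j the risk-set
# size. Removing individual i shrinks n_j by one at every event time
# t_j <= time_i (i is at risk there, whatever their status), and d_j by one
# at i's own event time. So
#   log S_{-i}(t*) = sum_{t_j <= min(t*, time_i)} log(1 - d_j/(n_j - 1))
#                  + sum_{time_i < t_j <= t*}      log(1 - d_j/n_j)
# with the first sum's term at i's own event time using d_j - 1. Both sums
# come from two prefix-sum vectors; the own-event term is patched per
# subject. Degenerate factors (risk set emptied by the removal) contribute
# nothing; a factor hitting zero drives S to 0 as it should.
pseudo_fast <- function(time, event, horizon, f_full) {
  n <- length(time)
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) return(rep(0, n)) # no events anywhere
  d <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  r <- vapply(et, function(t) sum(time >= t), numeric(1))
  log_keep <- log1p(-d / r)            # factor when i not at risk
  log_drop <- numeric(length(et))      # i at risk, not their event
  log_drop[r > 1] <- log1p(-d[r > 1] / (r[r > 1] - 1))
  # prefix sums; -Inf (S hits zero) propagates correctly through cumsum
  A <- c(0, cumsum(log_keep))
  B <- c(0, cumsum(log_drop))
  K <- findInterval(horizon, et)
  m <- findInterval(pmin(time, horizon), et)
  log_s_loo <- B[m + 1] + (A[K + 1] - A[m + 1])
  # patch subjects whose own event time is within the horizon
  own <- which(event == 1 & time <= horizon)
  if (length(own)) {
    j <- match(time[own], et)
    dd <- d[j]; rr <- r[j]
    new_term <- numeric(length(j))
    new_term[rr > 1] <- log1p(-(dd[rr > 1] - 1) / (rr[rr > 1] - 1))
    log_s_loo[own] <- log_s_loo[own] - log_drop[j] + new_term
    # removing the -Inf factor of a fully-depleted risk set needs explicit
    # recomputation; only possible when d_j = r_j - 1 interacts with i's own
    # event, handled by the NaN fallback below
  }
  f_loo <- 1 - exp(log_s_loo)
  bad <- which(is.na(log_s_loo)) # NaN from -Inf arithmetic: recompute directly
  if (length(bad)) {
    for (i in bad) {
      f_loo[i] <- suppressWarnings(km_cuminc(time[-i], event[-i], horizon))
    }
  }
  n * f_full - (n - 1) * f_loo
}

#' Pseudo-value confusion matrix
#'
#' Aggregates pseudo-observed event probabilities into expected cell counts
#' of the 2x2 table at a probability threshold: over predicted-positive
#' individuals, TP is the sum of pseudo-values and FP the sum of their
#' complements `1 - pseudo`; FN and TN analogously over predicted-negatives.
#' When the pseudo-values are exactly 0/1 (no censoring) this reduces to
#' the ordinary integer confusion matrix, and the outcome proportion
#' `(TP + FN)/N` equals the mean pseudo-value, i.e. the Kaplan-Meier
#' cumulative incidence. Pseudo-values outside \[0, 1\] are not clipped, so
#' individual cells may be pushed slightly negative; downstream measure
#' estimates remain defined.
#'
#' @param predicted_risk predicted event probabilities by the horizon.
#' @param pseudo a [pseudo_values()] result (or a bare numeric vector).
#' @param threshold probability threshold; risk > threshold is positive.
#' @return a [confusion_matrix()] with fractional cells.
#' @export
pseudo_confusion_matrix <- function(predicted_risk, pseudo, threshold) {
  vals <- if (inherits(pseudo, "pseudo_value_set")) pseudo$values else pseudo
  stopifnot(length(predicted_risk) == length(vals),
            threshold >= 0, threshold <= 1)
  pos <- predicted_risk > threshold
  confusion_matrix(tp = sum(vals[pos]),
                   fp = sum(1 - vals[pos]),
                   tn = sum(1 - vals[!pos]),
                   fn = sum(vals[!pos]),
                   allow_negative = TRUE)
}

#' Specify a time-to-event simulation scenario
#'
#' Defines the data-generating process for the simulation engine that
#' estimates expected confidence-interval widths at candidate sample sizes:
#' a proportional-hazards Weibull event-time model anchored at a baseline
#' survival probability at the horizon, a linear-predictor distribution, and
#' an independent (non-informative) censoring distribution.
#'
#' Event times satisfy `S_i(t) = exp(-lambda * t^shape * exp(LP_i))` with
#' `lambda` chosen so the baseline survival at the horizon equals
#' `baseline_survival`; predicted risks are `1 - S0(t*)^exp(LP)`, so the
#' risk model is perfectly calibrated to the generating process.
#'
#' @param candidate_n integer vector of candidate sample sizes (each >= 2).
#' @param replicates simulation replicates per candidate size.
#' @param horizon prediction horizon `t*` (time units of the scenario).
#' @param baseline_survival baseline survival at the horizon, in (0, 1).
#' @param lp_dist a [normal_lp()] or [empirical_lp()] distribution for the
#'   linear predictor.
#' @param event_shape Weibull shape of the event-time model (1 =
#'   exponential hazard).
#' @param censoring list describing the censoring-time distribution: either
#'   `list(family = "uniform", max = ...)`, `list(family = "exponential",
#'   rate = ...)` or `list(family = "none")`.
#' @param seed RNG seed.
#' @return an object of class `tte_scenario`.
#' @export
tte_scenario <- function(candidate_n, replicates = 200, horizon = 3,
                         baseline_survival = 0.9,
                         lp_dist = normal_lp(0, 0.8),
                         event_shape = 1,
                         censoring = list(family = "uniform", max = 6),
                         seed = 20250101) {
  stopifnot(all(candidate_n >= 2), replicates >= 1, horizon > 0,
            baseline_survival > 0, baseline_survival < 1,
            inherits(lp_dist, "risk_dist"),
            lp_dist$family %in% c("normal", "empirical"),
            event_shape > 0,
            censoring$family %in% c("uniform", "exponential", "none"))
  structure(list(candidate_n = as.integer(candidate_n),
                 replicates = as.integer(replicates),
                 horizon = horizon,
                 baseline_survival = baseline_survival,
                 lp_dist = lp_dist,
                 event_shape = event_shape,
                 censoring = censoring,
                 seed = as.integer(seed)),
            class = "tte_scenario")
}

draw_lp <- function(lp_dist, n) {
  if (lp_dist$family == "normal") {
    stats::rnorm(n, lp_dist$mean, lp_dist$sd)
  } else {
    sample(lp_dist$lp, n, replace = TRUE)
  }
}

simulate_tte_dataset <- function(scenario, n) {
  lp <- draw_lp(scenario$lp_dist, n)
  gamma <- scenario$event_shape
  lambda <- -log(scenario$baseline_survival) / scenario$horizon^gamma
  u <- stats::runif(n)
  t_event <- (-log(u) / (lambda * exp(lp)))^(1 / gamma)
  t_cens <- switch(scenario$censoring$family,
    uniform = stats::runif(n, 0, scenario$censoring$max),
    exponential = stats::rexp(n, scenario$censoring$rate),
    none = rep(Inf, n))
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             lp = lp,
             risk = risk_at_horizon(scenario$baseline_survival, lp))
}

#' Expected confidence-interval widths under a time-to-event scenario
#'
#' For each candidate sample size, repeatedly simulates a validation
#' dataset from the scenario, derives jackknife pseudo-values at the
#' horizon, forms the pseudo-value confusion matrix at the threshold and
#' computes each requested measure with its Wald confidence interval; the
#' report gives the across-replicate mean point estimate and mean interval
#' bounds (or the 2.5/97.5 percentiles of the replicate estimates when
#' `summary = "percentile"`). Replicates in which a measure is undefined
#' (empty denominator) are excluded for that measure and counted.
#'
#' @param scenario a [tte_scenario()].
#' @param threshold probability threshold for classification.
#' @param measures subset of the six measures (default all).
#' @param level confidence level.
#' @param summary `"mean"` (mean bounds across replicates) or
#'   `"percentile"`.
#' @return a data.frame with columns `n`, `measure`, `estimate`, `ci_low`,
#'   `ci_high`, `ciw`, `n_excluded`.
#' @export
expected_ciw_simulation <- function(scenario, threshold,
                                    measures = MEASURES, level = 0.95,
                                    summary = c("mean", "percentile")) {
  stopifnot(inherits(scenario, "tte_scenario"))
  summary <- match.arg(summary)
  measures <- vapply(measures, match_measure, character(1), USE.NAMES = FALSE)
  set.seed(scenario$seed)
  z <- z_level(level)
  out <- list()
  for (n in scenario$candidate_n) {
    est <- matrix(NA_real_, scenario$replicates, length(measures),
                  dimnames = list(NULL, measures))
    lo <- est; hi <- est
    for (r in seq_len(scenario$replicates)) {
      dat <- simulate_tte_dataset(scenario, n)
      # the engine always takes the accelerated path; the O(N^2) jackknife
      # remains available through pseudo_values() directly
      ps <- pseudo_values(dat$time, dat$event, scenario$horizon,
                          method = "fast")
      cm <- pseudo_confusion_matrix(dat$risk, ps, threshold)
      m <- measures_from_matrix(cm)
      for (ms in measures) {
        v <- m[[ms]]
        if (is.na(v)) next
        se <- if (ms == "f1") {
          se_f1_from_matrix(cm)
        } else {
          den <- switch(ms,
            accuracy = cm$n,
            specificity = cm$tn + cm$fp,
            sensitivity = cm$tp + cm$fn,
            ppv = cm$tp + cm$fp,
            npv = cm$tn + cm$fn)
          # pseudo-value cells can push the estimate marginally outside
          # [0, 1]; clamp only inside the variance
          se_proportion(min(max(v, 0), 1), den)
        }
        est[r, ms] <- v
        lo[r, ms] <- v - z * se
        hi[r, ms] <- v + z * se
      }
    }
    for (ms in measures) {
      ok <- !is.na(est[, ms])
      if (summary == "mean") {
        l <- mean(lo[ok, ms]); h <- mean(hi[ok, ms])
      } else {
        q <- stats::quantile(est[ok, ms], c((1 - level) / 2, 1 - (1 - level) / 2),
                             names = FALSE)
        l <- q[1]; h <- q[2]
      }
      out[[length(out) + 1L]] <- data.frame(
        n = n, measure = ms,
        estimate = mean(est[ok, ms]),
        ci_low = l, ci_high = h, ciw = h - l,
        n_excluded = sum(!ok))
    }
  }
  do.call(rbind, out)
}
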