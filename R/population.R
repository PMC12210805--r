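#' Risk-distribution families for the validation population
#'
#' The anticipated distribution of the model's predicted risks in the
#' external validation population. Three parametric families are supported:
#' a Beta distribution on the probability scale (the usual choice when a
#' histogram of predicted risks is available), a normal distribution on the
#' linear-predictor (log-odds) scale (the form used in the earlier
#' sample-size criteria literature), and a degenerate point mass (useful for
#' sanity checks). An empirical family carries a raw vector of linear
#' predictors, e.g. read from a development-study export; no fitting is
#' performed.
#'
#' @param shape1,shape2 strictly positive Beta shape parameters.
#' @return an object of class `risk_dist`.
#' @export
#' @examples
#' beta_risk(1.33, 1.75) # mean 0.432
beta_risk <- function(shape1, shape2) {
  stopifnot(is.numeric(shape1), is.numeric(shape2), shape1 > 0, shape2 > 0)
  structure(list(family = "beta", shape1 = shape1, shape2 = shape2),
            class = "risk_dist")
}

#' @rdname beta_risk
#' @param mean,sd mean and standard deviation of the linear predictor
#'   (log-odds scale); `sd` must be positive.
#' @export
normal_lp <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  structure(list(family = "normal", mean = mean, sd = sd), class = "risk_dist")
}

#' @rdname beta_risk
#' @param p fixed predicted probability in (0, 1) for the point-mass family.
#' @export
point_risk <- function(p) {
  stopifnot(is.numeric(p), p > 0, p < 1)
  structure(list(family = "point", p = p), class = "risk_dist")
}

#' @rdname beta_risk
#' @param lp numeric vector of linear predictors for the empirical family.
#' @export
empirical_lp <- function(lp) {
  stopifnot(is.numeric(lp), length(lp) > 0, all(is.finite(lp)))
  structure(list(family = "empirical", lp = lp), class = "risk_dist")
}

#' Specify the anticipated validation population
#'
#' Bundles the assumed distribution of predicted risks with the assumed
#' calibration of the model in the validation population. With
#' `calibration_intercept = 0` and `calibration_slope = 1` the model is
#' well calibrated: an individual's true event probability equals their
#' predicted probability. Other values let the planner explore miscalibration
#' scenarios (the outcome probability becomes
#' `expit(intercept + slope * LP)` where `LP = logit(predicted risk)`).
#'
#' @param dist a [beta_risk()], [normal_lp()], [point_risk()] or
#'   [empirical_lp()] object.
#' @param calibration_intercept calibration-in-the-large term on the log-odds
#'   scale (default 0).
#' @param calibration_slope calibration slope (default 1).
#' @param n_sim number of individuals to simulate when deriving anticipated
#'   performance by simulation. The default, one million, makes Monte-Carlo
#'   error in the derived performance values negligible at the third decimal.
#' @param seed integer RNG seed used by [simulate_population()].
#' @return an object of class `pop_spec`.
#' @export
#' @examples
#' spec <- pop_spec(beta_risk(1.33, 1.75), n_sim = 1e5, seed = 42)
#' spec
pop_spec <- function(dist,
                     calibration_intercept = 0,
                     calibration_slope = 1,
                     n_sim = 1e6,
                     seed = 20250101) {
  if (!inherits(dist, "risk_dist")) {
    stop("`dist` must be a risk_dist object (see beta_risk(), normal_lp()).",
         call. = FALSE)
  }
  stopifnot(is.numeric(calibration_intercept), length(calibration_intercept) == 1L,
            is.numeric(calibration_slope), length(calibration_slope) == 1L,
            is.numeric(n_sim), length(n_sim) == 1L, n_sim >= 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(dist = dist,
                 calibration_intercept = calibration_intercept,
                 calibration_slope = calibration_slope,
                 n_sim = as.integer(n_sim),
                 seed = as.integer(seed)),
            class = "pop_spec")
}

#' @export
print.pop_spec <- function(x, ...) {
  d <- x$dist
  desc <- switch(d$family,
    beta = sprintf("Beta(%g, %g) on the probability scale", d$shape1, d$shape2),
    normal = sprintf("Normal(%g, %g) on the linear-predictor scale", d$mean, d$sd),
    point = sprintf("point mass at p = %g", d$p),
    empirical = sprintf("empirical linear predictors (n = %d)", length(d$lp)))
  cat("Validation population specification\n")
  cat("  predicted risks: ", desc, "\n", sep = "")
  cat(sprintf("  calibration: intercept %g, slope %g%s\n",
              x$calibration_intercept, x$calibration_slope,
              if (x$calibration_intercept == 0 && x$calibration_slope == 1)
                " (well calibrated)" else ""))
  cat(sprintf("  simulation size %s, seed %d\n",
              format(x$n_sim, big.mark = ","), x$seed))
  invisible(x)
}

#' Simulate a validation population
#'
#' Draws predicted risks from the specified distribution and binary outcomes
#' from a Bernoulli with probability `expit(intercept + slope * LP)`, so that
#' under perfect calibration the outcome probability equals the predicted
#' probability. Reproducible under the spec's seed.
#'
#' @param spec a [pop_spec()].
#' @return a data.frame with columns `p` (predicted probability), `lp`
#'   (linear predictor, `logit(p)`) and `y` (binary outcome).
#' @export
#' @examples
#' sim <- simulate_population(pop_spec(beta_risk(1.33, 1.75), n_sim = 1e4))
#' mean(sim$y) # close to 1.33 / (1.33 + 1.75) = 0.432
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "pop_spec"))
  set.seed(spec$seed)
  n <- spec$n_sim
  d <- spec$dist
  if (d$family == "beta") {
    p <- stats::rbeta(n, d$shape1, d$shape2)
    lp <- logit(p)
  } else if (d$family == "normal") {
    lp <- stats::rnorm(n, d$mean, d$sd)
    p <- expit(lp)
  } else if (d$family == "point") {
    p <- rep(d$p, n)
    lp <- logit(p)
  } else { # empirical
    lp <- if (n == length(d$lp)) d$lp else sample(d$lp, n, replace = TRUE)
    p <- expit(lp)
  }
  prob_event <- expit(spec$calibration_intercept + spec$calibration_slope * lp)
  y <- stats::rbinom(n, 1L, prob_event)
  data.frame(p = p, lp = lp, y = y)
}

#' Anticipated performance profile at a threshold
#'
#' A `perf_profile` holds the anticipated "true" prevalence and the six
#' threshold-based performance measures at one probability threshold. Given
#' prevalence, sensitivity and specificity the remaining measures are fully
#' determined (Bayes' rule), so the constructor derives them:
#' \deqn{accuracy = \phi \cdot sens + (1-\phi) \cdot spec}
#' \deqn{PPV = \phi \, sens / (\phi \, sens + (1-\phi)(1-spec))}
#' \deqn{NPV = (1-\phi) spec / ((1-\phi) spec + \phi (1-sens))}
#' and the F1-score is the harmonic mean of PPV and sensitivity.
#'
#' @param threshold probability threshold in \[0, 1\].
#' @param phi outcome prevalence in (0, 1).
#' @param sensitivity,specificity anticipated values in \[0, 1\].
#' @return an object of class `perf_profile`: a list with elements
#'   `threshold`, `phi`, `accuracy`, `specificity`, `sensitivity`, `ppv`,
#'   `npv`, `f1`.
#' @export
#' @examples
#' perf_profile(0.1, phi = 0.43, sensitivity = 0.988, specificity = 0.147)
perf_profile <- function(threshold, phi, sensitivity, specificity) {
  stopifnot(threshold >= 0, threshold <= 1,
            phi > 0, phi < 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  pos <- phi * sensitivity + (1 - phi) * (1 - specificity)   # P(classified +)
  neg <- 1 - pos
  ppv <- if (pos > 0) phi * sensitivity / pos else NA_real_
  npv <- if (neg > 0) (1 - phi) * specificity / neg else NA_real_
  f1 <- if (!is.na(ppv) && (ppv + sensitivity) > 0) {
    2 * ppv * sensitivity / (ppv + sensitivity)
  } else NA_real_
  structure(list(threshold = threshold,
                 phi = phi,
                 accuracy = phi * sensitivity + (1 - phi) * specificity,
                 specificity = specificity,
                 sensitivity = sensitivity,
                 ppv = ppv,
                 npv = npv,
                 f1 = f1),
            class = "perf_profile")
}

#' @export
print.perf_profile <- function(x, ...) {
  cat(sprintf("Performance profile at threshold %g (prevalence %.4f)\n",
              x$threshold, x$phi))
  v <- unlist(x[MEASURES])
  print(round(v, 4))
  invisible(x)
}

#' @export
as.data.frame.perf_profile <- function(x, ...) {
  data.frame(threshold = x$threshold, phi = x$phi,
             measure = MEASURES,
             value = unlist(x[MEASURES], use.names = FALSE))
}

#' Derive the anticipated true performance at a threshold
#'
#' Computes the anticipated prevalence and the six threshold-based measures
#' for a population specification, either from a large simulated population
#' (classifying positive when predicted probability exceeds the threshold;
#' ties classify negative) or by adaptive numerical integration over the risk
#' density, which is seed-free and serves as an independent check on the
#' simulation. For a Beta or normal risk distribution the integrals are
#' \deqn{\phi = E[q(p)], \quad sens = E[q(p) 1(p > t)]/\phi, \quad
#'       spec = E[(1-q(p)) 1(p \le t)]/(1-\phi)}
#' with `q(p) = expit(intercept + slope * logit(p))` the true event
#' probability (`q = p` under perfect calibration).
#'
#' @param spec a [pop_spec()].
#' @param threshold probability threshold in \[0, 1\].
#' @param method `"simulation"` (default) or `"quadrature"`.
#' @param population optional pre-simulated population (as returned by
#'   [simulate_population()]) to reuse across thresholds.
#' @return a [perf_profile()].
#' @export
#' @examples
#' spec <- pop_spec(beta_risk(1.33, 1.75))
#' true_performance(spec, 0.1, method = "quadrature")
true_performance <- function(spec, threshold,
                             method = c("simulation", "quadrature"),
                             population = NULL) {
  stopifnot(inherits(spec, "pop_spec"), threshold >= 0, threshold <= 1)
  method <- match.arg(method)
  if (method == "simulation") {
    sim <- if (is.null(population)) simulate_population(spec) else population
    pos <- sim$p > threshold
    cm <- confusion_matrix(tp = sum(sim$y == 1L & pos),
                           fp = sum(sim$y == 0L & pos),
                           tn = sum(sim$y == 0L & !pos),
                           fn = sum(sim$y == 1L & !pos))
    return(profile_from_matrix(cm, threshold))
  }
  quadrature_performance(spec, threshold)
}

#' Build a performance profile from an observed confusion matrix
#'
#' @param cm a [confusion_matrix()].
#' @param threshold the threshold the matrix was formed at.
#' @return a [perf_profile()].
#' @export
profile_from_matrix <- function(cm, threshold) {
  m <- measures_from_matrix(cm)
  perf_profile(threshold, phi = prevalence(cm),
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]])
}

# Seed-free oracle: adaptive quadrature over the risk density.
quadrature_performance <- function(spec, threshold, abs_tol = 1e-10) {
  d <- spec$dist
  a0 <- spec$calibration_intercept
  b0 <- spec$calibration_slope
  q <- function(p) expit(a0 + b0 * logit(p)) # true event probability
  if (d$family == "empirical") {
    stop("quadrature is unsupported for an empirical linear-predictor ",
         "distribution; use method = \"simulation\".", call. = FALSE)
  }
  if (d$family == "point") {
    qq <- q(d$p)
    pos <- d$p > threshold
    return(perf_profile(threshold, phi = qq,
                        sensitivity = as.numeric(pos),
                        specificity = as.numeric(!pos)))
  }
  if (d$family == "beta") {
    dens <- function(p) stats::dbeta(p, d$shape1, d$shape2)
    int <- function(f, lo, hi) {
      if (hi <= lo) return(0)
      stats::integrate(f, lo, hi, abs.tol = abs_tol, rel.tol = abs_tol,
                       subdivisions = 500L)$value
    }
    phi <- int(function(p) q(p) * dens(p), 0, 1)
    ev_pos <- int(function(p) q(p) * dens(p), threshold, 1)
    noev_neg <- int(function(p) (1 - q(p)) * dens(p), 0, threshold)
  } else { # normal on the LP scale; integrate over lp
    dens <- function(lp) stats::dnorm(lp, d$mean, d$sd)
    qlp <- function(lp) expit(a0 + b0 * lp)
    tlp <- logit(threshold)
    int <- function(f, lo, hi) {
      if (hi <= lo) return(0)
      stats::integrate(f, lo, hi, abs.tol = abs_tol, rel.tol = abs_tol,
                       subdivisions = 500L)$value
    }
    phi <- int(function(lp) qlp(lp) * dens(lp), -Inf, Inf)
    ev_pos <- int(function(lp) qlp(lp) * dens(lp), tlp, Inf)
    noev_neg <- int(function(lp) (1 - qlp(lp)) * dens(lp), -Inf, tlp)
  }
  perf_profile(threshold, phi = phi,
               sensitivity = ev_pos / phi,
               specificity = noev_neg / (1 - phi))
}

#' Read or write a population specification as JSON
#'
#' Flat JSON serialisation of a [pop_spec()]: distribution family and
#' parameters, calibration intercept/slope, simulation size and seed.
#'
#' @param spec a [pop_spec()].
#' @param path file path.
#' @return `read_pop_spec()` returns a [pop_spec()]; `write_pop_spec()`
#'   returns `path` invisibly.
#' @export
write_pop_spec <- function(spec, path) {
  stopifnot(inherits(spec, "pop_spec"))
  x <- c(list(family = spec$dist$family),
         spec$dist[setdiff(names(spec$dist), "family")],
         list(calibration_intercept = spec$calibration_intercept,
              calibration_slope = spec$calibration_slope,
              n_sim = spec$n_sim, seed = spec$seed))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pop_spec
#' @export
read_pop_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dist <- switch(x$family,
    beta = beta_risk(x$shape1, x$shape2),
    normal = normal_lp(x$mean, x$sd),
    point = point_risk(x$p),
    empirical = empirical_lp(x$lp),
    stop("unknown risk distribution family: ", x$family, call. = FALSE))
  pop_spec(dist,
           calibration_intercept = x$calibration_intercept,
           calibration_slope = x$calibration_slope,
           n_sim = x$n_sim, seed = x$seed)
}
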