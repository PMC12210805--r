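test_that("absolute risk at the horizon follows the baseline-survival power", {
  expect_equal(risk_at_horizon(0.9, 0), 0.1)
  expect_equal(risk_at_horizon(1, c(-2, 0, 3)), c(0, 0, 0))
  expect_equal(risk_at_horizon(0.9, log(2)), 1 - 0.9^2)
})

test_that("Kaplan-Meier cumulative incidence matches a hand calculation", {
  # times 1..6, censoring at t = 3; product over event times up to t* = 5:
  # (1-1/6)(1-1/5)(1-1/3)(1-1/2) leaves S = 2/9
  time <- 1:6
  event <- c(1, 1, 0, 1, 1, 1)
  expect_equal(km_cuminc(time, event, 5), 1 - 2 / 9)
  # without censoring the estimate is the empirical CDF of event times
  expect_equal(km_cuminc(time, rep(1, 6), 3.5), 0.5)
  expect_warning(f0 <- km_cuminc(c(1, 2), c(0, 0), 5), "no events")
  expect_equal(f0, 0)
})

test_that("pseudo-values without censoring equal the event indicators", {
  set.seed(61)
  time <- rexp(40)
  event <- rep(1, 40)
  ps <- pseudo_values(time, event, horizon = 1)
  expect_equal(ps$values, as.numeric(time <= 1), tolerance = 1e-10)
  ps_fast <- pseudo_values(time, event, horizon = 1, method = "fast")
  expect_equal(ps_fast$values, ps$values, tolerance = 1e-10)
})

test_that("pseudo-value means equal the full-sample cumulative incidence", {
  set.seed(62)
  for (i in 1:5) {
    time <- rexp(60)
    event <- rbinom(60, 1, 0.7)
    ps <- pseudo_values(time, event, horizon = median(time))
    expect_equal(mean(ps$values), ps$km_cuminc, tolerance = 1e-10)
  }
})

test_that("the fast pseudo-value path equals the leave-one-out oracle", {
  set.seed(63)
  for (i in 1:6) {
    n <- 50
    time <- round(rexp(n), 2) # rounding forces tied times
    time[time == 0] <- 0.01
    event <- rbinom(n, 1, 0.6)
    horizon <- stats::quantile(time, 0.7, names = FALSE)
    fast <- pseudo_values(time, event, horizon, method = "fast")$values
    slow <- pseudo_values(time, event, horizon, method = "jackknife")$values
    expect_equal(fast, slow, tolerance = 1e-10)
  }
})

test_that("pseudo-value matrices reduce to binary matrices without censoring", {
  set.seed(64)
  n <- 200
  risk <- runif(n)
  time <- rexp(n, rate = -log(1 - risk)) # P(T <= 1) = risk
  ps <- pseudo_values(time, rep(1, n), horizon = 1, method = "fast")
  cm_pseudo <- pseudo_confusion_matrix(risk, ps, 0.5)
  y <- as.integer(time <= 1)
  pos <- risk > 0.5
  cm_binary <- confusion_matrix(sum(y & pos), sum(!y & pos),
                                sum(!y & !pos), sum(y & !pos))
  expect_equal(cm_pseudo$tp, cm_binary$tp, tolerance = 1e-8)
  expect_equal(measures_from_matrix(cm_pseudo),
               measures_from_matrix(cm_binary), tolerance = 1e-8)
})

test_that("constant pseudo-values give that constant as prevalence", {
  cm <- pseudo_confusion_matrix(c(0.2, 0.4, 0.9), rep(0.3, 3), 0.5)
  expect_equal(prevalence(cm), 0.3)
})

test_that("censored fixtures can push cells fractional and out of [0,1]", {
  set.seed(65)
  n <- 80
  time <- rexp(n)
  event <- rbinom(n, 1, 0.5)
  ps <- pseudo_values(time, event, horizon = median(time))
  expect_true(any(ps$values < 0 | ps$values > 1))
  cm <- pseudo_confusion_matrix(runif(n), ps, 0.5)
  m <- measures_from_matrix(cm)
  expect_true(all(is.finite(m[c("accuracy", "sensitivity", "specificity")])))
})

test_that("an uncensored scenario agrees with the analytic profile", {
  sc <- tte_scenario(candidate_n = 400, replicates = 40, horizon = 3,
                     baseline_survival = 0.9, lp_dist = normal_lp(0, 0.8),
                     censoring = list(family = "none"), seed = 660)
  out <- expected_ciw_simulation(sc, threshold = 0.1)
  # analytic truth by integrating over the linear-predictor density
  risk <- function(lp) 1 - 0.9^exp(lp)
  dens <- function(lp) dnorm(lp, 0, 0.8)
  phi <- integrate(function(lp) risk(lp) * dens(lp), -Inf, Inf)$value
  sens <- integrate(function(lp) risk(lp) * (risk(lp) > 0.1) * dens(lp),
                    -Inf, Inf)$value / phi
  est <- out[out$measure == "sensitivity", ]
  mc_se <- sqrt(sens * (1 - sens) / (400 * phi)) / sqrt(40)
  expect_lt(abs(est$estimate - sens), 4 * mc_se)
  acc_true <- phi * sens +
    (1 - phi) * integrate(function(lp) (1 - risk(lp)) * (risk(lp) <= 0.1) *
                            dens(lp), -Inf, Inf)$value / (1 - phi)
  acc <- out[out$measure == "accuracy", ]
  expect_lt(abs(acc$estimate - acc_true), 4 * sqrt(0.25 / 400) / sqrt(40))
})

test_that("censoring leaves the simulation engine consistent and scaled", {
  sc <- function(ns) tte_scenario(candidate_n = ns, replicates = 30,
                                  horizon = 3, baseline_survival = 0.85,
                                  lp_dist = normal_lp(0, 1),
                                  censoring = list(family = "uniform", max = 6),
                                  seed = 661)
  out <- expected_ciw_simulation(sc(c(100, 400)), threshold = 0.15,
                                 measures = c("accuracy", "sensitivity", "f1"))
  expect_equal(nrow(out), 6L)
  expect_named(out, c("n", "measure", "estimate", "ci_low", "ci_high",
                      "ciw", "n_excluded"))
  # widths shrink about 1/sqrt(N): factor 2 between N = 100 and 400
  for (ms in unique(out$measure)) {
    w <- out[out$measure == ms, ]
    expect_equal(w$ciw[w$n == 100] / w$ciw[w$n == 400], 2, tolerance = 0.25)
  }
  # estimates are stable across candidate sizes (same data-generating process)
  acc <- out[out$measure == "accuracy", "estimate"]
  expect_lt(abs(diff(acc)), 0.05)
})

test_that("percentile summarisation is available and ordered", {
  scn <- tte_scenario(candidate_n = 150, replicates = 30, horizon = 3,
                      censoring = list(family = "exponential", rate = 0.1),
                      seed = 662)
  out <- expected_ciw_simulation(scn, threshold = 0.1,
                                 measures = "accuracy",
                                 summary = "percentile")
  expect_lt(out$ci_low, out$estimate)
  expect_gt(out$ci_high, out$estimate)
})

test_that("scenario validation rejects bad inputs", {
  expect_error(tte_scenario(candidate_n = 1))
  expect_error(tte_scenario(candidate_n = 10, baseline_survival = 1.2))
  expect_error(tte_scenario(candidate_n = 10,
                            censoring = list(family = "gamma")))
})
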