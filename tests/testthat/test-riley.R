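test_that("the O/E criterion reproduces the published example", {
  res <- n_oe(0.43, precision_target("oe", ciw = 0.22))
  expect_equal(res$n_required, 423L)
  expect_equal(res$events_required, 182L)
})

test_that("an O/E width target and its implied SE target give the same N", {
  se <- asinh(0.22 / 2) / 1.96
  via_ciw <- n_oe(0.43, precision_target("oe", ciw = 0.22))
  via_se <- n_oe(0.43, precision_target("oe", se = se))
  expect_identical(via_ciw$n_required, via_se$n_required)
})

test_that("O/E closed form at symmetric prevalence", {
  res <- n_oe(0.5, precision_target("oe", se = 0.1))
  expect_equal(res$n_required, 100L)
})

test_that("Fisher information elements behave at reference points", {
  info <- fisher_information(rep(0, 10))
  expect_equal(info$I_alpha, 0.25)
  expect_equal(info$I_alpha_beta, 0)
  expect_equal(info$I_beta, 0)
  # symmetric LP sample about zero: odd integrand cancels
  lp <- c(-2, -1, -0.5, 0.5, 1, 2)
  expect_equal(fisher_information(lp)$I_alpha_beta, 0, tolerance = 1e-12)
  expect_error(fisher_information(numeric(0)))
})

test_that("simulated Fisher information converges to the quadrature values", {
  # standard-normal linear predictor: integrate a_i, b_i, c_i directly
  f <- function(g) function(x) g(x) * dlogis(x) * dnorm(x)
  Ia <- integrate(f(function(x) 1), -Inf, Inf, abs.tol = 1e-12)$value
  Iab <- integrate(f(function(x) x), -Inf, Inf, abs.tol = 1e-12)$value
  Ib <- integrate(f(function(x) x^2), -Inf, Inf, abs.tol = 1e-12)$value
  set.seed(314)
  info <- fisher_information(rnorm(2e5))
  expect_equal(info$I_alpha, Ia, tolerance = 0.005)
  expect_equal(info$I_alpha_beta, Iab, tolerance = 0.01)
  expect_equal(info$I_beta, Ib, tolerance = 0.01)
})

test_that("calibration-slope N matches the Beta example via quadrature", {
  # seed-free information elements under perfect calibration: with LP =
  # logit(p), a_i reduces to p(1-p)
  dens <- function(p) dbeta(p, 1.33, 1.75)
  Ia <- integrate(function(p) p * (1 - p) * dens(p), 0, 1, abs.tol = 1e-12)$value
  Iab <- integrate(function(p) qlogis(p) * p * (1 - p) * dens(p), 0, 1,
                   abs.tol = 1e-12)$value
  Ib <- integrate(function(p) qlogis(p)^2 * p * (1 - p) * dens(p), 0, 1,
                  abs.tol = 1e-12)$value
  info <- structure(list(I_alpha = Ia, I_alpha_beta = Iab, I_beta = Ib),
                    class = "calibration_information")
  res <- n_calibration_slope(info, precision_target("slope", ciw = 0.3),
                             phi = 1.33 / (1.33 + 1.75))
  expect_equal(res$n_required, 949L)
})

test_that("doubling the slope SE target quarters N", {
  info <- fisher_information(rnorm(5e3))
  n1 <- n_calibration_slope(info, precision_target("s", se = 0.05), 0.4)
  n2 <- n_calibration_slope(info, precision_target("s", se = 0.1), 0.4)
  expect_lt(abs(n1$n_required / n2$n_required - 4), 0.01)
})

test_that("degenerate linear predictors are rejected for the slope", {
  info <- fisher_information(rep(1.3, 50))
  expect_error(n_calibration_slope(info, precision_target("s", se = 0.05), 0.4),
               "degenerate")
})

test_that("the c-statistic criterion reproduces the published example", {
  res <- n_cstatistic(0.77, 0.43, precision_target("c", ciw = 0.1))
  expect_equal(res$n_required, 347L)
})

test_that("Newcombe SE decreases in N and the searches agree", {
  ns <- round(seq(10, 5000, length.out = 40))
  ses <- se_cstatistic(0.77, ns, 0.43)
  expect_true(all(diff(ses) < 0))
  set.seed(21)
  for (i in 1:20) {
    C <- runif(1, 0.6, 0.9); phi <- runif(1, 0.1, 0.9)
    tgt <- precision_target("c", ciw = runif(1, 0.08, 0.2))
    a <- n_cstatistic(C, phi, tgt, n_max = 1e5, search = "scan")$n_required
    b <- n_cstatistic(C, phi, tgt, n_max = 1e5, search = "bisect")$n_required
    expect_identical(a, b)
  }
  expect_error(n_cstatistic(1, 0.4, precision_target("c", ciw = 0.1)),
               "degenerates")
})

test_that("net-benefit sample size matches the Beta example at t = 0.1", {
  prof <- beta_profile_quad(0.1)
  res <- n_snb(prof, 0.1, precision_target("snb", ciw = 0.2))
  # published value 38 from one simulation draw; seed-free quadrature gives 37
  expect_lt(abs(res$n_required - 38L), 3)
  expect_equal(res$assumptions$nb, 0.371, tolerance = 0.015)
  expect_equal(res$assumptions$snb,
               prof$sensitivity - res$assumptions$w * (1 - prof$specificity))
})

test_that("at p equal to prevalence the sNB weight is one", {
  prof <- perf_profile(0.4, phi = 0.4, sensitivity = 0.8, specificity = 0.7)
  res <- n_snb(prof, 0.4, precision_target("snb", se = 0.05))
  expect_equal(res$assumptions$w, 1)
  direct <- (1 / 0.05^2) * (0.8 * 0.2 / 0.4 + 0.7 * 0.3 / 0.6 +
                              0.3^2 / (0.4 * 0.6))
  expect_equal(res$n_required, as.integer(ceiling(direct)))
})

test_that("smaller target widths never reduce any criterion's N", {
  widths <- c(0.08, 0.12, 0.2)
  prof <- beta_profile_quad(0.1)
  info <- fisher_information(qlogis(rbeta(5e3, 1.33, 1.75)))
  for (w in list(
    function(x) n_oe(0.43, precision_target("oe", ciw = x))$n_required,
    function(x) n_cstatistic(0.77, 0.43,
                             precision_target("c", ciw = x))$n_required,
    function(x) n_calibration_slope(info, precision_target("s", ciw = x),
                                    0.43)$n_required,
    function(x) n_snb(prof, 0.1, precision_target("b", ciw = x))$n_required)) {
    ns <- vapply(widths, w, integer(1))
    expect_true(all(diff(ns) <= 0))
  }
})
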