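test_that("a symmetric confusion matrix gives 0.8 for every measure", {
  m <- measures_from_matrix(confusion_matrix(40, 10, 40, 10))
  expect_equal(unname(m), rep(0.8, 6))
})

test_that("no true positives gives zero sensitivity and F1, not NA", {
  m <- measures_from_matrix(confusion_matrix(tp = 0, fp = 20, tn = 40, fn = 10))
  expect_equal(m[["sensitivity"]], 0)
  expect_equal(m[["f1"]], 0)
})

test_that("empty denominators yield NA, distinguishing undefined from zero", {
  # no predicted positives at all: PPV undefined, F1 undefined
  m <- measures_from_matrix(confusion_matrix(tp = 0, fp = 0, tn = 40, fn = 10))
  expect_true(is.na(m[["ppv"]]))
  expect_true(is.na(m[["f1"]]))
  expect_equal(m[["sensitivity"]], 0)
  # no actual negatives: specificity undefined
  m2 <- measures_from_matrix(confusion_matrix(tp = 10, fp = 0, tn = 0, fn = 5))
  expect_true(is.na(m2[["specificity"]]))
})

test_that("the F1 harmonic-mean forms agree on a hand-worked matrix", {
  cm <- confusion_matrix(30, 20, 40, 10)
  m <- measures_from_matrix(cm)
  expect_equal(m[["ppv"]], 0.6)
  expect_equal(m[["sensitivity"]], 0.75)
  expect_equal(m[["f1"]], 2 / 3)
  expect_equal(m[["f1"]], 2 * 0.6 * 0.75 / (0.6 + 0.75))
})

test_that("measures are invariant to rescaling all cells", {
  for (cm in random_matrices(10)) {
    scaled <- confusion_matrix(cm$tp * 2.5, cm$fp * 2.5,
                               cm$tn * 2.5, cm$fn * 2.5)
    expect_equal(measures_from_matrix(scaled), measures_from_matrix(cm))
  }
})

test_that("proportion standard error follows sqrt(p(1-p)/n)", {
  expect_equal(se_proportion(0.5, 100), 0.05)
  expect_equal(se_proportion(0, 50), 0)
  expect_equal(se_proportion(1, 50), 0)
  # sensitivity SE written with the prevalence-scaled denominator
  phi <- 0.43; N <- 42
  expect_equal(se_proportion(0.988, phi * N),
               sqrt(0.988 * (1 - 0.988) / (phi * N)))
})

test_that("the two printed covariance forms agree on any matrix", {
  for (cm in random_matrices(25)) {
    m <- measures_from_matrix(cm)
    if (m[["ppv"]] %in% c(0, 1) || m[["sensitivity"]] %in% c(0, 1)) next
    expect_equal(cov_precision_recall(m[["ppv"]], m[["sensitivity"]],
                                      m[["specificity"]], prevalence(cm),
                                      cm$n),
                 cov_precision_recall_cells(cm),
                 tolerance = 1e-12)
  }
})

test_that("covariance vanishes without false positives", {
  expect_equal(cov_precision_recall_cells(confusion_matrix(30, 0, 40, 10)), 0)
})

test_that("covariance rejects degenerate prevalence", {
  expect_error(cov_precision_recall(0.5, 0.5, 0.5, 0, 100), "undefined")
})

test_that("the covariance convention is conservative for multinomial tables", {
  # fixed population matrix; resample whole tables of size N and measure the
  # empirical covariance of (precision, recall) across replicates. The exact
  # delta-method covariance is the first closed-form term alone; the two-term
  # convention overstates it, so the F1 SE is never understated.
  probs <- c(tp = 0.3, fp = 0.2, tn = 0.4, fn = 0.1)
  N <- 1e4; reps <- 1e5
  set.seed(202)
  draws <- stats::rmultinom(reps, N, probs)
  P <- draws[1, ] / (draws[1, ] + draws[2, ])
  R <- draws[1, ] / (draws[1, ] + draws[4, ])
  emp <- stats::cov(P, R)
  theo <- cov_precision_recall(0.6, 0.75, 2 / 3, 0.4, N)
  sim_se <- stats::sd((P - mean(P)) * (R - mean(R))) / sqrt(reps)
  first_term <- 0.6 * 0.4 * 0.25 / (0.4 * N)
  expect_lt(abs(emp - first_term), 3 * sim_se) # exact delta-method value
  expect_gt(theo, emp + 3 * sim_se)            # convention is conservative
})

test_that("the F1 standard error is conservative against the same oracle", {
  probs <- c(tp = 0.3, fp = 0.2, tn = 0.4, fn = 0.1)
  N <- 1e4; reps <- 1e5
  set.seed(203)
  draws <- stats::rmultinom(reps, N, probs)
  P <- draws[1, ] / (draws[1, ] + draws[2, ])
  R <- draws[1, ] / (draws[1, ] + draws[4, ])
  f1 <- 2 * P * R / (P + R)
  theo <- se_f1(0.6, 0.75, 2 / 3, 0.4, N)
  sd_se <- stats::sd(f1) / sqrt(2 * (reps - 1)) # SE of a sample SD
  expect_gte(theo, stats::sd(f1) - 3 * sd_se)
  # and it is not wildly conservative: within 25% of the realised spread
  expect_lt(theo / stats::sd(f1), 1.25)
})

test_that("F1 standard error halves when N quadruples", {
  s1 <- se_f1(0.47, 0.99, 0.15, 0.43, 400)
  s2 <- se_f1(0.47, 0.99, 0.15, 0.43, 1600)
  expect_equal(s1 / s2, 2, tolerance = 1e-12)
})

test_that("cell-count and closed-form F1 standard errors coincide", {
  for (cm in random_matrices(10, seed = 77)) {
    m <- measures_from_matrix(cm)
    if (m[["ppv"]] %in% c(0, 1) || m[["sensitivity"]] %in% c(0, 1)) next
    expect_equal(se_f1_from_matrix(cm),
                 se_f1(m[["ppv"]], m[["sensitivity"]], m[["specificity"]],
                       prevalence(cm), cm$n),
                 tolerance = 1e-12)
  }
})

test_that("width/SE conversions and Wald intervals are consistent", {
  expect_equal(ciw_to_se(0.1), 0.1 / (2 * 1.96)) # conventional 95% critical value
  expect_equal(ciw_to_se(0.1, level = 0.9), 0.1 / (2 * qnorm(0.95)))
  expect_equal(se_to_ciw(ciw_to_se(0.37)), 0.37)
  ci <- wald_ci(0.5, 0.05)
  expect_equal(unname(ci["upper"] - ci["lower"]), se_to_ciw(0.05))
})

test_that("confusion matrices round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  cm <- confusion_matrix(30.5, 20.25, 40, 10)
  write_confusion_csv(cm, path)
  back <- read_confusion_csv(path)
  expect_equal(back, cm)
})

test_that("invalid matrices are rejected", {
  expect_error(confusion_matrix(-1, 2, 3, 4), "non-negative")
  expect_error(confusion_matrix(0, 0, 0, 0), "positive total")
  expect_silent(confusion_matrix(-0.2, 2, 3, 4, allow_negative = TRUE))
})
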