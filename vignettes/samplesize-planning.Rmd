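---
title: "Planning sample size for threshold-based external validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning sample size for threshold-based external validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thresholdval)
```

## The planning problem

Before a clinical prediction model is used in practice its performance must
be evaluated in data that played no part in its development. When the model
will be used with a classification threshold $t$ — treat, refer, or test
when the predicted probability exceeds $t$ — the evaluation study should
estimate the threshold-based measures (accuracy, specificity, sensitivity
or recall, PPV or precision, NPV, and the F1-score) precisely, alongside the
established validation criteria: the observed/expected ratio, the
calibration slope, the c-statistic, and the standardised net benefit.
`thresholdval` computes, before any data are collected, the minimum number
of participants $N$ needed so that each of these estimates reaches a target
precision, expressed as a 95% confidence-interval width (CIW) or a standard
error; and conversely the interval widths expected at a given $N$.

All calculations run off *planning assumptions*: an anticipated outcome
prevalence $\phi$, an anticipated distribution of the model's predicted
risks in the validation population, and anticipated calibration. No
validation data are needed (that is the point — the study has not been run
yet).

## The population model

The anticipated distribution of predicted risks is specified with
`pop_spec()`. The default family is a Beta distribution on the probability
scale, the natural choice when the development paper shows a histogram of
predicted risks; a normal distribution on the linear-predictor (log-odds)
scale and a raw vector of linear predictors are also supported, the former
because the earlier criteria literature works on that scale. Calibration is
encoded by an intercept $\alpha$ and slope $\beta$: an individual with
predicted probability $p$ has true event probability
$\operatorname{expit}(\alpha + \beta\,\operatorname{logit} p)$, so
$\alpha = 0, \beta = 1$ is the well-calibrated case in which the event
probability *is* the predicted probability.

Anticipated "true" performance at a threshold is derived two ways:

* **simulation** — draw `n_sim` individuals (default $10^6$, which puts
  Monte-Carlo error in the third decimal of each measure), draw outcomes
  Bernoulli with the calibrated probability, and read the measures off the
  confusion matrix. The classification rule is *predicted probability
  strictly greater than $t$ is positive*; a prediction exactly equal to the
  threshold classifies negative.
* **quadrature** — adaptive numerical integration of
  $\phi = E[q(p)]$, $sens = E[q(p)\,1(p>t)]/\phi$,
  $spec = E[(1-q(p))\,1(p\le t)]/(1-\phi)$ over the risk density
  (absolute tolerance $10^{-10}$). This is seed-free, so it serves as an
  independent oracle for the simulation path throughout the test suite.
  It is unavailable for the empirical linear-predictor family, which has
  no density to integrate.

The remaining measures follow from identities: accuracy
$= \phi\,sens + (1-\phi)\,spec$, PPV and NPV by Bayes' rule, F1 as the
harmonic mean of PPV and sensitivity.

```{r}
spec <- pop_spec(beta_risk(1.33, 1.75))   # prevalence 1.33/3.08 = 0.432
true_performance(spec, 0.1, method = "quadrature")
```

## From standard errors to sample sizes

Five of the six measures are simple proportions $X/n$, with measure-specific
denominators ($N$ for accuracy, $(1-\phi)N$ for specificity, $\phi N$ for
sensitivity, the predicted-positive count for PPV and the predicted-negative
count for NPV), so $SE = \sqrt{\hat P(1-\hat P)/n}$ inverts in closed form.
A width target converts to a standard-error target as $SE = CIW/(2 \times
1.96)$; results round *up*, with events $= \lceil N\phi \rceil$
("minimum required" semantics — the convention here, since the rounding
direction is genuinely open, is that a fractional participant is a whole
participant).

The F1-score is not a proportion. Its delta-method standard error combines
the standard errors of precision $P$ and recall $R$ with their covariance
(they share the true-positive count):

$$SE_{F1} = \sqrt{4\,\frac{R^4 SE_P^2 + 2P^2R^2\,cov(P,R) + P^4 SE_R^2}
{(P+R)^4}}, \qquad
cov(P,R) = \frac{P(1-P)(1-R)/\phi + P(1-P)\,spec/(1-\phi)}{N}.$$

Because $SE_P$ and $SE_R$ depend on the sample size being sought, the
minimum $N$ is found iteratively: evaluate $SE_{F1}$ at each candidate $N$
and return the first that meets the target. Every variance term scales as
$1/N$, so the curve is strictly decreasing and a bisection search gives the
same answer as the linear scan; both are implemented and cross-checked.

Two numerical notes on this covariance. First, its two algebraic forms (a
cell-count form and the closed form above) agree exactly on any confusion
matrix — the test suite asserts this. Second, under simple multinomial
sampling of the four cells the exact large-sample covariance is the *first*
term alone, $P(1-P)(1-R)/(\phi N)$; the two-term convention adopted here —
the one the sample-size procedure for the F1-score is built on — therefore
*overstates* the covariance and makes $SE_{F1}$, and hence the returned
$N$, conservative (never too small). The package follows the two-term
convention deliberately, so that its sample sizes agree with the published
planning values; the conservatism is quantified in the test suite against a
multinomial Monte-Carlo oracle and is modest (under 25% on the spread of
F1 in the worked example's range).

## The four established criteria

* **O/E ratio**: $N = (1-\phi)/(\phi\,SE(\ln O/E)^2)$. A width target on
  the O/E scale is converted assuming the anticipated O/E is 1 (the
  well-calibrated planning assumption): the interval $\exp(\pm z\,SE)$ has
  width $CIW$ when $SE = \operatorname{asinh}(CIW/2)/z$. Supplying an SE
  directly overrides this assumption.
* **Calibration slope**: $N = I_\alpha/(SE(\beta)^2(I_\alpha I_\beta -
  I_{\alpha\beta}^2))$, with the Fisher-information elements computed as
  sample means of the logistic weights $a_i, b_i, c_i$ over the anticipated
  linear-predictor distribution, by default at $\alpha=0,\beta=1$ (both
  overridable to study miscalibration). The logistic weight is evaluated
  via `dlogis()` so extreme linear predictors do not overflow; a constant
  linear predictor gives a singular information matrix and is rejected with
  a relative-tolerance determinant check.
* **c-statistic**: Newcombe's distribution-free standard error, inverted by
  iterative search (scan and bisection agree; SE is strictly decreasing in
  $N$).
* **Standardised net benefit** at threshold $p$: the Marsh variance
  expression with weight $w = \frac{1-\phi}{\phi}\frac{p}{1-p}$. The
  implied $sNB = sens - w(1-spec)$ is reported alongside the *net benefit*
  $NB = \phi \cdot sNB$; published tables in this literature sometimes
  print the latter under the former's name, so both are exposed.

## Adjusted (Agresti-Coull) intervals

Wald intervals misbehave for proportions near 0 or 1. The adjusted
alternative recentres at $(x+2)/(n+4)$ with half-width $z\sqrt{\tilde
p(1-\tilde p)/n}$ — the variance denominator $n$, not $n+4$, following the
convention of the planning literature this package accompanies; the
textbook $n+4$ variant is available behind a flag. No closed-form inversion
exists, so `n_measure_ac()` searches over $N$, evaluating the *expected*
interval width at real-valued expected cell counts (rounding expected
counts to integers would make the width non-monotone in $N$ and the search
ill-defined). For mid-range measure values the adjusted and Wald sample
sizes agree within 1%; for extreme values (sensitivity 0.99, NPV 0.94 at a
low threshold) the recentring pulls the adjusted estimate toward 0.5 and
the adjusted-interval sample sizes are *substantially larger* than the Wald
ones. That is a real property of the adjusted interval, not an artefact:
published adjusted-interval sample sizes that sit within a participant or
two of the Wald values for a sensitivity of 0.99 cannot have been produced
by this interval, and the package makes no attempt to match them.

## Time-to-event outcomes

For a proportional-hazards model, the predicted risk by the horizon $t^*$
is $1 - S_0(t^*)^{\exp(LP)}$. Without censoring before $t^*$ the event
status is known for everyone and the binary machinery applies directly.
With right censoring, each individual's unknown event indicator is replaced
by a jackknife pseudo-observation of the Kaplan-Meier cumulative incidence,

$$\tilde F_i(t^*) = N\,F_{KM}(t^*) - (N-1)\,F_{KM(-i)}(t^*),$$

which assumes non-informative censoring (a pragmatic choice; grouped
pseudo-values or flexible hazard regression are the usual remedies when
censoring is suspected to be informative, and are out of scope here).
Pseudo-values average exactly to $F_{KM}(t^*)$, reduce to the event
indicator when no one is censored before $t^*$, and may fall outside
$[0,1]$ under censoring.

The confusion matrix is then assembled from *expected counts*: TP is the
sum of pseudo-values over predicted positives, FP the sum of their
complements, and so on. This aggregation is chosen because it reduces
exactly to the ordinary integer matrix in the uncensored case and keeps the
outcome-proportion identity $(TP+FN)/N = F_{KM}(t^*)$ valid; out-of-range
pseudo-values are deliberately *not* clipped (clipping would break the
jackknife mean identity), so cells can be marginally negative — measure
estimates remain defined and the variance calculation clamps only the
proportion inside the square root.

Leave-one-out recomputation is $O(N^2)$; the package also derives all $N$
leave-one-out Kaplan-Meier estimates in a single pass from prefix sums of
the log survival factors (the risk set shrinks by one at every event time
up to the removed individual's time, and the event count drops by one at
their own event time). The two paths agree to $10^{-10}$ on censored
fixtures with ties, and the $O(N^2)$ form is kept as the oracle; `"auto"`
switches to the fast path above 500 individuals, and the simulation engine
always uses it.

`expected_ciw_simulation()` estimates the interval widths expected at
candidate sample sizes: for each replicate it simulates a dataset from a
`tte_scenario()` (Weibull proportional-hazards event times anchored at a
baseline survival probability, a normal or empirical linear-predictor
distribution, uniform or exponential independent censoring), computes
pseudo-values, the pseudo confusion matrix, and each measure with its Wald
interval, then averages point estimates and interval bounds across
replicates (2.5/97.5 percentiles of the replicate estimates are available
as an alternative summary). The demonstration scenario — horizon 3,
baseline survival 0.9, $LP \sim N(0, 0.8^2)$, uniform censoring on $(0,6)$
— was chosen to resemble a moderate-risk prognostic setting with roughly a
third of follow-up censored by the horizon; it is a synthetic stand-in, not
a reconstruction of any published model, whose numerical results are
validated only through the censoring-free reduction to the binary pipeline
and the $1/\sqrt N$ width scaling.

## Worked planning example

The running example used throughout the documentation and tests: predicted
risks $\sim$ Beta(1.33, 1.75) (prevalence 0.432), perfect calibration,
thresholds 0.1 and 0.3, a global width target of 0.1 — the usual
recommendation of "0.1 or less" for good precision on a proportion scale —
plus the established criteria (anticipated c-statistic 0.77, O/E width
0.22, slope width 0.3, net-benefit width 0.2).

```{r}
cfg <- plan_config(pop_spec(beta_risk(1.33, 1.75), n_sim = 2e5),
                   thresholds = c(0.1, 0.3), ciw = c(0.08, 0.1, 0.12),
                   c_statistic = 0.77, oe_ciw = 0.22,
                   slope_ciw = 0.3, snb_ciw = 0.2)
report <- run_min_samplesize(cfg)
report
```

The calibration slope binds: roughly 950 participants, more than any
threshold-based measure demands (NPV, the largest of the six, needs about
930). That ordering — calibration first — is expected to be typical, which
is why these six criteria complement rather than replace the established
ones. The reverse direction confirms the choice:

```{r}
head(run_expected_ciw(cfg, n = report$binding$n_required), 6)
```

## Choices, defaults, and limitations

* `n_sim` defaults to $10^6$ with a fixed documented seed (20250101); both
  are overridable. Vignette and some tests use smaller sizes purely to keep
  them quick; the derived values then carry proportionally larger
  Monte-Carlo error.
* The 95% critical value is the customary 1.96 — the constant the
  planning formulas are written with; other confidence levels use the exact
  normal quantile. At boundary cases a real-valued solution of, say,
  384.005 rounds up to 385, so the constant matters and is pinned.
* Measures with empty denominators return `NA` ("undefined"), never 0, so
  a report can distinguish "no predicted positives" from "zero
  performance". Wald-based closed forms refuse measure values of exactly 0
  or 1 and point to the adjusted-interval search.
* The simulation generator draws Bernoulli outcomes given the risk draws;
  it emulates a perfectly (or deliberately mis-) calibrated model and
  ignores everything a real validation sample adds: clustering, covariate
  shift, measurement error in predictors, informative censoring. Passing
  tests therefore certify the arithmetic of the planning formulas under
  the stated assumptions, not the behaviour of any model on real data.
* Power-style hypothesis-testing sample sizes, decision-curve analysis
  across a threshold continuum, exact (Clopper-Pearson) and Wilson
  intervals, multi-class macro-averaged F1, and fitting a risk distribution
  to observed validation data are out of scope.
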