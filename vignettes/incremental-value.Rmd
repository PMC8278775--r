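---
title: "Comparing risk models with Delta-AUC, Delta-AP, and Delta-sBrS"
author: "incvalue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing risk models with Delta-AUC, Delta-AP, and Delta-sBrS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incvalue)
```

## The problem

When a risk prediction model is updated — a biomarker added, or a crude
exposure measurement replaced by a precise one — the change in performance is
summarised by an *incremental value* (IncV): the new model's accuracy measure
minus the existing model's, $\Delta\Psi = \Psi_{new} - \Psi_{old}$. Different
measures can disagree. A new model can *lose* a little area under the ROC
curve ($\Delta\mathrm{AUC} < 0$) while *gaining* a great deal of area under
the precision–recall curve ($\Delta\mathrm{AP} \gg 0$), leaving the analyst
with two contradictory verdicts. The disagreement is systematic, not noise,
and it is most pronounced for rare outcomes. This package computes all the
quantities needed to understand and quantify it:

* **analytic ("true") values** of AUC, AP, and the scaled Brier score for
  risk-score distributions that are known in closed form (binormal scores) or
  derivable from a specified data-generating mechanism (probit working models
  below);
* **nonparametric estimates** of the same measures from individual-level
  samples;
* the **decomposition** that explains the disagreement, and a **scenario
  sweep** engine that maps it out across event rates and effect sizes.

## One integrand, two weightings

Write $F_1$ and $F_0$ for the CDFs of a risk score among events ($D=1$) and
non-events ($D=0$), $q_\alpha = F_1^{-1}(\alpha)$ for the event-score
quantile, and $\pi = \Pr(D=1)$ for the event rate. Then

$$\mathrm{AUC} = \int_0^1 F_0(q_\alpha)\,d\alpha, \qquad
\mathrm{AP} = \int_0^1 \left\{1 + \frac{\pi^{-1}-1}{1-\alpha}
  \left[1-F_0(q_\alpha)\right]\right\}^{-1} d\alpha .$$

$F_0(q_\alpha)$ — the proportion of non-events scoring below the
$\alpha$-th event quantile — is the *separation curve*
(`f0_at_f1_quantile()`); it fully determines both measures. For two models,
let $\Delta(\alpha) = F_{new,0}(q_{new,\alpha}) - F_{old,0}(q_{old,\alpha})$
(`delta_alpha()`). Both IncVs are weighted averages of this one curve,

$$\Delta\Psi = \int_0^1 w_\Psi(\alpha)\,\Delta(\alpha)\,d\alpha,$$

with $w_{\mathrm{AUC}} \equiv 1$ and

$$w_{\mathrm{AP}}(\alpha) = \frac{\frac{\pi^{-1}-1}{1-\alpha}}
 {\left[1+(\pi^{-1}-1)\frac{1-F_{new,0}(q_{new,\alpha})}{1-\alpha}\right]
  \left[1+(\pi^{-1}-1)\frac{1-F_{old,0}(q_{old,\alpha})}{1-\alpha}\right]}$$

(`ap_weight()`). The weight rises steeply toward $\alpha \to 1$ and rises
further as $\pi$ falls: $\Delta$AP concentrates on what the new model does
among the *highest-risk* subjects, exactly where a rare-outcome screening
model earns its keep, while $\Delta$AUC averages wins and losses evenly
across the whole risk range. `incv()` evaluates $\Delta\Psi$ both directly
and through this identity and raises an error if the two routes disagree
beyond `1e-4` — the identity is algebraically exact, so disagreement can
only mean a numerical defect.

Because AUC and AP are rank-based they are only *semi-proper*: a misspecified
model that ranks subjects like the true model ties it. The Brier score
$\mathrm{BrS} = E\{[D - p(\mathbf X)]^2\}$ is strictly proper, and splits by
outcome status into mean squared prediction errors,
$\mathrm{BrS} = \pi\,\mathrm{MSPE}_1 + (1-\pi)\,\mathrm{MSPE}_0$
(`brier_components()`). The scaled version
$\mathrm{sBrS} = 1 - \mathrm{BrS}/[\pi(1-\pi)]$ is 0 for the non-informative
model $p \equiv \pi$ and 1 for perfect prediction.

Two further single-threshold utilities round out the measure set: the average
negative predictive value $E[\mathrm{NPV}(r_0(\mathbf X))]$
(`average_npv()`), the lower-tail mirror image of AP, and the net benefit
$NB(p_t) = \pi\,\mathrm{TPR} - (1-\pi)\,\mathrm{FPR}\,p_t/(1-p_t)$
(`net_benefit()`).

### Conventions that matter

* **Binormal notation.** `binormal_spec(1.8, 2)` means mean 1.8,
  **standard deviation** 2. With the canonical hypothetical scores (events
  $N(1.8, \mathrm{sd}\,2)$ vs $N(1.5, \mathrm{sd}\,1.5)$, standard-normal
  non-events) only this reading produces the characteristic near-zero
  $\Delta$AUC ($-0.0077$) alongside a sizable $\Delta$AP; a variance reading
  flips the AUC comparison's sign.
* **Sign convention.** $\Delta\Psi = \Psi_{new} - \Psi_{old}$ everywhere.
  (A derivation can equivalently be written from the old-minus-new side with
  the integrand negated; this package uses new-minus-old throughout.)
* **The AP weight's denominators** use each model's own quantile,
  $F_{new,0}(q_{new,\alpha})$ and $F_{old,0}(q_{old,\alpha})$.

## True values under a misspecified probit working model

The numerical-study engine asks a sharper question than "is the new marker
informative": *neither* candidate model is the truth. Markers $X, Y$ are
independent standard normal and the outcome follows

$$\pi(X,Y) = \Phi(\beta_0 + \beta_1 X + \beta_2 Y + \beta_3 XY),$$

with a genuine interaction ($\beta_3 \neq 0$). The compared working models
are the one-marker probit $\Phi(\gamma_0 + \gamma_1 X)$ and the two-marker
probit $\Phi(\gamma_0 + \gamma_1 X + \gamma_2 Y)$ — both misspecified. Their
coefficients are the *population* (large-sample limit) values: the
maximizers of the expected probit log-likelihood under the true distribution
(`population_coefficients()`), so every reported IncV is a true value of a
population quantity, not a sample estimate.

### Numerical scheme

All expectations reduce to low-dimensional smooth integrals; no step is
simulated.

* **Intercept calibration** (`solve_beta0()`): integrating $Y$ out of
  $\Phi(\beta_0+\beta_1 x+(\beta_2+\beta_3 x)Y)$ is closed-form
  ($E[\Phi(a+bZ)] = \Phi(a/\sqrt{1+b^2})$), leaving a one-dimensional
  Gauss–Hermite integral over $x$ inside a bracketed root finder. Achieved
  event rates match the target to below $10^{-10}$.
* **Population coefficients**: Newton iterations with analytic Hessian on
  the quadrature-evaluated expected score; convergence is declared only when
  the gradient norm is below $10^{-8}$. The objective is concave, and step
  halving guards the iteration. Probit tail ratios such as
  $\phi/[\Phi(1-\Phi)]$ are evaluated in log space so extreme linear
  predictors at outer quadrature nodes cannot overflow.
* **Conditional score CDFs** (`score_distribution_pair()`): rotate $(X,Y)$
  so the working linear predictor $\eta = \gamma_0 + \gamma_1 X + \gamma_2 Y$
  is one coordinate, $U$, of an orthonormal pair $(U, V)$ of independent
  standard normals. Conditional on $U=u$ the true risk is $\Phi$ of a
  quadratic in $V$ — smooth, so 80-node Gauss–Hermite in $V$ converges fast
  (the one-marker model needs no quadrature at all) — and the CDFs follow
  from cumulative trapezoids of $g(u)\varphi(u)$ and $(1-g(u))\varphi(u)$
  along a 4,001-point $u$-grid spanning $\pm 10$ SD, with survival functions
  accumulated from the upper end so the tails keep relative accuracy. The
  point of the rotation is that an indicator function never meets a Hermite
  rule: tensor quadrature of the discontinuous integrand
  $1\{\eta \le c\}$ converges slowly, whereas every integrand here is smooth
  and Gaussian-decaying, for which the trapezoid rule is spectrally
  accurate.
* **Built-in exactness check**: the marginal of $\eta$ is exactly
  $N(\gamma_0, \gamma_1^2+\gamma_2^2)$, so
  $\pi F_1(c) + (1-\pi)F_0(c)$ must equal a known normal CDF at every grid
  point. `score_distribution_pair()` asserts this to $10^{-6}$ and raises an
  accuracy error otherwise; every scenario of every sweep passes through
  this check.
* **$\alpha$-integration** for AUC/AP: composite trapezoid on a uniform
  20,001-point grid over $[10^{-6}, 1-10^{-6}]$, with the bounded integrand
  extended constantly onto the clipped end strips; the survival ratio
  $[1-F_0(q_\alpha)]/(1-\alpha)$ is formed from log-survival values near
  $\alpha \to 1$. Documented accuracy is about $10^{-5}$; doubling all
  resolutions moves every IncV of random scenarios by less than
  $5\times10^{-4}$ (tested).

Defaults (`n_grid = 4001`, `nodes = 80`, `alpha_points = 20001`,
`u_max = 10`) were chosen once to meet that stability target at roughly
50–100 ms per scenario, which puts the full 3,200-scenario sweep at about
three minutes on a single core.

### The sweep

`default_scenario_grid()` crosses $\beta_1, \beta_2 \in \{0.3, \dots, 1.0\}$
(step 0.1), $\beta_3 \in \{-0.5,\dots,-0.1, 0.1,\dots,0.5\}$, and
$\pi \in \{0.01, 0.05, 0.1, 0.2, 0.5\}$: 640 scenarios per event rate, 3,200
in all. `run_sweep()` is deterministic and optionally resumable
(`cache_file`), `summarize_sweep()` reports five-number summaries (type-7
quantiles — the interpolation rule is stated because it is not prescribed
anywhere) and negative-scenario counts, and `incv_agreement_table()` reports
Pearson correlations plus a concordance measure: the proportion of scenarios
in which two IncVs share a sign class ($>0$ versus $\le 0$; an exact zero
counts as $\le 0$) minus the proportion in which they differ.

With the default grid the package computes, at $\pi = 0.01$: median
$\Delta$AUC 0.080 (IQR 0.094), median $\Delta$AP 0.148,
$\mathrm{cor}(\Delta\mathrm{sBrS}, \Delta\mathrm{AP}) = 0.995$ with
concordance 0.931, and
$\mathrm{cor}(\Delta\mathrm{sBrS}, \Delta\mathrm{AUC}) = -0.111$; across all
3,200 scenarios $\Delta$AUC is negative 29 times and $\Delta$AP 389 times.
The acceptance suite compares these against published reference values for
this exact design: every sign-based count and every correlation/concordance
value reproduces at printed precision, but the quoted medians/IQRs do not
(e.g. a quoted $\pi=0.01$ median $\Delta$AP of 0.21 versus the computed
0.148). A Monte-Carlo cross-check at $n = 2\times10^7$ on a median-region
scenario confirms the quadrature values, and the reference text is
internally inconsistent on this point (it quotes an all-positive
$\Delta$AP range at $\pi = 0.5$ while its own concordance of 0.922 there
requires some $\Delta\mathrm{AP} \le 0$). The corresponding assertions are
kept at reference tolerance and left failing rather than loosened.

## Empirical estimators

From a sample $(D_i, \hat r_i)$, `estimate_auc()` is the Mann–Whitney
proportion of event/non-event pairs ranked correctly, computed by sorted
counting in $O(n\log n)$ and proven (in tests) identical to the $O(n^2)$
double sum, ties included. Tied pairs count 0 by default (`ties = "zero"`,
the strict-inequality form) with a mid-rank option.

`estimate_ap()` averages, over events, the precision of "call positive at or
above this event's score". The default comparison is $\ge$ in both numerator
and denominator, so each event's own record counts and every term is
well-defined (denominator $\ge 1$) even with ties. The literal
strict-inequality form is available (`comparison = "strict"`); it makes the
top-ranked event a $0/0$ term, which is dropped from both the sum and the
event count. Both conventions converge to the same population AP for
continuous scores.

`estimate_brier_sbrs()` needs predicted risks, not just scores, and returns
the full MSPE split. `empirical_pair()` exposes a sample as stepwise ECDFs
so the analytic machinery ($\Delta(\alpha)$ curves, weights, curve tables)
applies verbatim to data; quantiles use the left-continuous ECDF inverse
$\hat q_\alpha = \inf\{c : \hat F_1(c) \ge \alpha\}$, a documented choice —
nothing prescribes how the discrete jumps should be handled, and this
inverse makes `auc(empirical_pair(s))` equal `estimate_auc(s)` exactly for
tie-free scores.

AP with an *external* event rate (`ap(pair, pi)` on an `empirical_pair`
built from case-control data) is the supported path for designs in which
$\hat\pi$ from the sample is meaningless; inverse-probability weighting is
out of scope.

## What the generators emulate — and what they do not

`sample_true_model()` and `sample_binormal()` reproduce exactly the
distributional assumptions above (independent standard-normal markers,
probit outcome; or Bernoulli status with conditional-normal scores), with an
explicit seed on every call and restoration of the caller's RNG state.
`fit_probit()` is a self-contained Newton MLE, so the oracle chain
(generate, fit, estimate, compare with the analytic truth) has no moving
part outside the package.

Passing tests on these generators therefore validates the *estimators and
the analytic engine*, not the realism of any particular clinical dataset:
real risk scores are bounded, often heavily tied, calibrated imperfectly,
and collected under censoring or case-control sampling. Time-to-event
outcomes, NRI/IDI, confidence intervals for estimated IncVs, and
decision-curve analysis beyond the single net-benefit formula are all out of
scope.

## Degenerate inputs and edge behaviour

* A point-mass event distribution has no quantile function: a
  degenerate-distribution error.
* Samples without both outcome classes: rank metrics and sBrS refuse with
  explicit errors.
* `curve_points()` beyond the score support returns the limiting PPV/NPV
  from the interior rather than 0/0.
* `ap_weight()` and the AP integrand are evaluated in survival/log-survival
  form; the useless-model limit $w_{\mathrm{AP}} = \pi(1-\pi)/(1-\alpha)$ is
  recovered to $10^{-9}$.
* Grid pairs apply piecewise-linear interpolation between tabulated CDF
  values and resolve flat stretches to their left edge; all rank quantities
  are exactly invariant under monotone relabelling of the threshold axis.

## Worked example

```{r example, eval = FALSE}
r1 <- make_binormal_pair(binormal_spec(1.8, 2))    # new score
r2 <- make_binormal_pair(binormal_spec(1.5, 1.5))  # existing score

incv(r2, r1, pi = 0.05, metric = "AUC")   # -0.0077: r1 slightly *loses* AUC
incv(r2, r1, pi = 0.05, metric = "AP")    # +0.0968: r1 clearly gains AP

scenario_incv(1, 0.8, 0.2, 0.01)[, c("d_auc", "d_ap", "d_sbrs")]
#  0.0574    0.334    0.226
```

The disagreement in the first pair is the package's subject in miniature:
$\Delta(\alpha) < 0$ at lower quantiles and $> 0$ at upper ones, the uniform
AUC weight nets them out to almost zero, and the AP weight — two orders of
magnitude larger at $\alpha = 0.9$ than at $\alpha = 0.1$ when $\pi = 0.05$
— rewards the upper-tail gain.
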