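---
title: "Item reduction by running-total AUC: models and design choices"
author: "rocreduce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Item reduction by running-total AUC: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rocreduce)
```

## The problem

Clinical and behavioural rating scales — a depression inventory with 21
items scored 0–3 is the motivating case — are expensive to administer in
full, and many items contribute little to the decision the scale is
actually used for: predicting an external binary diagnosis. `rocreduce`
shortens such a scale while holding (or improving) its predictive
accuracy, and supplies two independent lenses for judging the shortened
scale: item response theory (a graded response model) and classical
reliability from factor loadings.

## The reduction method

Let item $i$ have ordinal score $x_i \in \{0, \dots, m_i\}$ and let
$d \in \{0, 1\}$ be the diagnosis. For any score $s$, the ROC curve is the
staircase of (FPR, TPR) pairs produced by sweeping the positivity cutoff
("positive" means $s \ge c$), and

$$\mathrm{AUC}(s) = \Pr(s_{\text{pos}} > s_{\text{neg}})
  + \tfrac12 \Pr(s_{\text{pos}} = s_{\text{neg}}),$$

the probability that a random positive outranks a random negative, ties
credited one half. The procedure is:

1. compute $\mathrm{AUC}(x_i)$ for every item (`item_aucs()`);
2. order items by descending individual AUC, ties broken by input order;
3. trace $\mathrm{AUC}\!\left(\sum_{j \le k} x_{(j)}\right)$ for
   $k = 1, \dots, K$ — the running-total curve (`running_total_auc()`);
4. keep the prefix at the curve's global maximum (`select_peak()`),
   shortest prefix on ties.

Because the last point of the running-total curve *is* the full scale's
total-score AUC, the selected subset never predicts worse than the full
scale. The ranking is computed once from individual AUCs; there is no
stepwise re-ranking and no exhaustive subset search — the contribution of
the method is precisely this cheap, transparent ordering.

The ordering direction deserves a note: ranking *descending* by
individual AUC is what makes the running-total curve start at the
strongest single item and rise steeply; the shipped worked-example tables
(see below) confirm that this ordering reproduces the published running
sequence of the study that motivated the package.

### Tie handling and the Gini identity

Tied score values collapse into a single ROC vertex, and the rank route
credits tied positive–negative pairs one half. Under exactly this
convention the trapezoidal area under the staircase equals the
Mann–Whitney form to machine precision — the package carries both routes
and the test suite asserts their equality on thousands of tied instances,
so either can be treated as the definition.

The Gini coefficient is the rescaling $G_1 = 2\,\mathrm{AUC} - 1$. A
staircase form without the trapezoid's $\tfrac12$ factor,
$G_1 = 1 - \sum_k (X_k - X_{k-1})(Y_k + Y_{k-1})$, holds exactly when the
curve is traversed with $X = \mathrm{TPR}$, $Y = \mathrm{FPR}$: the sum is
then twice the area between the curve and the TPR axis, i.e.
$2(1 - \mathrm{AUC})$. `gini_trapezoid()` implements that convention as a
cross-check on `gini()`.

### Polarity

Higher item scores are assumed more disease-like; items are never flipped
silently. `flip_negative_items = TRUE` opts in to reverse-scoring items
whose individual AUC falls below 0.5 (category $m - x$), in which case
the running totals use the reversed scores too.

## The graded response model

Validation asks whether the selected items are also the ones an IRT
analysis flags as discriminating. The graded response model gives item
$i$ a discrimination $a_i > 0$ and ordered thresholds
$b_{i1} < \dots < b_{im}$ on a standard-normal latent trait $\theta$,
with cumulative category curves
$P(X_i \ge k \mid \theta) = \operatorname{logistic}(a_i(\theta - b_{ik}))$
and category probabilities as adjacent differences.

`grm_fit()` maximizes the marginal likelihood, integrating $\theta$ out
with 61-node Gauss–Hermite quadrature (fixed nodes; the standard-normal
prior identifies the scale). Optimization is quasi-Newton (BFGS) with
analytic gradients on a transformed parameterization — $\log a_i$ for
positivity, first threshold plus log-spacings for strict ordering — run
in restarts whose recorded log-likelihood sequence must be non-decreasing;
the restart loop stops when the improvement falls below `tol` ($10^{-5}$
by default). Duplicate response patterns are collapsed before evaluation.
Starting values are $a_i = 1$ with thresholds read off the marginal
cumulative proportions. Categories never observed in the data are
collapsed out with a warning, since their probabilities are not
estimable by maximum likelihood.

The constrained variant shares one discrimination across items
($Km + 1$ parameters for equal category counts) and is compared with the
unconstrained one ($K(m+1)$ parameters) by
`likelihood_ratio_test()`: statistic $2(\ell_u - \ell_c)$, $\chi^2$ with
$K - 1$ degrees of freedom. A negative statistic beyond numerical
tolerance is reported as a fitting failure rather than clamped silently.

Item Fisher information is
$I_i(\theta) = a_i^2 \sum_k (u_k - u_{k+1})^2 / P_k$ with
$u_k = F_k(1 - F_k)$; for a dichotomous item this reduces to
$a^2 F(1-F)$, peaking at $a^2/4$ at $\theta = b$. `test_information()`
integrates the summed curve by a 1000-point trapezoid over
$(-10, 10)$ and reports both the grid total and the share inside
$(-4, 4)$, where virtually all respondents lie; both the absolute subset
information and its percentage of the subset total are reported, since
either may be the quantity of interest.

## Reliability from factor loadings

For standardized loadings $\lambda_i$ with error variances $\delta_i$,

$$\mathrm{CR} = \frac{(\sum_i \lambda_i)^2}
  {(\sum_i \lambda_i)^2 + \sum_i \delta_i}, \qquad
  \mathrm{VE} = \frac{\sum_i \lambda_i^2}{n}.$$

Loadings are *inputs* (from any CFA tool); fitting the factor model is
out of scope. When $\delta$ is not supplied it defaults to
$1 - \lambda^2$, the standardized-solution convention. The acceptability
flag in `compare_scales()` uses the conventional CR $\ge 0.7$ cut, the
threshold the measurement literature the formulas come from treats as
adequate.

## The synthetic study generator

`study_scenario()` emulates the shape of a school-based screening study:
21 items with 4 categories, one latent severity trait, a planted subset
of 6 genuinely informative items (default positions 1, 7, 9, 10, 14, 15),
and a diagnosis defined by thresholding the *same* trait —
`qnorm(0.8)`, i.e. 20% expected prevalence, a typical elevated-symptom
rate in adolescent samples. Discriminations default to 1.8 (informative)
vs 0.4 (background), thresholds $(-0.5, 1.0, 2.4)$ for every item, values
in the range fitted graded models report for real depression
inventories. `bdi_style_fixture()` is this default scenario at $n = 1500$.

What the generator does *not* emulate: diagnostic error (the criterion is
deterministic given the trait, so simulated AUCs — informative items
around 0.81–0.83 — run higher than the 0.59–0.73 per-item band real
studies report), multidimensionality, item-specific threshold variation,
and missing data. Passing tests on this generator therefore demonstrate
the machinery recovers planted structure under clean conditions, not that
any particular real scale will shorten as gracefully.

## Numerical choices and problem sizes

* Quadrature: 61 Gauss–Hermite nodes; information grid 1000 trapezoid
  points on $(-10, 10)$.
* AUC routes are exact (rank arithmetic), no smoothing, no confidence
  intervals; tied thresholds are collapsed, never jittered.
* Peak ties resolve to the fewest items — when two subsets predict
  equally well, the simpler scale is preferred.
* Listwise deletion for missing cells at read time, with a warned count;
  no imputation.
* The simulation studies the package ships run at: 1000 random tied
  instances for dual-route agreement; 20 replicates of $n = 2000$,
  $K = 6$ for parameter recovery; 500 replicates of $n = 300$, $K = 5$
  for the likelihood-ratio test's type-I error; 50 replicates of the
  $n = 1500$ fixture for selection recovery. These sizes give
  Monte-Carlo error comfortably inside the tolerances being asserted.

## Known limitations

* Greedy ordering by individual AUC is not optimal subset selection;
  strongly redundant items can enter the prefix before a complementary
  weaker item.
* The GRM fitter targets unidimensional logistic graded models only — no
  guessing parameter, no multidimensional traits, no Bayesian posterior.
* Reported AUCs are in-sample; there is no cross-validation, so peak
  positions on small samples are optimistic.
* CR/VE depend entirely on the loadings supplied; with the
  $1 - \lambda^2$ default they assume a standardized solution without
  correlated errors.
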