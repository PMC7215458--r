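---
title: "Societal risk analysis of hazmat transportation accidents with hazfn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Societal risk analysis of hazmat transportation accidents with hazfn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazfn)
```

hazfn analyses hazardous-materials transportation accident (HTA) records in
three stages — characteristics, cause, severity — around one central object:
the F-N curve of fatal accidents, with the uncertainty of its log-log slope
modelled explicitly. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, what the synthetic
generator does and does not emulate, and the known limitations.

## The data model and severity grading

A record set (`hta_records`) is one row per accident: timestamp (ISO date
plus hour of day, hour bins `[h, h+1)` in local time), province, a
non-empty set of ADR hazmat classes 1–9 (semicolon-separated in files, since
commas delimit fields), species, accident taxonomy (twelve specific types,
of which types 1–7 are collisions and 8–12 non-collisions — the coarse
`accident_type` must agree with the specific type), a cause factor
(environment, management failure, equipment malfunction, driver error), road
level, and the three consequence counts: deaths, serious injuries, direct
economic loss in units of 10^4 yuan.

`classify_severity()` grades each accident into China's five levels. Each
consequence dimension triggers a level on its own and the accident receives
the most severe triggered level; the classification is therefore total and
monotone in every argument. The official wording is ambiguous at the exact
cut points ("more than 3 … but less than 10"), so boundaries are closed on
the more severe side: 3 deaths is Level III, 10 is IV, 30 is V, and
analogously for injuries (10/50/100) and loss (10/50/100 million yuan). One
further reading is required for consistency: taken literally, Level II's
"loss below 10 million yuan" clause would make *every* accident at least
Level II, contradicting "Level I means no deaths and serious injuries". We
therefore let loss below 10 million yuan trigger nothing, so Level I is an
accident with no deaths, no serious injuries and loss under that threshold.

Accidents carrying k hazmat classes are expanded by `expand_multiclass()`
into k identical single-class cases before tree modelling; the case count at
the tree root therefore exceeds the accident count. Note that the expanded
cases are no longer statistically independent — see the CHAID caveats below.

## The F-N curve

For fatal accidents grouped by death toll, the cumulative frequency of N or
more deaths is the within-sample survival ratio

$$F_j = \frac{\sum_{i \ge j} n_i}{\sum_i n_i},$$

so the smallest group always has F = 1. No per-year normalisation is
applied: F is a relative frequency within the surveyed accidents, not an
events-per-year rate, and criterion-line intercepts must be interpreted on
that same scale. Per-group slopes are `lgF_i / lgN_i`, undefined for the
N = 1 group where lgN = 0.

The packaged `hta_fn_table()` (19 fatality groups of 370 fatal Chinese HTAs,
2004–2018) exists in two pathways. The published table's F column is not
exactly the count ratio (it prints 0.480 where 177/370 = 0.478), so
`printed = TRUE` returns the published columns verbatim — the pathway on
which the published fit parameters are reproduced — while
`printed = FALSE` recomputes everything from the group counts at full
precision, which is the pathway used for any new data. All downstream fits
read the series' columns, so the choice is made once, at loading.

## Slope-uncertainty models

`fit_normal()` summarises the defined per-group slopes by their mean μ and
sample standard deviation σ (n − 1 denominator). Its `interval_95`,
μ ± 1.96σ, is a **population dispersion interval** — the plausible range of
the slope itself — not a standard-error confidence interval for μ. This is
deliberate: the downstream fatality-ratio bounds
(`fatality_ratio(a, n1, n2) = (n2/n1)^a` evaluated at the interval
endpoints) are meant to bracket the consequence ratio under slope
uncertainty, which requires the dispersion interval.

`fit_improved_normal()` fits
$$f(x) = B + \frac{D}{\sigma\sqrt{\pi/2}}\, e^{-2(x-\mu)^2/\sigma^2}$$
to the histogram densities of the slopes by Levenberg–Marquardt least
squares. B absorbs a baseline offset and D the amplitude, freeing the curve
from integrating to one; note σ here is *not* the normal-density standard
deviation (the exponent uses 2/σ² rather than 1/(2σ²)). Histogram-space
metrics depend on the binning, which published analyses rarely state; the
binning is therefore an explicit argument everywhere (`bins`), defaulting to
Sturges' rule with exact equal-width breaks over the sample range, and the
test suite documents (without asserting a value) that changing the bin count
changes R². Starting values come from the sample moments; for this model
`interval_95` is the t-based confidence interval of μ from the curve fit,
since a dispersion interval of the non-standard σ has no direct use.

`fit_powerlaw_loglog()` is ordinary least squares of lgF on lgN over all
groups, *including* the pinned (0, 0) point of the N = 1 group, with
t(n − 2) intervals for both coefficients. `fit_powerlaw_linear()` fits
F = C·N^(−a) by unweighted nonlinear least squares in linear F space
(started from the log-log fit), computing R² on the F values and the
degree-of-freedom-adjusted RMSE √(SSE/(n − 2)), with Wald/t(n − 2) intervals
from the Jacobian linearisation. Both fit spaces are exposed and labelled
(`fit_space`) because they answer different questions: the log-space fit is
the statistically conventional estimator and drives band construction for
new data, while the linear-space fit is what standard curve-fitting toolbox
output reports for a cumulative-frequency series — on the packaged series it
gives R² = 0.9936 and RMSE = 0.0197, and its t-based parameter intervals,
a ∈ (1.2286, 1.3785) and C ∈ (0.9757, 1.0570), are the source of the
uncertainty band. Including the (N = 1, F = 1) point is required for the
linear-space metrics to take these values; excluding it changes both.

`select_model()` ranks fits by descending R², ties broken by ascending RMSE,
stably in input order. On the packaged series the ranking is power law,
adjusted normal, normal — but note the three R² values live in different
spaces (linear F space vs histogram-density space), so the ranking is a
pragmatic device, not a likelihood comparison.

`fn_band()` turns a fit with intervals into a three-line band: the lower
(optimistic) edge pairs the steepest slope with the smallest C and the upper
(pessimistic) edge the shallowest slope with the largest C, so the band
nests the central line for every N ≥ 1. Slope-distribution fits yield bands
through the origin of the log-log plane (C = 1), as their lines are defined
by slope alone.

## ALARP classification

`default_lines()` encodes risk-neutral (a = 1) limit lines with intercepts
0.1 (tolerable) and 0.001 (acceptable — 1% of the tolerable intercept).
Points above the tolerable line are unacceptable, points below the
acceptable line broadly acceptable, anything between tolerable-if-ALARP.
Points exactly on a line belong to the less severe zone, the conventional
"up to and including" reading of a limit line.

`assess_curve()` classifies each band edge at each supported N and
summarises the central curve by the worst zone it attains; the N range of
that summary is configurable. By default the assessment refuses N outside
the observed fatality support: readings like "the risk becomes acceptable
beyond X deaths" typically extrapolate the fitted line far beyond any
observed accident, so they require `extrapolate = TRUE` and should be
reported as extrapolations. `crossing_fatalities()` gives the closed-form
crossing N\* = (C_c/C_l)^(1/(a_c − a_l)) behind such statements, flagging
parallel and identical lines as degenerate.

## The CHAID cause–consequence tree

`build_tree()` grows a CHAID tree with the severity level as target.
At each node, for each candidate predictor, categories whose target
distributions do not differ are merged stepwise: the pair with the largest
chi-square p-value is merged while that p-value exceeds `alpha_merge`
(adjacent pairs only for ordinal predictors — here the four day periods;
all other predictors are nominal). The merged table's Pearson p-value is
then multiplied by Kass's Bonferroni factor, the number of ways the
original c categories can be reduced to the final r groups:
$$B_{nominal} = \sum_{i=0}^{r-1} (-1)^i \frac{(r-i)^c}{i!\,(r-i)!}, \qquad
B_{ordinal} = \binom{c-1}{r-1}.$$
The node splits on the predictor with the smallest adjusted p-value if it
is at most `alpha_split` and the size constraints hold; if the best
predictor's split would produce a child smaller than `min_child`, the node
becomes a leaf (we deliberately do not fall back to the second-best
predictor: that keeps tree size monotone in the stopping parameters, which
the test suite asserts). Defaults — `alpha_merge = alpha_split = 0.05`,
`min_parent = 20`, `min_child = 10`, `max_depth = 3` — are conventional
CHAID settings. Missing values are excluded listwise with a logged count.
Prediction routes by merged-group membership, returns the leaf's modal
level with ties broken toward the more severe level (conservative for risk
management), and routes categories unseen at a split to the largest child,
flagging the count.

Two caveats. First, expanded multi-class cases are duplicated rows; the
chi-square tests treat them as independent, which overstates significance —
the same approximation the case-expansion design always makes, worth
remembering when reading adjusted p-values. Second, CHAID applies no
across-predictor multiplicity correction: with m predictors tested at
α = 0.05 the probability of *some* spurious split under complete
independence is about 1 − 0.95^m (≈ 26% for the six default predictors).
Both effects are measured, not hidden, in the test suite.

`confusion_matrix()` evaluates predictions as a K×K table (rows actual,
columns predicted) with per-row correct percentages and overall accuracy
(trace/total); `node_report()` gives a node's case share and class
percentages to one decimal.

## Spatial clustering

`correlation_screen()` retains regional features whose correlation with
accident counts exceeds 0.6 and selects among them the least mutually
correlated pair — correlated-with-outcome but minimally redundant cluster
features. Features are z-scored before clustering (`standardize = TRUE`)
since regional indicators are on incommensurate scales. `elbow_sse()`
reports within-cluster SSE per k (best of 10 restarts, seeded) with
curvature-based elbow candidates that are advisory only: the final k is
adjudicated by `validate_clusters()`, which requires a significant one-way
ANOVA *and* all Tukey HSD pairwise comparisons significant at 0.05 on the
per-region scores. The default score is the first principal component of
the standardized selected features, oriented positively with the features —
"comprehensive factor score" constructions are rarely fully specified in
published analyses, so the scoring function is pluggable and this default
is a documented package choice, not a canonical definition. Singleton
clusters are excluded from the tests with a warning.

## The synthetic generator

`generate_records()` emulates the structure of the surveyed Chinese HTA
records: categorical marginals default to the observed 569-case
distributions (`hta_category_marginals()`), the accident type is derived
from the specific type so the taxonomy invariant holds by construction, and
death tolls come from `generate_deaths()`, which plants a discrete power
law on the survival function — P(deaths ≥ N) = N^(−a\*) for N = 1..60 —
so the planted exponent *is* the F-N slope that downstream fits recover.
The truncation at 60 deaths mirrors the observed range (maximum 58); the
default exponent 1.34 is the observed slope magnitude. The number of hazmat
classes per accident is 1/2/3 with probabilities 0.5/0.45/0.05, chosen once
so that the expected expansion ratio (≈1.55 cases per accident) matches the
observed 569/371. Injuries and losses are light-tailed noise around
plausible magnitudes — they exist so severity grading has all three inputs,
not to match any survey. Planted cause→consequence rules override the
consequence distribution of a chosen cause factor, drawing the death toll
uniformly within the planted level's death range; this is what decision-tree
recovery experiments use. `generate_regions()` draws Gaussian cluster
profiles and links accident counts to the features through a latent score
with configurable correlation (default 0.9, comfortably above the 0.6
screening threshold).

The generator does **not** emulate temporal seasonality, spatial
autocorrelation, between-variable dependence beyond the planted rules, or
reporting artefacts of real accident databases (under-reporting of minor
accidents, rounded loss figures). Passing tests on generated data therefore
demonstrate the pipeline's statistical behaviour under the stated model,
not the fidelity of any real-world database.

## Numerical choices and degenerate inputs

Base-10 logarithms throughout; published-table emulation rounds to 3
decimals only in display, never internally. A 2-group series is fitted
exactly by the log-log line (zero-width intervals, undefined RMSE); the
other fits refuse it. Zero-residual fits are legitimate (R² = 1, RMSE = 0).
Zero-variance targets, degenerate contingency tables (fewer than two
non-empty rows or columns), non-positive freight volumes, and k exceeding
the number of regions are errors with specific messages. Nonlinear fits use
Levenberg–Marquardt (minpack.lm) with moment-based starts and report
non-convergence rather than guessing. All stochastic operations take
explicit seeds; k-means uses 10 restarts by default.

The test suite runs its heavier properties at fixed, stated sizes: slope
recovery uses 200 replicates of 370 fatal accidents (the survey scale),
point-estimate recovery 10 replicates of 5000, the CHAID independence
experiment 100 replicates of 371 single-class records, and the end-to-end
smoke property 50 random configurations of 80–200 accidents.

## Known limitations

* **OLS intervals on cumulative curves are too narrow.** The points of an
  F-N series are cumulative tail frequencies and hence strongly positively
  correlated; the iid-error standard errors of both power-law fits
  understate the sampling variability of the slope estimate several-fold.
  Replicated experiments in the test suite show the nominal 95% interval
  covering a planted exponent well under half the time at survey scale,
  and even the dispersion interval μ ± 1.96σ reaches only ≈87% coverage.
  The intervals faithfully implement the standard curve-fitting
  constructions — but for honest frequentist coverage of a tail exponent, a
  maximum-likelihood discrete power-law estimator with its asymptotic or
  bootstrap variance would be needed, which is a documented extension, not
  part of this package.
* The slope-distribution and power-law treatments answer subtly different
  questions (dispersion of local slopes vs parameter uncertainty of one
  global line); their R² values live in different spaces, so model ranking
  is indicative.
* CHAID p-values are anti-conservative on expanded multi-class cases and
  carry no across-predictor correction (see above).
* The severity classifier's boundary conventions and the loss-clause
  reading are package decisions where the official wording is ambiguous;
  they are stated prominently in `?classify_severity`.
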