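---
title: "Equivalent Score norms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent Score norms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esnorms)
```

## The norming model

`esnorms` scores a clinical test against a normative sample in three
stages, each with its own statistical footing.

**1. Demographic adjustment.** Raw scores are regressed by ordinary least
squares on transformed demographic covariates, and each score is corrected
by the fitted demographic contribution relative to the sample-mean
reference values:

$$\text{adjusted}_i = \text{raw}_i - \sum_j \hat\beta_j\,
  \bigl(t_j(x_{ij}) - \bar t_j\bigr).$$

Centering at the fitting-sample means makes the mean adjustment zero, so
the adjusted and raw distributions share their location. All declared
covariates are kept: normative studies differ on significance-based
predictor selection, and silently dropping predictors changes the norms,
so selection is left to the user. Transforms default to the identity for
age and education and a 0/1 contrast for two-level sex, with `log` and
`sqrt` (or any R function) available per covariate; the underlying
normative literature uses various transforms without a single convention,
so the default is declared rather than inferred. Adjustment assumes the
demographic effects are additive and homoscedastic; it removes linear (or
user-transformed) trends, not distributional shape, and the adjusted
scores may remain skewed — which is precisely why the later stages are
non-parametric.

**2. Non-parametric tolerance limits.** Let p be the deficit-tail
proportion (default 0.05) and 1 − α the confidence (default 0.95). For the
k-th worst observation of a sample of n, the probability that at most
k − 1 population-deficit cases fall below it is binomial, which gives two
rank rules:

* **Outer tolerance limit (OTL):** the largest k with
  $F_{\mathrm{bin}}(k-1;\,n,\,p) \le \alpha$. With 95% confidence, no more
  than 5% of the population scores worse than this observation; a score
  beyond it supports a diagnosis of pathology at a controlled error rate.
* **Inner tolerance limit (ITL):** the smallest k with
  $F_{\mathrm{bin}}(k;\,n,\,p) \ge 1-\alpha$. A score better than it
  supports a diagnosis of normality; the zone between the two limits is
  reported as an `uncertain` flag, never as a category of its own.

These rules reproduce every published rank pair we use as ground truth
(n = 100: 2/9; n = 300: 9/21; n = 600: 21/39; n = 1000: 39/62). A wording
subtlety is worth recording: the verbal definition of the ITL ("no less
than 5% score below it, with 95% probability") literally corresponds to
$F_{\mathrm{bin}}(k-1) \ge 1-\alpha$, which would give 63 rather than 62
at n = 1000. We implement the rule consistent with the published rank
tables and document, rather than resolve, the discrepancy; a consequence,
checked by Monte Carlo in the test suite, is that the ITL order statistic
clears the true 5th percentile with probability slightly below the nominal
0.95 (about 0.93 at n = 300), while the OTL side attains 0.966 ≥ 0.95.

At the defaults the OTL exists only for n ≥ 59
($(1-p)^n \le \alpha$); smaller samples raise an explicit error naming the
minimum, never a silent clamp. A parametric counterpart
($\bar x - k_{n}\,s$ with the noncentral-t k-factor) is provided for
normally distributed data as a cross-check; it is not used in norm
construction.

**3. Subdivision into ES0–ES4.** The OTL bounds ES0 and the median bounds
ES4; these two anchors are method-independent. The interior boundaries
come from one of three rules: equal thirds of the *rank* interval
(`rank`, the recommended method; `step = floor((m - k_{OTL})/3)`), equal
thirds of the *standardized score* interval from the OTL score to the
sample mean (`zscore`), or equal thirds of the *raw score* interval from
the OTL score to the median score (`direct`). Only the rank rule
guarantees equal category densities irrespective of distributional shape;
the other two agree with each other on Gaussian data and drift apart with
skewness, which is the core argument for rank subdivision.

## Conventions that required a decision

**Median rank and direction.** The median observation is the one at
ascending-score position $\lceil (n+1)/2 \rceil$ (the upper-middle
observation for even n). Counted from the deficit tail this is rank 151
for n = 300 when the deficit is the low end, but rank 150 when the deficit
is the high end (timed tests). We deliberately define the median on the
score scale rather than symmetrically in deficit ranks: it keeps the
ES3/ES4 anchor at the same observation regardless of scoring direction,
at the price of a one-rank asymmetry between the two directions for even
n (ES1/ES2/ES3 densities 47/47/47 versus 47/47/48 at n = 300). For odd n
the two conventions coincide.

**Thirds rounding.** The integer step is `floor(span/3)` and the second
cutoff is `otl + 2*step`, so the remainder of the division (0, 1 or 2
ranks) accrues to the block adjoining the median. ES1 and ES2 therefore
always have exactly equal counts, and ES3 exceeds them by `span mod 3` at
most 2 (n = 250: 39/39/41). The alternative `floor(2*span/3)` placement
disagrees with the published reference ranks (e.g. at n = 225) and is not
used.

**Boundary membership.** A score exactly on an interior boundary (b0, b1,
b2) is assigned to the worse category — the OTL is read as the limit *of*
ES0 — while a score exactly at the median boundary is ES4. Both choices
are configurable (`boundary_rule`, `median_rule`) because published
practice does not pin them down. Density tables use the `median_rule =
"es3"` convention (median observation counted in ES3), under which the
ES1–ES3 counts equal consecutive boundary-rank differences; batch
classification with that same flag reproduces the density report exactly,
and with the default flag differs only by the median observation itself.

**Ties.** Boundary scores are order statistics; when tied values straddle
a boundary rank all tied observations take the boundary's (worse)
category, so equal-density holds up to the tie-class size. The nearest
observation to a score-based cutoff breaks distance ties toward the
median — the less pathological rank, conservative against over-diagnosis
— with `tie = "deficit"` available.

**z anchor.** The z-score method anchors z = 0 at the sample mean, which
matches its behaviour on Gaussian data (boundary ranks near 120 and 278
at n = 1000). Whether the anchor should instead be the median for skewed
samples is an open question in the source practice; we keep the mean and
note that on skewed data the z method is mis-specified regardless of the
anchor — that is the argument for rank subdivision, not a defect to patch.

## The synthetic generators

`generate_sample()` provides the three archetypes used for method
comparison, each calibrated once to plausible clinical landmarks:

| kind | distribution | defaults | emulates |
|---|---|---|---|
| `skew_lower_better` | 20 + Lognormal(log 22.35, 0.45), n = 300 | median ≈ 42.4, ~97th pct ≈ 72.7 | execution/reaction time |
| `skew_higher_better` | 50·Beta(1.54, 0.665), n = 300 | median ≈ 38.2, ~3rd pct ≈ 6.8 | recall with ceiling |
| `gaussian` | Normal(50, 10), n = 1000 | — | well-behaved adjusted scores |

Both skewed kinds reject Shapiro–Wilk normality decisively (p < 0.001 at
n = 300), the Gaussian kind does not. The generators emulate
distributional class, direction and rough score range only: they are
continuous (no integer scores, no ties), have no measurement error model,
and their demographics are independent of the score unless you construct
them otherwise. Passing tests therefore demonstrate the rank machinery
and the direction of the method contrasts, not the exact interior
boundary ranks a particular real (or externally simulated) normative
dataset would give, which depend on the realized sample.

## Numerical and scale choices

Sample standard deviations use the n − 1 denominator. Internal arithmetic
is at full precision; scores are rounded to 2 decimals only for display.
Displayed trisection cutoffs computed from endpoints that are themselves
rounded to 2 decimals are determined only to about one unit in the last
digit. Shapiro–Wilk is delegated to `stats::shapiro.test` (3 ≤ n ≤ 5000);
binomial and noncentral-t quantities to `stats::pbinom`/`stats::qt`. The
Monte-Carlo checks in the test suite use 2000 replicates of n = 300 for
tolerance-limit coverage and 200 replicates of n = 1000 for the
Gaussian-data method comparison; these sizes put the binomial standard
error of a coverage estimate near 0.005 and the median boundary rank
within a couple of ranks of its centre.

One quantitative caveat from those simulations: the z-score and direct
methods differ per sample by a fraction of the sample mean–median gap, so
although their *typical* boundary ranks coincide (medians within 1–2
ranks across replicates), per-replicate agreement within ±2 ranks occurs
in well under 95% of Gaussian samples (about 85% at the ES1/ES2 boundary
and 40% at ES2/ES3 for n = 1000). "The two methods give the same results
on normal data" is a statement about their population boundaries, not
about rank-level agreement in any finite sample.

## Limitations

* One-sided limits only: lateralized scores needing deficit tails on both
  sides (e.g. spatial neglect) are out of scope.
* No continuous norming across age and no percentile smoothing; norms are
  built from one undivided adjusted sample.
* The ordinal ES scale is coarse by design; it is not suited to measuring
  small longitudinal change.
* The intermediate boundaries are the aleatory part of the method under
  any subdivision rule; the clinically decisive anchors remain the OTL
  and the median, which all three methods share.
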