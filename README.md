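# esnorms

Equivalent Score norms for clinical test scores, built on one-sided
non-parametric tolerance limits.

## The problem

Neuropsychological (and many other clinical) tests are interpreted against
norms drawn from a healthy reference sample. The Equivalent Score (ES)
method is the standard non-parametric scheme for this: raw scores are first
adjusted for demographic effects (age, education, sex) estimated by
multiple regression on an undivided normative sample, and each adjusted
score is then mapped to an ordinal five-point scale:

- **ES0** — defective: worse than the **outer tolerance limit (OTL)**;
- **ES1** — borderline; **ES2** — low-end normal; **ES3** — normal;
- **ES4** — normal: at or beyond the **median** of the normative sample.

The OTL is the order statistic guaranteeing, with confidence 1 − α = 0.95,
that no more than p = 5% of the population scores beyond it on the deficit
side; the **inner tolerance limit (ITL)** is the matching inside bound, and
scores between the two are of uncertain classification. Both are pure rank
statements from the binomial distribution. Counting ranks k = 1, 2, … from
the deficit tail:

- OTL rank: the largest k with `F_bin(k − 1; n, p) ≤ α`,
- ITL rank: the smallest k with `F_bin(k; n, p) ≥ 1 − α`,

where `F_bin` is the binomial CDF. At n = 300 these are the 9th and 21st
worst observations; at n = 1000 the 39th and 62nd. No OTL exists below
n = 59 at the 95%/95% defaults.

The two fixed points ES0 (OTL) and ES4 (median) are non-parametric; the
package's focus is the subdivision of the ranks *between* them into ES1,
ES2, ES3. Three methods are implemented and compared:

- **rank** — equal thirds of the rank interval between the OTL rank and
  the median rank (`step = floor((m − k_OTL)/3)`): distribution-free,
  equal category density. This is the recommended method.
- **zscore** — equal thirds of the standardized interval between the OTL
  score and the sample mean: the classical parametric practice.
- **direct** — arithmetic trisection of the raw score interval between
  the OTL score and the median score.

On Gaussian data the z-score and direct methods coincide (up to the sample
mean–median gap); on skewed data — the rule rather than the exception for
timed or ceiling-affected tests — they produce unequal category densities,
while the rank method keeps the three intermediate categories equally
populated by construction.

## Worked example

A right-ceiling "recall-like" synthetic normative sample (higher = better,
n = 300):

```r
library(esnorms)
s <- generate_sample("skew_higher_better", seed = 3)
normality_test(s$scores)
#> Shapiro-Wilk: W = 0.9127, p < 0.001

nm <- build_norms(s, method = "rank")
nm
#> Equivalent Score norms (rank method, n = 300, higher_better)
#>   boundaries (deficit tail -> median): ES0|6.45|ES1|19.52|ES2|27.07|ES3|37.95|ES4
#>   ranks from deficit tail: OTL 9, ITL 21, ES1/2 56, ES2/3 103, median 151

density_report(s, nm)
#> ES category density:
#>  category count   pct
#>       ES0     9  3.00
#>       ES1    47 15.67
#>       ES2    47 15.67
#>       ES3    48 16.00
#>       ES4   149 49.67

assign_es(7.2, nm)
#> ES = 1 (borderline) [uncertain: between OTL and ITL]
```

The sample is decisively non-normal (p < 0.001), so the z-score method
would be mis-specified here; the rank norms put 47/47/48 observations in
ES1/ES2/ES3 regardless of the distribution's shape. The score 7.2 is
better than the OTL score (6.45) but below the ITL, so it is classified
borderline **with an explicit uncertainty flag**: neither pathology nor
normality can be asserted at the 95%/95% level.

Rank limits depend only on n, so they can be read from a table instead of
computed:

```r
reference_table(c(100, 300, 600))[, 1:6]
#>     n otl itl es1_es2 es2_es3 median
#> 1 100   2   9      18      34     51
#> 2 300   9  21      56     103    151
#> 3 600  21  39     114     207    301
```

## Command line

A thin wrapper over the same functions is installed as `exec/esnorms`:

```sh
esnorms adjust   --input raw.csv --model model.json --output adjusted.csv
esnorms build    --input scores.csv --direction higher-better --method rank \
                 --output norms.json --density density.csv
esnorms score    --norms norms.json --input patients.csv --output es.csv
esnorms table    --sizes 100..600:25
esnorms simulate --kind gaussian --seed 1 --comparison cmp.csv
```

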