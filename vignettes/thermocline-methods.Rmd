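---
title: "Methods: Pst-Fst comparisons and thermal vulnerability along elevational gradients"
author: "thermocline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pst-Fst comparisons and thermal vulnerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocline)
```

## The scientific question

Populations of an ectotherm distributed across an elevational gradient may
adapt their critical thermal limits (CTmax, the hot endpoint of coordinated
function under ramped heating; CTmin, the cold endpoint) to local climate —
or they may not, if breeding phenology, microhabitat buffering and
acclimation plasticity equalise the temperatures larvae actually
experience. `thermocline` implements the quantitative machinery for asking
that question from four kinds of data: multi-allelic neutral genotypes
(microsatellites in GENEPOP format), per-individual thermal-limit assays,
pond datalogger series plus monthly macroclimate tables, and acclimation
experiments.

The inference has three legs:

1. **Divergence**: is the among-population variance in a thermal limit
   larger than neutral drift can explain? This is the Pst-Fst comparison.
2. **Vulnerability**: how close does each population live to its limits?
   Warming tolerance `WT = CTmax - TMAX` (macroclimate) and
   `wt = CTmax - tmax` (pond microclimate); cooling tolerance
   `CT = TMIN - CTmin` and `ct = tmin - CTmin`.
3. **Plasticity**: how much do the limits move under acclimation? The
   plasticity range (difference of treatment means) and the acclimation
   response ratio `ARR = (CT_high - CT_low) / deltaT`.

## Fst: the Weir-Cockerham estimator

Neutral differentiation is estimated by Weir and Cockerham's (1984) theta.
For each allele at each locus the estimator decomposes variance into
among-population (a), among-individual-within-population (b) and
within-individual (c) components, using the sample-size-weighted allele
frequencies, the weighted frequency variance with the `n_c` correction for
unequal sample sizes, and the observed heterozygote frequencies.
Components are summed over alleles; the multilocus estimate is the ratio
of sums over loci, `theta = sum(a_l) / sum(a_l + b_l + c_l)`. Negative
estimates are reported as computed — truncation would bias the estimator
near zero.

Missing genotypes are deleted locus-wise (the standard practice; each
locus uses every individual scored at it). Confidence intervals resample
loci — the unit that carries the evolutionary replication — with a 95%
percentile bootstrap by default; a delete-one jackknife over loci is
provided as an option. With only a handful of loci both methods are
approximate; the bootstrap was chosen as the default because it does not
rely on the normal approximation the jackknife interval uses.

## Pst: phenotypic divergence scaled by c/h²

With no breeding design, Qst is replaced by its phenotypic surrogate

\[
P_{ST} = \frac{c\,\sigma_B^2}{c\,\sigma_B^2 + 2 h^2 \sigma_w^2},
\]

where \(\sigma_B^2\) and \(\sigma_w^2\) are the between- and
within-population variances of the trait, \(h^2\) the (unknown) narrow-sense
heritability and \(c\) the (unknown) proportion of the between-population
variance that is additive. Pst depends on the two unknowns only through
the ratio \(r = c/h^2\), so the package evaluates Pst over a grid of
ratios (default 0.05 to 2 in steps of 0.05, spanning the range where
published critical ratios for this kind of data fall) rather than
pretending to know either scalar.

### Variance components

\(\sigma_B^2, \sigma_w^2\) come from the one-way random-intercept model
`trait ~ 1 + (1 | population)` fitted by REML. The implementation profiles
the REML criterion in the variance ratio \(\lambda = \sigma_B^2/\sigma_w^2\):
for fixed \(\lambda\) the GLS mean, the profiled residual variance
\(\hat\sigma_w^2 = Q(\lambda)/(N-1)\) and the criterion
\((N-1)\log Q + \sum_i \log(1 + n_i\lambda) + \log\sum_i n_i/(1+n_i\lambda)\)
are all closed-form, so one bounded scalar search on \(\log\lambda\)
(tolerance 1e-10; the profile is unimodal for this model) finds the
optimum. Boundary cases are handled explicitly: all-identical data return
(0, 0); data with no within-population variation return
\(\sigma_w^2 = 0\) and the between-group variance of the population means.
The fit agrees with `lme4::lmer` to numerical precision (a test asserts
this) but costs microseconds from sufficient statistics, which is what
makes bootstrap refits with thousands of replicates practical.

### Bootstrap band and the resampling unit

The 95% band around the Pst curve is a nonparametric percentile bootstrap:
resample the trait table, refit the variance components, evaluate Pst at
every grid ratio. What to resample is a genuine design choice, and the
package exposes three units:

- `"population"` (default): resample whole populations with replacement.
  The dominant uncertainty in \(\sigma_B^2\) at realistic designs (10-20
  populations) is which population effects were drawn, and only
  population-level resampling propagates it.
- `"individual"`: stratified resampling of individuals within populations.
  This preserves the observed population means almost exactly, so the band
  reflects only within-population sampling error. It answers "how well are
  these particular populations measured", not "how variable is the
  divergence process" — with 20 populations of 50 individuals its bands
  cover the generative Pst in only about a fifth of simulated datasets.
- `"twostage"`: populations, then individuals within each; the full
  hierarchical bootstrap.

Even with population-level resampling, a plain percentile interval for a
between-group variance at ~20 groups is known to undercover (the
resampled variance is shrunk by the factor \(1 - 1/k\), the bootstrap
spread slightly understates the chi-square sampling spread, and the
percentile method does not correct the skew). The package's own coverage
experiment (20 populations x 50 individuals, \(\sigma_B^2 = \sigma_w^2 = 1\),
truth Pst = 1/3 at ratio 1) measures roughly 80% empirical coverage for a
nominal 95% band. The percentile method is retained because it is the
standard reported with this analysis; users should read the bands as
approximate, and the coverage experiment (in the test suite) quantifies
how approximate.

Replicates in which both variance components collapse to zero carry no
Pst information; they are dropped and counted, and more than 20% of them
aborts the analysis.

### The critical c/h² ratio

Robustness of a `Pst > Fst` conclusion is summarised by the largest ratio
\(r\) at which the lower Pst bound still overlaps the upper Fst bound:
below that ratio the data cannot distinguish the trait divergence from
drift. `criticalCH2Ratio()` scans the grid and refines the crossing by
bisection, re-evaluating the percentile bound at candidate ratios on the
*stored* bootstrap replicates (no re-resampling, so the refinement is
deterministic and consistent with the grid). With few replicates the
lower band can be non-monotone; the last crossing is used, with a
warning. Sentinels distinguish "no overlap anywhere on the grid" from
"overlap everywhere".

The Fst upper bound used for the overlap is the bootstrap CI upper limit
of the global theta. The "overall" Pst is computed from the
all-populations model fit; pairwise Pst matrices (per-pair REML refits)
are produced separately for the Mantel comparison against pairwise Fst.

### Mantel tests

The Mantel statistic is the Pearson correlation of the lower triangles;
significance comes from jointly permuting row/column labels of one
matrix, `p = (1 + #(r_perm >= r_obs)) / (n_perm + 1)`, one-sided greater
by default. For matrices up to 7x7 an exact mode enumerates all `n!`
permutations. Matrices with missing entries are refused rather than
silently imputed.

## Climate summaries over phenology windows

All climate quantities are restricted to each population's larval-period
window, because that is when the assayed life stage is exposed. Windows
are recurring month-day intervals and may wrap the calendar year
(lowland autumn-to-spring breeding): `start > end` means the window
crosses 31 December.

From datalogger series: days need a record span of at least 20 h (default)
to contribute daily extremes; `tmax` is the mean daily maximum over the
warmest calendar month in the window (the month with the highest mean
daily maximum — the "mean maximum temperature of the warmest month"
convention), `tmin` symmetrically over the coldest month, `sr = tmax -
tmin`, and `dr` is the mean daily range over all qualifying days. Months
need 20 qualifying days to count; if no month qualifies the summary
downgrades to all-days means with a warning rather than failing a short
deployment. Ties between months go to the earlier month. From monthly
macroclimate tables: a month is in the window when at least 15 of its
days are; `TMAX`/`TMIN` are the extreme monthly values over included
months. Because a seasonal range can be defined from the extremes
(`TMAX - TMIN`) or as the mean within-month range, both variants are
emitted (`SR` and `SR_monthly`); published tables of this kind are
ambiguous between the two, so neither is silently preferred.

A lost logger is handled by an explicit alias map (population -> donor
series) in `climateSummary()`/`runPipeline()`, never by silent borrowing.

## Vulnerability, plasticity and censoring

`vulnerabilityTable()` applies the four exact identities to per-population
trait means (taken from assays at the common 20 °C pre-acclimation) and a
climate summary. `plasticityRange()` uses the trait-specific treatment
pair (27 vs 6 °C for CTmax; 27 vs 20 °C for CTmin) and `arr()` is the
two-point slope, reported to three decimals by convention; an OLS slope
across all treatments is deliberately *not* the default, for fidelity to
the standard two-point definition. CTmin assays at cold acclimation
treatments often reach the freezing point of water before the endpoint;
those observations are right-censored (the true CTmin is colder than
recorded) and `censorCtminTrials()` excludes them — and the 6/13 °C
treatments wholesale — rather than imputing.

## The statistical battery

Regressions of tolerances and limits on elevation and climate are plain
OLS (degree 1 or 2) with the overall F test; the ANCOVA for population
differences adjusts for body mass via the partial F of the population
factor given mass; acclimation experiments use a two-way fixed-effects
ANOVA with sequential (Type I) sums of squares in the order population,
temperature, interaction — matching how such tables are conventionally
printed; vulnerability scale comparisons use the paired t and the
asymptotic two-sample Kolmogorov-Smirnov test. These are standard fits
delegated to base R (`lm`, `anova`, `t.test`, `ks.test`); the package adds
the contracts (guards, df bookkeeping, labelled outputs), not new
machinery.

## The synthetic-data generator

Every stage is testable without field data because the generator produces
inputs with known ground truth:

- **Genotypes**: the Balding-Nichols island model. Population allele
  frequencies are Dirichlet around the ancestral frequencies with
  concentration \(p_a (1-F)/F\), then Hardy-Weinberg genotypes within
  populations. \(E[F_{ST}] \approx F\) without coalescent machinery —
  approximate for the Weir-Cockerham estimator at small sample sizes,
  which is why recovery tests use tolerance bands (±0.02 around a target
  of 0.066 over 100 replicates), not equalities. `targetFst = 0` copies
  the ancestral frequencies exactly.
- **Traits**: population effects N(0, σB²) plus residuals N(0, σw²);
  body mass is lognormal (median 150 mg, a realistic tadpole mass) and
  independent of the trait unless an optional mass slope is set — mass
  effects on thermal limits are typically weak, and the option exists so
  ANCOVA power can be probed.
- **Logger series**: seasonal plus diel sinusoids with Gaussian noise on
  an even timestamp grid (defaults: 12 °C mean, 6 °C seasonal and 4 °C
  diel amplitude, 0.5 °C noise, 30-min interval over May-August — a
  temperate-pond regime).
- **Acclimation**: per-population intercepts and a true ARR slope around
  a 20 °C reference, treatments 6/13/20/27 °C.

A single global seed expands into fixed per-generator child seeds
(documented offsets), so adding one generator to a script never perturbs
the streams of the others, and family structure within populations is
deliberately *not* simulated (the sampling designs this emulates mix
several families per population without recording pedigree; inventing one
would fake information).

What passing tests on synthetic data do **not** show: real microsatellite
panels have null alleles, allele-size homoplasy and scoring error; real
pond series have gaps, sensor drift and non-sinusoidal weather; real
trait distributions can be skewed and family-structured. The generator
validates the estimators' arithmetic and sampling behaviour, not their
robustness to those artefacts.

## Numerical and design choices

- REML search bounds: \(\log\lambda \in [-30, 30]\), wider than any
  realistic variance ratio, with an explicit comparison against the
  \(\lambda = 0\) boundary.
- Percentile quantiles are type-7 (R's default) everywhere, so bootstrap
  results are reproducible across functions.
- Problem sizes in tests and experiments (e.g. 100 seeds x 500 bootstrap
  replicates for the coverage experiment; 100 replicates for Fst
  recovery) were chosen to make Monte-Carlo error small relative to the
  asserted tolerances while keeping the whole suite comfortably fast on
  one CPU.
- GENEPOP files do not store population names; reading takes the last
  individual id of each block as the label (the common convention), and
  both 2- and 3-digit allele encodings are auto-detected. Mixed encodings
  within one file are a hard parse error, not a guess.
- `runPipeline()` stages communicate only through serialized outputs;
  missing inputs skip stages (recorded in the manifest), while errors
  inside a stage abort the run after the manifest is written. Outputs
  contain no wall-clock content, so identical configs reproduce
  byte-identical artifacts.

## Known limitations

- Pst is a surrogate for Qst: non-additive variance, maternal effects and
  G×E can distort it, which is exactly why results are reported across
  the whole c/h² grid with the critical-ratio robustness summary instead
  of a single number.
- The percentile bootstrap band undercovers at realistic population
  counts (see above); treat the critical ratio as a sensitivity index,
  not an exact boundary.
- The Fst CI resamples loci; with six loci the interval is coarse and the
  bootstrap's discreteness shows.
- No marker QC (null alleles, HWE screening) is performed — marker
  selection is an upstream decision.
- Climate summaries assume the logger represents the pond the larvae
  occupy; no gap-filling or water/air transfer modelling is attempted.
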