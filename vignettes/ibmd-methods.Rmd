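---
title: "Measuring and comparing observer disagreement with IBMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing observer disagreement with IBMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibmd)
```

## The problem

When several observers rate the same cases — judges scoring gymnasts,
obstetricians reading printed heart-rate tracings — we often need to compare
the *degree* of disagreement between two populations, methods or
circumstances: is a new scoring rulebook more contentious than the old one?
Is a tracing harder to read late in labor? Reliability coefficients are the
wrong tool for that comparison. The intraclass correlation (ICC) and Lin's
concordance coefficient (CCC) express observer error *relative to the trait
variance of the rated population*: the same observers with the same error
look highly "reliable" on a heterogeneous population and unreliable on a
homogeneous one. Between-population comparisons of ICC or CCC therefore
confound observer behaviour with population spread.

## The measure

The information-based measure of disagreement (IBMD) scores a pair of
observations $x, y \ge 0$ of the same case by the information, in bits,
carried by their relative difference:

$$d(x, y) = \log_2\!\left(\frac{|x - y|}{\max(x, y)} + 1\right),
\qquad d(0, 0) \equiv 0 .$$

$d$ is 0 exactly on ties, 1 when one observer reports 0 and the other a
positive value (the largest relative difference a non-negative scale
admits), symmetric, scale free — it depends on $x, y$ only through their
ratio — and a metric on positive reals (the triangle inequality is
property-tested in the suite). For $N$ cases where case $i$ carries $M_i$
observations $x_{i1}, \dots, x_{iM_i}$,

$$\mathrm{IBMD} \;=\; \frac{1}{\sum_{i=1}^{N}\binom{M_i}{2}}
  \sum_{i=1}^{N}\sum_{j<k} d(x_{ij}, x_{ik}),$$

the average kernel value over every within-case observation pair. Because
cases enter only through their own pairs, $M_i$ may vary freely: a case some
observers skipped still contributes its remaining pairs. Cases with
$M_i < 2$ contribute no pairs at all; they are dropped with a warning and
counted in the result (`n_cases_dropped`), and the drop happens *before*
bootstrap resampling so every replicate is well defined.

IBMD is 0 exactly when all observations agree within every case, bounded
above by 1, and invariant to rescaling all observations by a common positive
factor — the property that makes values comparable across populations
measured on different ranges, and the property ICC/CCC lack. The kernel uses
base-2 logarithms throughout: that base is what normalizes the maximal
pair (one zero, one positive) to exactly 1.

Two conventions deserve a note. A pair of zeros scores $d(0,0) = 0$: the
convention defines the kernel value, so a case consisting entirely of zeros
still counts its $\binom{M_i}{2}$ pairs in the denominator (counted
agreement, not an exclusion). And a `0` in a data file is a legal
observation; only a *blank* cell is a missing one — conflating the two
silently changes the estimate.

## Interval estimation and group comparison

Standard errors for IBMD have no convenient closed form, so intervals come
from the nonparametric bootstrap: resample the $N$ usable cases with
replacement — each case carries its whole observation vector; observers are
never resampled, since the case is the sampling unit — recompute IBMD on
each of $B$ replicate tables, and take the empirical $\alpha/2$ and
$1-\alpha/2$ percentiles of the replicate values. The point estimate is the
plug-in value on the original table, not a bootstrap mean. $B = 1000$ is the
default, adequate for 90–95% intervals. Percentiles are computed with linear
interpolation between order statistics (`stats::quantile` type 7); the
convention matters at the margin because $B\alpha/2$ is an integer at
$B = 1000$, and it is stated here because other software may differ by one
order statistic.

Two independent populations are compared by `compare_ibmd()`: each group is
bootstrapped independently and the verdict is read from interval overlap —
disjoint intervals indicate significantly different disagreement. A
percentile interval for the difference $\mathrm{IBMD}_b - \mathrm{IBMD}_a$,
formed by pairing replicate $r$ of each group, is reported alongside as a
finer-grained (and less conservative) supplement; the overlap verdict is the
primary criterion.

Reproducibility: a `seed` makes intervals bit-for-bit repeatable. In a
two-group comparison one root seed deterministically spawns an independent
child stream per group, so a group's interval never depends on the other
group's size or content. Without a seed the session stream is used and
results are not reproducible. A degenerate replicate (every resampled case
internally constant) is legal and contributes the value 0 — no redraw.

On a single-case table the bootstrap is formally defined but vacuous: every
replicate is the same case, so the interval collapses to the point estimate.

## Packaged studies

Two studies ship with the package, transcribed once and frozen by md5
digests that the loaders verify on every load:

* `load_gymnasts()` — 40 gymnasts, each scored by the same eight judges on a
  0–10 scale; 20 under an old rulebook and 20 under a new one.
* `load_maternal_hr()` — maternal heart-rate baseline (bpm) estimated by
  three obstetricians for 26 printed one-hour tracing segments: one
  initial-hour and one last-hour segment for each of 13 mothers in labor.

```{r examples}
compare_ibmd(load_gymnasts(), n_boot = 1000, seed = 3)
compare_ibmd(load_maternal_hr(), n_boot = 1000, seed = 3)
```

The gymnastics intervals are disjoint (the new rulebook roughly doubles
disagreement); the labor-phase intervals overlap (no evidence the last hour
is harder to agree on). A transcription note: the old-rulebook group
computes to IBMD = 0.093 on the packaged table. The source report of this
study quotes 0.090 for that group alongside values for the other three
groups that the packaged tables reproduce exactly (0.174, 0.048, 0.048);
no faithful reading of the published table yields 0.090, so the packaged
transcription is kept verbatim and the computed value stands.

## The synthetic generator

`simulate_ratings()` generates cases with true values uniform on
`true_value_range`; observer $j$ of case $i$ reports
$t_i e^{\varepsilon_{ij}}$ with $\varepsilon_{ij} \sim N(0,
\sigma^2)$ i.i.d. Multiplicative log-normal error is the default
because IBMD is a relative measure: under this model the population IBMD
depends only on the noise scale $\sigma$ (log units) and the observer count,
not on the value range — the generator-level scale-invariance harness in the
test suite exercises exactly that. An additive-error variant
(`error = "additive"`, sd in original units) exists for demonstrations that
need trait variance and error scale decoupled, e.g. showing ICC moving with
trait spread while IBMD stays put. Observations are deleted independently
with probability `missing_rate`, and a case left with fewer than two
observations is redrawn whole, so every generated case is usable.

Defaults (30 cases, 3 observers, values on 50–150, $\sigma = 0.1$, no
missingness) mirror a small clinical agreement study such as the heart-rate
one. What the generator does *not* emulate: systematic observer bias or
observer-specific error variances, correlation between error and trait
magnitude beyond proportionality, digit preference and rounding, and
informative missingness (observations are deleted completely at random).
Tests passing under this model therefore certify the estimator and its
intervals under i.i.d. multiplicative error, not robustness to structured
observer behaviour.

Bootstrap calibration is checked at desk scale in the acceptance suite: 200
datasets of 30 cases × 3 observers at $\sigma = 0.1$, each bootstrapped with
$B = 500$, against the large-sample IBMD estimated once from a single
100 000-case run of the same model; observed 95% interval coverage is
required to land in [0.90, 0.99], the usual mild undercoverage of percentile
intervals at $n = 30$ being within that band.

## Comparators

For side-by-side reporting the package includes the classical measures,
which require rectangular (complete-case) tables — IBMD is the only measure
here that accepts ragged ones:

* `icc()` — the two-way random-effects, absolute-agreement, single-measure
  intraclass correlation, ICC(A,1), computed from the mean-squares
  decomposition. This variant is chosen because it is the
  agreement-appropriate one (systematic observer differences penalize it);
  the variant name is embedded in every result so downstream reports cannot
  quietly mix ICC forms.
* `ccc()` — Lin's concordance correlation coefficient with biased ($1/N$)
  moment estimators, Lin's original definition; at small $N$ this visibly
  differs from a sample-variance version, hence the explicit choice.
  Always $|\mathrm{CCC}| \le |r|$.
* `limits_of_agreement()` — Bland–Altman bias $\pm 1.96\,\mathrm{sd}$ of the
  paired differences (sample sd), for two observers.

```{r comparators}
icc(split_ratings(load_maternal_hr())[["Initial hour"]])
```

## Numerical choices and limitations

* Kernel and estimator run in double precision with no internal rounding;
  the 3-decimal presentation happens only in `print()` methods and
  human-readable CLI reports. JSON output carries full precision.
* Within-case kernel terms and per-case sums are added in sorted order, so
  the estimate is bit-for-bit invariant to case order and to observation
  order within a case — reordering a CSV can never change a reported value
  even in the last digit.
* Exact ties (including 0/0) short-circuit to 0 before any logarithm is
  taken; no NaN ever enters the sum.
* Duplicate observer labels within a case are rejected at parse time: the
  estimator has no provision for replicate readings by one observer, and
  averaging them silently would understate disagreement.
* CSV parsing is strict RFC-4180-style with period decimals; decimal commas
  are rejected, not coerced.
* The interval-overlap criterion is conservative as a test of equality;
  the paired-replicate difference interval is the sharper summary, and
  neither is a substitute for a designed hypothesis test. BCa and
  studentized intervals are out of scope.
* IBMD is defined for non-negative ratio scales only; interval or ordinal
  data (and the kappa family) are out of scope. Values near zero make the
  kernel saturate (any positive value paired with 0 scores 1), so scales
  where 0 is a common legitimate reading deserve a look at the raw kernel
  values before interpretation.
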