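---
title: "Estimating national cancer incidence from partial registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating national cancer incidence from partial registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canestim)
```

## The estimation problem

A national cancer-control programme needs the number of new cases per year
by sex and site, but only a minority of countries record this directly.
The international estimation framework that `canestim` implements walks a
data-availability ladder: use the country's own incidence history if it
exists; otherwise recent national rates; otherwise infer incidence from
national mortality via case-fatality proxies; otherwise transport rates
from regional registries or neighbouring countries. Each rung trades an
assumption for data:

* **Projection methods (1A, 1B)** assume recent incidence trends continue
  into the near future.
* **Rate transport (2, 6, 7, 9)** assumes the source population's rates —
  recent years, a region, the neighbours — are representative of the
  target nation at the target year.
* **Mortality-based methods (3, 4, 5)** assume incidence, mortality and
  survival are in approximate equilibrium, so that deaths divided by a
  case-fatality proxy (an M:I ratio, or 1 − S with S the 5-year relative
  survival) recover incidence.
* **Frequency partition (8)** assumes the site mix of the source equals
  that of the target.

All inputs are long-format stratified tables keyed by dataset, year, sex,
ICD-10 site group and 5-year age band (indices 0–17 for 0–4 … 85+). A
missing stratum always means zero events, never missing data, so sparse
registry extracts are valid. The site catalogue fixes 21 male and 23
female groups that partition all cancers excluding non-melanoma skin
(C44); unspecified uterus (C55) survives as a staging group until it is
reallocated to cervix and corpus.

## The projection engines

### Long-term: age–period–cohort with a power-5 link

Method 1A (and the mortality projection feeding methods 3–5) models counts
on an 18-age × P-period grid of 5-year bins:

$$ E[Y_{ap}] = \frac{N_{ap}}{10^5}\,\big(\alpha_a + \delta p + \pi_p +
\gamma_{c}\big)^5, \qquad c = p - a, $$

a Poisson likelihood with the fifth-root of the rate linear in age,
period and cohort. The fifth-power link is the convention of the Nordic
projection software lineage: it damps the explosive growth a log link
produces when a strong trend is extrapolated, while keeping rates
non-negative. Identifiability follows the classical drift decomposition:
$\pi$ and $\gamma$ are each constrained to sum to zero with zero slope
(implemented with orthogonal-polynomial bases of degree ≥ 2), so the
shared linear trend — the drift $\delta$ — is unique.

Fitting is Fisher scoring with step halving, started from the null model
($\alpha_a$ = fifth root of the pooled age-specific rate, everything else
zero), tolerance 1e-8 on the relative deviance change, at most 100
iterations, and no randomness anywhere, so identical inputs give
bit-identical fits. A negative linear predictor is floored at zero with a
warning (the power link requires a non-negative base); age rows with no
events anywhere are dropped from the optimisation and reported as rate
zero, since their maximum-likelihood rate is the boundary. The fit is
cross-checked in the test-suite against an independent `glm` fit with a
`power(1/5)` link on an exposure-scaled design, which agrees to
~1e-6 — the engine is hand-rolled only because it needs the flooring,
the deterministic start and the constrained parameterisation in one
place.

Projection continues $\alpha$ and $\delta$, carries the most recent
period effect forward, extrapolates unseen cohorts at the last estimated
cohort's value, and attenuates the drift increment by the cut-trend
schedule (defaults 1.00, 0.75, 0.50, 0.25 for prediction periods 1–4;
all-ones disables it). Projected 5-year-period rates are read as annual
rates at the period midpoint — the 2008–2012 projection supplies the 2010
estimate — and applied to the target-year population.

### Medium-term: age-specific linear rate trends

Method 1B fits, per age band, expected count =
person-years × max(0, a + b·t)/10⁵ with t centred at the window midpoint
(1998–2007 by default), by the same Fisher-scoring routine with the
identity-in-rate link. Additive-in-rate rather than multiplicative is the
deliberate choice for a 10-year window: it extrapolates soberly over
3 years and floors at zero instead of decaying exponentially. All-zero
age rows get a zero fit.

### Sparsity fallback

A (sex, site) with fewer than 50 events in the fit window cannot support
a trend model; it falls back to average rates (the last five window years
for methods 1A/1B, the whole window for the mortality projection) and is
recorded in the `fallback_sites` attribute. The threshold is an argument;
50 keeps the APC grid from being fitted to noise while letting genuinely
informative sites through.

## The mortality-based methods

M:I ratios are age-specific: pooled deaths over pooled cases per (sex,
site, age band) across the proxy datasets and the reference period
(2003–2007). Two stabilisations apply. First, sites averaging fewer than
100 national deaths per year add the neighbour datasets to the pool
before the ratio is taken — the framework's rule for rare-death cancers
(national annual death counts in the low tens make a regional ratio
meaningless). Second, age bands with zero pooled cases — or zero pooled
deaths, for a site that has deaths at some age — are merged with the
adjacent younger band until every band has an informative ratio; a thin
band's zero is a sampling artifact, and without the merge valid sparse
data would produce ratio-0 bands that make the inversion impossible.
A site with deaths but no cases anywhere in the pool is still an error.

Method 5 inverts M = I(1 − S) at sex-site granularity (survival tables
are published at that resolution, not by age). S is capped at 0.99 before
inversion and capped sites are flagged: as S → 1 the inversion divides by
nearly zero, which is exactly the documented failure mode for
good-prognosis cancers where cure is not attained by five years.

Two choices here were genuinely open. The ratios are applied on rates
rather than counts (equivalent when source and target populations match,
explicit otherwise), and method 4's neighbour ratios use the same
2003–2007 reference period as method 3, to keep the two methods
comparable.

## Validation arithmetic

Estimates are rounded to whole cases (half away from zero) before
comparison, matching publication practice; percentages are rounded half
away from zero to one decimal. Per method and sex the report carries the
total underestimated and total overestimated cases separately — summing
signed errors would let opposite-signed sites cancel — and the aggregate
percentage difference 100 × Σ|diff| / Σ observed. "Mean percentage
difference" in this literature is this ratio of sums, not the mean of
per-site percentages. A site with zero observed cases and a nonzero
estimate has an undefined percentage, reported as NA.

The bundled Norway 2010 reference table (observed counts and the nine
methods' estimates, 21 male + 23 female site groups) is checksummed on
load and carries counts only; every percentage and aggregate is
recomputed. The separately bundled published percentages are used solely
to flag discrepancies; one flag is expected — head and neck, women,
method 2, printed −3.3 against a recomputed −13.3 — a typesetting error
in the source, with the count authoritative. Differences of one unit in
the last printed digit are not flagged, because the source computed its
percentages from unrounded estimates.

## The synthetic registry generator

`generate_registry()` emulates the structure of a Nordic-style extract:
four national regions with population shares and rate multipliers (the
capital region holds half the population), four neighbouring countries
with relative sizes echoing the Nordic ratios, years 1983–2012, a
five-million-person nation growing 0.5% per year with a near-flat age
pyramid rolling off logistically around age 72. Site age curves are
log-quadratic in the age-band midpoint (two parameters: peak rate and
peak age, with a fixed 30-year curvature scale); calendar trends are
log-linear with an optional changepoint. Counts are Poisson around the
expected values; mortality expectation is incidence × (1 − S) per
stratum. Everything derives deterministically from one seed.

Two knobs deliberately break the survival link to reproduce documented
real-world failure modes:

* `mortality_inflation` multiplies mortality (deaths beyond five years of
  follow-up), so survival inversion overestimates — the good-prognosis
  scenario.
* `mortality_trend` adds an extra log-linear decline to mortality
  (improving treatment), anchored `survival_lag = 10` years before the
  target year: a period survival estimate reflects patients diagnosed and
  followed up well before the estimation year, so when treatment improves
  the printed 1 − S overstates current case fatality. Without the lag the
  link would hold exactly at the target year and method 5 would be
  unbiased by construction, contradicting what is observed on real rare-
  death cancers.

The `rare_death` preset uses a testis-like site: peak rate 30 per 10⁵ at
age 32, S = 0.95, incidence rising 2%/year, mortality falling 8%/year —
about 13 national deaths per year at the target, the order of magnitude
that motivates the neighbour-pooling rule. The `screening_bump` preset
rises 5%/year until a 2003 plateau, prostate-like. Presets are
qualitative testbeds: they reproduce the direction and rough size of each
failure mode, not Norway's actual magnitudes.

What passing tests on these synthetics do *not* show: real registries
have reporting delays, completeness drift, coding changes, age-varying
survival, and regional differences in case mix rather than a clean
multiplicative rate factor. The generator validates the estimation
arithmetic and its documented failure modes, not the methods' real-world
accuracy.

## Numerical conventions and degenerate inputs

* Counts become real-valued after C55 reallocation; rounding to integers
  happens only at report time.
* C55 splitting uses cell-level (dataset, year, age) cervix/corpus
  proportions, falling back to dataset-level proportions, then 50/50 with
  a warning — a deterministic hierarchy that conserves the uterine total
  exactly per cell.
* 19-band age inputs (85–89/90+) collapse into 85+ with a warning.
* Duplicate strata in input files are summed with a warning; rows with
  invalid sex or age are rejected with row numbers.
* Neighbour pooling always sums counts and person-years (person-year
  weighting), never averages per-country rates.
* Method 8 frequencies are per sex without an age split; the all-sites
  transport is age-resolved, so the partition conserves the all-sites
  total exactly by construction.

## Problem sizes

The test-suite runs the engines at desk scale: 18 × 5 grids with 5 × 10⁵
person-years per cell for exact-recovery checks, 200 Poisson replicates
at 2 × 10⁶ person-years per cell for the drift-coverage check, and 200
generator replicates per directional scenario restricted to the focal
site (methods are site-separable, so this is a pure shortcut). The full
suite completes in about two minutes on one CPU.

## Limitations

* No uncertainty quantification: the framework reports point estimates,
  and so does the package.
* No age-standardised rates, no ICD-9/ICD-O conversion, no joinpoint or
  Bayesian trend models.
* The internals of the historical projection programs are not public;
  the APC-power-5 and age-linear engines here follow their published
  descriptions, with every choice (link power, attenuation schedule,
  windows, thresholds) exposed as an argument rather than folklore.
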