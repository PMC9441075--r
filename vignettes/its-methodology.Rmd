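---
title: "Methods: segmented NB interrupted time series for 311 report streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented NB interrupted time series for 311 report streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its311)
```

## The estimation problem

A place-based sanitation intervention (a new public restroom, the
staffing of an existing one, or extended service hours) starts at a
known date $T_0$ at a known location. The outcome proxy is a stream of
geocoded municipal 311 incident reports of exposed feces. The question
is whether the intervention changed the weekly rate of nearby reports —
instantaneously (a level change) and/or in trend (a slope change).

`its311` implements a multiple-baseline interrupted time series: each
site contributes its own 53-week window centred on its own $T_0$
(26 weeks pre, the transition week, 26 weeks post), so calendar-time
shocks that hit all sites at once are not absorbed into any single
pre/post contrast, and each site acts as its own control.

## From raw reports to the analysis panel

**Filtering.** Only reports in the configured target category
(default `"Human/Animal Waste"`) are kept; records whose free-text
status notes contain `"dup"` or `"transfer"` — case-insensitively,
anywhere in the note — are removed as duplicates/misroutes, and an
optional agency whitelist and date range can be applied. Removal
reasons are tallied in the fixed order *category, note, agency, date*
(first matching reason wins), so the tallies plus the retained count
always partition the input; this makes ingest audits additive. The
live data dictionary does not pin down matching semantics for the note
tokens, so the broadest (case-insensitive substring) reading was
chosen; anything narrower risks silently retaining duplicates.

**Buffers.** The published study used 500 m *walking-network* buffers
computed in a commercial GIS; pedestrian-network routing is not
reproducible offline, so the default here is the geodesic circle of
radius `radius_m` (default 500 m) on the WGS84 ellipsoid, with an
escape hatch: any per-site polygon (e.g. an externally computed network
buffer) can be supplied as GeoJSON and is used verbatim. Circle
containment is decided by exact geodesic distance (no polygon
discretization error); user polygons use even-odd ray casting in
lon/lat, which is accurate for the small, mid-latitude polygons this
pipeline targets. Points exactly on a boundary count as inside — the
convention is arbitrary, but it must be fixed and tested, since
simulated points land exactly on disc edges with positive probability
in finite precision.

**Weeks.** Week $k \in 1..53$ covers
$[T_0 + (k-27)\cdot 7\,\mathrm{d},\; T_0 + (k-26)\cdot 7\,\mathrm{d})$,
half-open, anchored at midnight (UTC) of $T_0$. This is the unique
convention under which the start date falls in exactly one week —
week 27 — which is then removed from every analysis as the transition
week. Whether the original study anchored weeks at $T_0$ or at
calendar boundaries is not recoverable from its text; $T_0$-anchoring
is recorded here as this package's choice because it makes the
transition-week rule exact rather than approximate. All timestamps are
handled in a single zone (UTC) so bin edges are unambiguous.

**Zero filling.** Every retained site-week appears in the panel, with
count 0 where no reports matched. Zeros are real observations;
dropping empty weeks would truncate the outcome distribution and bias
slopes upward in sparse strata.

## The two estimators

### Permutation test of the mean difference

The statistic is $\Delta = \bar y_{post} - \bar y_{pre}$ (reports per
week; negative = decline), pooling site-weeks across the interventions
of a stratum — matching the pooled stratum means the summary table
reports. Inference relabels the pooled site-weeks into groups of the
original sizes. With $N$ random relabelings the reported p-value is the
add-one estimate $(1 + \#\{|\Delta^*| \ge |\Delta_{obs}|\})/(N+1)$,
which is never exactly zero; when $\binom{n}{n_{pre}} \le N$ the null
distribution is enumerated exactly instead and the plain tail fraction
is reported. Defaults: $N = 10{,}000$, two-sided. Sidedness is
configurable because published permutation p-values rarely state it;
two-sided is the conservative default. Exchangeability of site-weeks
across the pre/post labels is the operative assumption — serial and
spatial dependence make the test approximate on real data, which is
one reason the regression estimator exists alongside it.

### Segmented NB2 regression

$$\log E[y_{it} \mid X] = \beta_0 + \beta_1\,\mathrm{week}_t +
\beta_2\,\mathrm{intervention}_{it} +
\beta_3\,\mathrm{week}_t\,\mathrm{intervention}_{it} +
\beta_4\,\mathrm{neighborhood}$$

with $\mathrm{week}_t$ the *relative* index $t \in \{1..26, 28..53\}$
and $\mathrm{intervention}_{it} = \mathbf 1\{t \ge 28\}$ — defined from
the week index, never from raw timestamps, so transition removal is
structural. $\beta_1$ is the pre-intervention weekly trend $m$,
$\beta_2$ the level change, $\beta_3$ the slope change $\Delta m$, all
in log-reports per week; the post-period trend is $\beta_1 + \beta_3$.
Counts are NB2: $\mathrm{Var} = \mu + \mu^2/\theta$, the standard
choice for overdispersed weekly counts. A single pooled intercept per
stratum (not per-site intercepts) mirrors the displayed model; the
neighborhood fixed-effect block (treatment coding, alphabetically
first level as reference) adjusts type-stratified fits for the spatial
clustering of sites, and is dropped in neighborhood-within-type fits
where it would be constant. No exposure offset is needed: every
observation is one week of one buffer.

**Fitting.** $\beta$ given $\theta$ by iteratively reweighted least
squares (Fisher scoring; working weight $\mu/(1+\mu/\theta)$, inner
tolerance $10^{-10}$ on $\max|\Delta\beta|$), $\theta$ given $\beta$
by one-dimensional profile maximum likelihood on $\log\theta$ over
$[\log 10^{-4}, \log 10^{6}]$, alternated until
$\max|\Delta\beta| < 10^{-8}$ and $|\Delta\log\theta| < 10^{-6}$
(at most 100 outer iterations; each half-step maximizes the joint
likelihood in its block, so the profile log-likelihood trace is
non-decreasing, which the test suite asserts). $\beta$ and $\theta$
are information-orthogonal in NB2, so the alternation converges in a
handful of outer iterations. If the profile optimum lands beyond
$\theta = 10^5$ the quadratic term $\mu^2/\theta$ is numerically
negligible and the likelihood surface is a flat (and, in finite
precision, noisy) Poisson plateau; the fit then restarts as a Poisson
GLM and reports $\theta = \infty$ with a warning rather than a
meaningless huge $\hat\theta$. Rank-deficient designs and all-zero
responses fail with explicit errors naming the problem.

**Robust inference.** HC0 sandwich $A^{-1} B A^{-1}$ with bread
$A = X^\top W X$ (expected information at the fitted $\beta, \theta$,
with $\theta$ treated as fixed, as is standard for GLM sandwiches) and
meat $B = \sum_i s_i s_i^\top$ from per-observation scores
$s_i = x_i (y_i - \mu_i)/(1 + \mu_i/\theta)$. CIs are Wald
$\hat\beta \pm 1.96\,\mathrm{SE}$ (z, not t). The published analysis
says only "sandwich estimators"; HC0 with z intervals is the plainest
reading. Scores are *not* clustered by site or week: serial
correlation within a site is therefore only partially guarded against,
a documented gap rather than a silent choice — Newey–West or
cluster-robust flavors are deliberately out of scope.

## The synthetic generator

`synth_config()` + `simulate_panel()` draw latent weekly counts from
exactly the model above (optionally plus a sinusoidal log-scale
seasonal term, default off because the fitted model has no seasonal
term), and `materialize_reports()` explodes them into point records:
timestamps uniform within the week bin, locations uniform on the
buffer disc via $r\sqrt{u}$ and a uniform bearing — the
least-informative micro-placement, since no sub-weekly or sub-buffer
structure is claimed by the design. Week 27 is generated like any
other week; only the pipeline drops it. Contamination knobs append
duplicate records (status notes flagging them), off-category records,
and records displaced 2–10 radii off-site, exercising each filter and
the matcher's rejection path.

Defaults are the study-scale conditions used throughout validation:
13 sites, $\beta_1 = 0.013$, $\beta_3 = -0.024$, $\theta = 2$,
baseline $e^{\beta_0} = 20$ reports/week, $\beta_2 = -0.1$ (the level
change is not printed in the published tables; a modest decline of
~10% was fixed once as a realistic value and not revisited), 500 m
buffers, sites placed on a grid ~2 km apart so buffers are disjoint
and round-trip recovery is exact. Overlapping buffers are supported in
matching (one match per containing site, flagged `multi_matched`) but
are not the generator default, because exact count conservation is the
more valuable test invariant.

What passing tests on this generator do **not** show: robustness to
reporting-propensity drift (media events, app launches), diurnal or
street-network clustering of reports, misclassification of animal
versus human waste, or walking-network buffer geometry. Those are
properties of real data the generator deliberately does not model.

## Validation problem sizes

The test suite and acceptance script use: 200 replicates of
13 sites × 52 analysed weeks for slope-change recovery (bias and
robust-CI coverage), 1,000 null trials at 26 + 26 weeks with 999
relabelings each for permutation calibration, five random fixture
panels for coefficient/dispersion/SE agreement with an independent
reference GLM implementation (`MASS::glm.nb` + `sandwich`) at
$10^{-6}$/$10^{-4}$ relative tolerance, and six-site streams of a few
thousand reports for end-to-end conservation. These sizes give Monte
Carlo error comfortably below the effects being checked while keeping
a full run in tens of seconds.

## Known limitations

* Geodesic circles are not walking-network buffers; in dense street
  grids the circle over-covers (rivers, freeways) or under-covers
  (diagonal shortcuts). Supply network polygons via
  `read_buffers_geojson()` where fidelity matters.
* HC0 without clustering understates uncertainty under strong serial
  correlation of weekly counts within a site.
* The permutation test pools site-weeks across interventions within a
  stratum; a within-site blocked scheme is a plausible alternative the
  package intentionally does not implement.
* Season/year summaries use meteorological seasons (DJF/MAM/JJA/SON)
  on Monday-anchored calendar weeks; these are descriptive only and
  enter no model.
* A report inside two overlapping buffers counts once per site, so
  pooled stratum totals can double-count such reports; the
  `multi_matched` flag supports sensitivity analyses.
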