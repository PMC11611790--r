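---
title: "Partitioning trends in prevalence and incidence-based mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trends in prevalence and incidence-based mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.2)
```

```{r setup, message = FALSE}
library(hfpartition)
library(dplyr)
```

## The scientific question

Chronic-disease prevalence and mortality among older adults move for
entangled reasons. The prevalence of heart failure in a Medicare-age
population can rise because incidence rises, because patients survive
longer, or simply because cohorts diagnosed long ago are still alive;
all-cause mortality among ever-diagnosed patients — *incidence-based
mortality* (IBM) — additionally moves with the mortality of the general
population. A trend in either quantity is therefore uninterpretable on its
own: the same decline in prevalence is good news if incidence is falling and
bad news if patients are dying faster.

Partitioning analysis resolves this by decomposing the *logarithmic time
derivative* of prevalence and of IBM into additive, determinant-specific
contributions. This package implements that decomposition end to end for
claims-like data: case ascertainment from diagnosis-coded claims,
person-year aggregation, age-standardized rate and survival estimation,
trend smoothing, and the exact partition itself — together with a
synthetic-cohort simulator with known ground truth, so that every stage can
be validated without access to restricted claims data.

## Outcome definitions

All quantities are directly age-standardized over single years of age 66-99
with a weight vector $w(a)$ (uniform by default; any standard can be
supplied as an `age, weight` CSV). The 65th year of life is treated as an
ascertainment run-in, not as analysis time.

Prevalence splits by where a case's onset falls relative to the two
observation boundaries — the age boundary (65) and the calendar boundary
(the first observed year):

$$P(y) = P_0(y) + P_{00}(y) + P_{is}(y),$$

the contributions of cases diagnosed before age 65, before the calendar
boundary, and inside the observation window. The split matters because
onset timing is *unobservable* for the first two groups; they must be
carried as separate pools.

IBM is the all-cause death rate of ever-diagnosed persons per unit of
**total population** person-time. With $\pi_c = C_c/N$ the prevalent
person-time fraction of onset category $c$, $h_c$ that category's death
rate, and $\mu = D_{all}/N$ the general-population mortality:

$$M(y) = M_\mu(y) + M_0(y) + M_{00}(y) + M_{is}(y),$$

where $M_\mu = \sum_a w\,(\pi_0+\pi_{00}+\pi_{is})\,\mu$ is what the
prevalent pool would die of anyway and $M_c = \sum_a w\,(D_c - C_c\mu)/N$ is
each pool's excess. Both identities hold *exactly* by construction, on any
input: they are tested to $10^{-10}$ relative error and typically hold to
machine precision. The total-population denominator is the only choice
consistent with the component magnitudes this kind of study reports (the
general-population component is roughly prevalence times elderly background
mortality).

## The partition

Write $D(y) = [X(y{+}1) - X(y{-}1)]\,/\,2X(y)$ for the central-difference
log-derivative (one-sided at the window edges, which are flagged and
excluded from contribution tables). The package decomposes

$$D_P(y) = T_0 + T_{00} + T_{inc} + T_s, \qquad
  D_M(y) = \hat T_\mu + \tilde T_0 + \tilde T_{00} + \tilde T_{inc} + \tilde T_S,$$

with every equality exact — the closure residual is a test invariant, not an
approximation.

Two principles shape the construction:

**Terms are trend attributions, not gross flows.** In a stationary
illness-death process every contribution must vanish. A decomposition into
gross inflow (incidence) and gross attrition (deaths of prevalent cases)
would instead produce two large, nearly-cancelling terms in every year —
each 15-20 times the derivative itself — and the incidence term would carry
the wrong sign whenever prevalence falls while incidence declines. The
contribution table's sign semantics (a positive percentage = pushes in the
trend's direction) only work for trend attributions. The gross flows are
still computed (`tinc_gross`, `touflow_gross`) as diagnostics; in a
stationary cohort they balance each other, while the trend terms are zero.

**The incident pool is tracked along cohort diagonals at fixed duration.**
The incident prevalent fraction, resolved by diagnosis-year lag
$l = y - \lfloor\text{onset}\rfloor$, obeys the exact recursion

$$q(y,a,l) = \sigma_l(y,a)\, q(y{-}1, a{-}1, l{-}1),
  \qquad q(y,a,0) = \iota(y,a),$$

because the cohort occupying cell $(y,a,l)$ is, one year later, exactly the
cohort of cell $(y{+}1,a{+}1,l{+}1)$. Here $\iota$ is newly diagnosed
person-time and $\sigma_l$ the continuation ratio of the lag-$l$ pool.
Differencing the recursion with the midpoint (Bennet) product rule —
$f_1g_1 - f_0g_0 = \Delta f\,\bar g + \bar f\,\Delta g$, exact for discrete
differences and symmetric in the factors — and unrolling along the diagonal
splits any two-year change of $P_{is}$ exactly into

* an **incidence part** (differences of $\iota$ at like lags) → $T_{inc}$;
* a **survival part** (differences of $\sigma_l$ at like lags) → $T_s$;
* a **boundary carry** (everything whose diagonal leaves the observed
  window, plus comparisons against the depleted boundary-year onset cohort)
  → merged into $T_{00}$.

Comparing $\sigma$ and the case death rates at *fixed lag* is essential:
the incident pool's duration mix matures for decades after the calendar
boundary (high-excess fresh cases are progressively diluted by long-term
survivors), and a pool-level comparison would misread that composition
drift as a survival trend. Lags are capped at 10 years (`lag_cap`), where
the excess hazard has decayed to a few per mille and composition drift
within the capped bin is negligible.

Routing the boundary carry into $T_{00}$ gives that term a readable
meaning: the pre-boundary cohort's own drainage *plus* the replacement
transient as incident cases fill the space it vacates. In the calibrated
scenario this term dominates the early-period contribution table and then
fades — the same behaviour reported for the pre-boundary determinant in
published partitioning studies — while in a burn-in stationary cohort it is
zero like everything else.

For IBM the same split is pushed through the cell products
$\pi_c h_c$: the general-population term collects $\bar\pi\,\Delta\mu$, each
pool's term collects its size change at current death rates plus its
case-fatality change net of $\Delta\mu$, and the incident pool's size change
is divided among incidence, survival and carry by the diagonal recursion.
The survival term $\tilde T_S$ thus contains both the *pool-size* effect of
survival trends (more survivors → more future deaths) and the
*case-fatality* effect (each survivor dies at a different rate), at fixed
duration. These genuinely oppose each other — a lasting survival
deterioration first raises mortality through case fatality and is then
partly offset as the depleted pool produces fewer deaths — which is exactly
the transient the method is designed to expose.

One property is deliberately *not* symmetric: reversing the time axis
negates the log-derivative (tested), but the diagonal split is
time-directional, because cohorts flow forward. A "reverse-time" partition
would attribute to incidence what is really survival of reversed cohorts;
we do not offer one.

### Raw and model-based (smoothed) sources

`series_source = "raw"` differences the empirical cells directly. It is the
right choice for identity checks and for large cohorts, but single-cell
death counts (a handful per year × age × lag cell at desk scale) make the
derivative terms noisy.

`series_source = "smoothed"` (the default) mirrors the
empiric-versus-model-based strategy of parametric trend studies:

* cell series ($\pi_0$, $\pi_{00}$, $\mu$, pool death rates, $q$) are fitted
  across years with natural cubic splines (`df = 4` by default, on the
  identity scale with clamping at zero);
* the lag-level death rates are replaced by a pooled excess model
  $h(y,a,l) = \hat\mu(y,a) + \bar E_l\,\hat\phi(y)$: a fixed duration
  profile $\bar E_l$ (time-pooled excess per lag) scaled by one smooth
  calendar multiplier $\hat\phi(y)$ fitted by weighted least squares to
  *all* excess deaths jointly (with `df + 2` spline degrees of freedom — it
  pools every death, so it supports more flexibility than single cells);
* the continuation ratios become
  $\hat\sigma_l(y) = \kappa_l \exp(-E^\*_l\,\bar\phi(y))$, with $\kappa_l$ a
  per-lag baseline fitted to the observed pools ($\kappa_1 \approx 2$
  mechanically, because lag-0 cases contribute only partial first-year
  person-time).

Everything the model misses stays in the exact remainder and is routed to
the carry term, so closure survives modelling unchanged. Structural zeros —
lag-$l$ pools before any onset cohort is old enough to fill them — are
pinned at zero so the spline cannot ramp across the filling edge and read
the pool's appearance as a trend; for the same reason the boundary-year
onset cohort (depleted by the ascertainment proxies below) is excluded from
the spline fits and its comparisons are carried, not attributed.

### Contribution tables and phases

`relative_contributions()` emits $100\,T_k(y)/D(y)$, which sums to 100
within each year by construction. Years with $|D| < 10^{-6}$/yr are
suppressed rather than divided through (near trend reversals the shares
blow up into the thousands of percent — visible in published tables too),
and the one-sided edge years are excluded by default.
`classify_phases()` labels years by the signs of $D$ and its central
difference: accelerated/decelerated × increasing/declining, with
zero-derivative years inheriting a neighbour's label.

## Case ascertainment choices

* **Two-claim confirmation.** Onset is the earliest disease-coded claim
  confirmed by a second claim within 0.3 years; the window is inclusive,
  same-day duplicates do not confirm (a double-billed encounter must not
  self-confirm), and the scan continues past unconfirmed claims.
* **Coverage.** Persons with less than 20% coverage since 65 are excluded;
  exactly 20% is kept.
* **Pre-existing-at-65 proxy.** A pre-65 onset is unobservable in 65+
  claims. Operationally: persons first observed at their 65th birthday whose
  confirmed onset falls within the first 0.5 years are classified `PRE65`.
  The simulator plants claim pairs accordingly, so the proxy is exact for
  planted cases; genuinely incident onsets inside the proxy window are
  absorbed by it. This is the main ascertainment compromise, it is
  configurable (`pre65_window`), and the category-exactness test quantifies
  it (well under 10% of cases at default settings).
* **Pre-boundary proxy.** Persons already over 65 when observation starts
  whose confirmed onset falls within the first year are `PREBOUNDARY`. A
  side effect is that the boundary year itself has no ascertainable
  incidence; reported incidence effectively starts one year in, which is
  also why published analyses of this design lose their edge years.

## The synthetic cohort

The simulator is a continuous-time illness-death model, exact for its
stated hazards: piecewise-constant on (calendar year × integer age ×
completed duration) cells with exponential waiting times within cells, so
no discretization error enters. Persons enter at max(boundary, 65th
birthday) and exit at death, the 100th birthday, or the end of observation.

Default calibration (each value is a package choice, stated once here):

| parameter | default | rationale |
|---|---|---|
| incidence at 65, `b0` | solved so the uniformly age-standardized rate is 29.4/1000 in 1992 | published anchor for 1992 |
| age slope `theta_age` | 0.07/yr | incidence roughly doubles per decade of age |
| calendar trend `theta_cal` | -2.05%/yr to 2010, -0.3%/yr after | reaches the 19.9/1000 anchor in 2017 with the reported late levelling-off |
| background `m0`, `gamma` | 0.013, 0.085 | ~1.3% annual mortality at 65, doubling every ~8 years |
| background trend `delta_cal` | -0.3%/yr | slow secular improvement |
| first-year excess `e0` | 0.19 | 1-year survival near 0.75-0.76 in the early 1990s |
| duration decay `rho_dur` | 0.65 | excess fades over ~5 years; 3- and 5-year survival near 0.50/0.41 |
| excess trend `eta_cal` | -1.0%/yr to 2007, +0.5%/yr to 2013, +3.0%/yr after | survival improves, plateaus, then deteriorates; the late slope is set to the magnitude implied by published late-period survival *contributions*, not by the 1-year endpoints alone, which would be statistically invisible at desk scale |
| `prev65_frac` | 0.02 | small pre-65 diagnosed pool |
| `prevboundary_frac` | 0.11 | boundary prevalence near the overall prevalence level |
| claims | 4/yr after onset, 2% stray claims | free choices; real claim-frequency distributions are not published |

What the generator emulates: age- and calendar-dependent incidence,
Gompertz background mortality, duration-dependent excess with calendar
trends, both pre-existing pools, partial coverage, confirmable claim pairs
and unconfirmed noise claims. What it does not: geographic/sex/race
structure, disease subtypes, under-ascertainment of true cases (every true
case is confirmable by construction, so estimator tests can demand
exactness), realistic code mixes, and mortality thinning of the boundary
cohort's age profile (ages at the boundary are uniform; age standardization
makes every estimator conditional on age, so this affects precision, not
bias). Passing tests on this cohort therefore validate the *estimators and
the decomposition algebra*, not claims about any particular real
population.

With uniform standard weights the synthetic prevalence runs at 15-20 per
100 person-years — above the published 11-14.6, because uniform weights
load on the oldest ages where prevalence is highest; a younger standard
population brings the level down. Levels are anchors for shape, not
reproduction targets.

## Numerical choices

* Dates are decimal years; cells are half-open $[y, y+1) \times [a, a+1)$;
  person-time is apportioned exactly (conservation to $10^{-9}$ is a test).
* Continuation ratios are only compared when both stencil sides have a pool
  above $10^{-7}$; raw-mode ratios are clamped at 2.5 (a cohort cannot much
  more than double its prevalent share in a year; the legitimate lag-1
  timing factor is ~2) with the residue carried, so sparse cells cannot
  amplify along diagonals.
* Weights are renormalized once over ages with complete data (never per
  year inside the partition, which would break the additive identities).
* Smoothing never crosses structural zeros or the depleted boundary cohort.
* The derivative estimator is a central difference; both raw and smoothed
  sources are exposed because published work does not state which side of
  that choice it took.
* Kaplan-Meier (via `survival::survfit`) was chosen over life-table
  survival; horizons whose follow-up would leave the data are not emitted.
  Expected survival for the relative-survival ratio integrates
  $\mu(y,a)$ along each case's own year-age diagonal (an Ederer-style
  matched cohort); by default $\mu$ comes from the full cohort including
  cases (standard practice), with a `background = "noncases"` option that
  removes the disease's own contamination (roughly prevalence × excess).

## A short run

A deliberately small cohort keeps this vignette quick; the package's tests
run the same pipeline at 50,000-200,000 persons.

```{r run, message = FALSE}
cfg <- sim_config(n_persons = 20000, seed = 7)
res <- run_pipeline(cfg, out_dir = file.path(tempdir(), "hf-demo"))
res$rates |> filter(year %in% c(1994, 2005, 2017)) |>
  select(year, P, incidence, M, Mmu) |> mutate(across(-year, ~ round(.x, 1)))
```

```{r phases}
res$phases |> filter(outcome == "prevalence") |>
  count(phase)
```

```{r plot-derivatives, fig.alt = "Derivatives and partitioned determinants"}
plot_derivatives(res$partition_prev, res$partition_ibm)
```

## Known limitations

* The incidence/survival attribution needs the lag-resolved side table;
  person-year tables read back from CSV must be read with their companion
  lag file.
* The survival term's pool-size and case-fatality effects partially cancel
  by construction; at small $n$ the net term is noisy, and window averages
  (as used in the package's own tests) are the reliable summary.
* Early-window years are dominated by the boundary carry — a property of
  any finite observation window, not of the estimator; contribution tables
  are most interpretable once each age has passed its $(a-65)$-year filling
  transient.
* Confidence intervals for contributions are out of scope, as is any causal
  reading of the determinants.
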