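---
title: "Estimating children affected by maternal cancer: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating children affected by maternal cancer: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinloss)
```

## The estimation problem

Registries record *rates* — age-specific fertility, cancer incidence, cancer
mortality, child mortality — but usually cannot link mothers to children over
long historical periods. `kinloss` estimates, from rate surfaces alone, the
expected number of children under 18 whose mother is diagnosed with cancer
(*affected children*) or dies of cancer (*maternal orphans*), by calendar
year and child age. The estimates are indirect and model-based: no family
linkage is used anywhere.

## The demographic convolution

All bookkeeping is in completed years on the lexis grid: a child aged $k$ at
an event in year $y$ was born in year $y-k$ to a mother then aged $a-k$,
where $a$ is her age at the event. For a woman with an event at $(a, y)$ the
expected number of her children aged $k \in \{0,\dots,17\}$ and alive at the
event is

$$c(k \mid a, y) = r \cdot f(a-k,\; y-k)\cdot S(k;\; y-k),$$

where $f$ is the age-specific fertility rate (zero outside maternal ages
15–49), $S(k; b) = \prod_{j=0}^{k-1}\bigl(1-q(j, b+j)\bigr)$ is cohort child
survival built from annual death probabilities $q$ read along lexis
diagonals, and $r$ is the site's parity relative risk. Expected maternal
events are $E(a,y) = \lambda(a,y)\,P(a,y)$, the event rate times the female
population. The **new affected children** in year $y$ at child age $k$ are

$$N(y,k) = \sum_{a=15}^{66} E(a,y)\, c(k \mid a, y),$$

with maternal ages capped at 66 because $49 + 17 = 66$ is the oldest a
mother of a minor can be. **Prevalent** counts age each past event's
children forward under continued background survival, retaining them while
under 18:

$$P(y,c) = \sum_{d=0}^{c}\sum_a E(a,\,y-d)\; r\, f\bigl(a-(c-d),\; y-c\bigr)\,
S(c;\; y-c).$$

Output years are limited by a 17-year lookback: fertility available from
year $t_0$ supports new-count estimates from $t_0+17$, and prevalence
additionally needs the 17 preceding event years.

Modelling assumptions worth stating plainly:

* **Integer-year lexis approximation.** No mid-year corrections; a child
  born at maternal age $a-k$ is aged exactly $k$ in the event year. At
  one-year granularity this is the standard demographic approximation.
* **"Ever diagnosed" prevalence** counts only children born on or before
  the event year; the mother's post-event fertility and her own survival
  are not tracked, so a child can appear in both diagnosed-mother prevalence
  and orphan prevalence if the mother later dies.
* **No excess mortality for orphans**: children of deceased mothers keep
  background child survival.
* **No competing-risk coupling** between the diagnosis and death analyses;
  they are separate estimands computed from separate surfaces.

## Parity relative risks

Cancer risk is associated with parity for some sites (breast, cervix,
ovary). The RR of the cancer in parous versus nulliparous women enters the
model as a *single multiplicative factor* on the fertility attributed to
event-experiencing women, constant over maternal age. Consequently dividing
a site's estimates by its RR recovers the unadjusted estimates exactly: with
$r = 0.8$, removing the adjustment raises every count by exactly 25%. This
exact arithmetic is enforced by tests and is the package's primary
acceptance check. The shipped site panel (`default_panel()`) carries RR 1.0
for all 14 reporting groups and the all-sites aggregate — the breast and
cervical values in the literature are not authoritative defaults, so users
supply their own — plus a site-specific ovarian entry with the established
RR 0.8, applicable only to ovary-specific surfaces, not to the
female-genital-organs aggregate.

## Standardisation and summaries

Rates per 100,000 children are directly standardised over child age 0–17
with the World Standard Population 2000 in 1-year groups. The WHO standard
is published in 5-year groups (0–4: 8.86, 5–9: 8.69, 10–14: 8.60, 15–19:
8.47 per 100; Ahmad et al. 2001); we split each group uniformly into single
ages and renormalise the 0–17 slice to sum to one. Period summaries use
arithmetic means over inclusive 5-year windows; a changepoint at year $c$ is
summarised over the centred window $(c-2, c+2)$. Rate denominators accept
either mid-year or start-of-year child populations; the convention of the
input should be documented by its provider, as the model treats the counts
opaquely.

## Segmented Poisson trends

Trends in counts or rates are modelled as a continuous piecewise log-linear
function of calendar year with a log-exposure offset, Poisson likelihood,
and optional additive stratum effects (child age groups 0–5, 6–11, 12–17;
optionally crossed with maternal age groups 15–24 … 55–66, with expected
mother–child pairs as exposure). Per segment the annual percent change is
$APC = 100(e^{\beta}-1)$ with Wald 95% CIs on the log scale. The number of
changepoints (0–2) is chosen by $BIC = -2\log L + p\log n$, where $p$ counts
the intercept, segment slopes, changepoint locations and stratum effects.

Design choices that were genuinely open:

* **Exhaustive integer-year search.** Iterative segmented-regression
  algorithms are fast but locally convergent and tolerance-dependent. With
  yearly data the candidate set is small (about 1,100 changepoint pairs for
  55 years), so we search it exhaustively and return the global maximum
  likelihood — bit-reproducible and oracle-checkable. A minimum segment
  span of 3 years is enforced, and changepoints must be 3 years apart;
  BIC ties favour the simpler model.
* **Non-integer responses.** The modelled series are model-based expected
  counts, so the Poisson log-likelihood is evaluated at real-valued
  responses (its continuous extension). Fits go through `stats::glm` with
  the quasi-Poisson family — the identical maximum-likelihood solution
  without integer-response warnings — and covariance rescaled to dispersion
  1; an optional Pearson overdispersion inflation (`quasi = TRUE`) is off
  by default.
* **Conditional confidence intervals.** As in joinpoint-style tools, the
  segment CIs condition on the estimated changepoint locations. Simulation
  during development (55-year series, APCs +0.9%/−1.2%, counts 300–2,000
  per year) shows the post-break APC CI covers its true value in about 95%
  of replicates when the breakpoint is fixed at its true year, but only
  about 84–86% when it is estimated, because breakpoint uncertainty is not
  propagated. This is a known limitation of conditional Wald inference for
  segmented models, not an artefact of the exhaustive search; interpret CIs
  near changepoints cautiously.

## The synthetic registry and its microsimulation oracle

Real registry extracts of this kind are permit-restricted, so validation
uses a synthetic world whose structure mirrors the phenomena the method
must handle: a Gaussian-shaped fertility schedule over ages 15–49 whose
peak age drifts linearly older (default 27 → 31 across 1951–2022, echoing
the documented rise in maternal ages) while total fertility declines
(2.6 → 1.4); per-site incidence and mortality that are log-linear in age
and piecewise log-linear in calendar time with stated APCs; child mortality
declining 4% per year from a 3% infant death probability with a steep
age-profile decay; and constant population counts per single-year age
(35,000 women, 30,000 children per cell — Nordic-country magnitudes). All
surfaces are deterministic given the scenario; `fixture_small()` is a
30-year, 2-site instance with a built-in mortality changepoint used
throughout the tests.

The same scenario is realised as individual life histories by
`microsimulate()`:

* maternal events are independent annual Bernoulli draws per woman-year at
  the event rate, with no absorbing state — exactly the recurrent-hazard
  convention of the analytic estimand $E = \lambda P$;
* births of event-experiencing women are annual Bernoulli draws at
  $r \times f$, realising the multiplicative RR convention (a
  parity-mixture mechanism would be a different model and is deliberately
  not used);
* child deaths are realised by exact binomial thinning year by year, which
  is distributionally identical to per-child Bernoulli simulation and
  computed by an independent product loop, not by the analytic survival
  code.

One seeded RNG stream drives the simulation in a fixed iteration order
(site, event, cohort, event age), so results are bit-reproducible for a
given `n_women_per_cohort`. Tallies are scaled to population counts by
`female_pop / n_women_per_cohort`, and per-cell Monte-Carlo standard errors
are `scale * sqrt(raw count)` (the tallies are Poisson-like sums of
Bernoulli indicators). The headline validation — run in the test suite with
roughly 200,000 simulated women on a stationary 35-year scenario — requires
the analytic new/prevalent counts of both affected children and orphans to
fall within 4 standard errors of the realised tallies in at least 95% of
year cells.

What the synthetic world deliberately does *not* emulate: migration,
twinning, parity-dependent fertility heterogeneity, cohort effects beyond
the linear drifts, sex-specific child mortality, and correlation between a
mother's cancer risk and her children's survival. Passing the oracle
therefore demonstrates the estimator's internal correctness under its own
assumptions, not the validity of those assumptions in any real population.

## Problem sizes and numerical conventions

The test suite runs the microsimulation oracle at ~200,000 women, the trend
operating-characteristics study at 500 Poisson replicates of a 55-year
series, and the BIC no-overfit study at 200 replicates; these sizes give
Monte-Carlo noise comfortably below the asserted tolerances while keeping
the whole suite in the low minutes. Degenerate inputs are errors, not
silent results: incomplete rate rectangles, negative rates, fertility
outside ages 15–49, child death probabilities outside $[0,1]$, zero child
populations in a rate denominator, output years lacking the 17-year
lookback (all named with the offending cell), and trend segments with
all-zero counts (slope unidentifiable). Reported tables round counts to
integers and rates to one decimal only at display time.

## A worked example

```{r, eval = FALSE}
library(kinloss)
sc <- fixture_small()
cfg <- run_config(outdir = "kinloss-out", scenario = sc, sites = "Ovary")
est <- run_estimate(cfg)   # estimates.csv, rate_series.csv, summary.csv, periods.csv
tr  <- run_trends(cfg)     # trends.csv
subset(tr$table, event == "death" & measure == "new" & adjustment == "none")
```

The ovarian mortality trend in the fixture is constructed with APC +3%
until 1992 and −6% after; the fitted table recovers the 1992 changepoint
and two sections with CIs covering those values. The same functions accept
registry tables from disk (`run_config(inputs = ...)`) in the documented
`age,year,rate` / `age,year,count` CSV formats.
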