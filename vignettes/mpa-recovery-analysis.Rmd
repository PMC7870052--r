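---
title: "Growth-curve analysis of reef fish recovery under protection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve analysis of reef fish recovery under protection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpagrowth)
```

## The question

A no-take marine protected area (MPA) removes fishing mortality; the fish
assemblage inside it is then expected to rebuild towards the carrying
capacity of the habitat. Annual underwater visual censuses (UVC) along
fixed belt transects give a yearly series of density
(individuals 250 m^-2^) and biomass (g 250 m^-2^) for the whole assemblage
and for trophic subsets. Two questions drive the analysis: *what shape does
the recovery trajectory take* (still growing, or saturating at a carrying
capacity K?), and *how is that answer distorted when enforcement lapses for
a few years* in the middle of the series.

`mpagrowth` implements that pipeline end to end: census records to
descriptor series, a fixed suite of seven population-growth curves fitted
by nonlinear least squares, information-theoretic model selection, and
capacity estimation per enforcement period — together with a synthetic-data
generator that emulates the sampling design, so the whole chain is testable
without the original monitoring data.

## From census records to descriptor series

A sighting records a species on a 50×5 m^2^ transect with an ordinal
**abundance class** (nine classes) or an exact count, and a visual length
class (2-cm wide; 5-cm for large-bodied species). The conversion to
quantitative measures is:

* counts: class midpoints under a configurable `abundance_scheme()`. The
  original nine class limits live in field-protocol literature that the data
  do not carry, so the default ladder (1; 2–5; 6–10; 11–30; 31–50; 51–100;
  101–200; 201–500; 501–1000, arithmetic midpoints) is an explicit,
  replaceable object rather than a buried constant.
* lengths: class midpoint (lower bound + half width).
* weight: the allometric length-weight relationship W = a·L^b^ per species;
  species without published coefficients fall back to the isometric
  a = 0.01, b = 3 with a warning (any supplied coefficient table
  overrides this).

A **descriptor** is a species aggregation: `total`, `total_reduced`
(excluding pelagic species, whose large transient shoals otherwise dominate
the variance), one of seven trophic groups (PISC, MACRO, MICRO, OMNI, HERB,
PLAN, DETR), or a `_reduced` variant of any group (piscivores-reduced being
the one analysed by default). Transects surveyed in a year but holding no
matching sightings contribute explicit zeros — without this, yearly means
are biased upward.

Yearly series pool all transects of a year across sites
("global yearly mean"; SE = sample SD/√n). Site-mean pooling is available
as an option since the pooling unit is not dictated by the data; transect
pooling matches the variable one-to-three transects per site of the design.
The time axis is t = year − 1995 (protection inception), so the first
survey (1996) sits at t = 1; period sub-series keep this absolute axis,
because re-zeroing would silently change the meaning of the initial-value
parameters across periods.

## The seven growth families

| family | equation | long-run behaviour |
|---|---|---|
| linear | y = a + m·t | unbounded (constant rate) |
| exponential | y = a·e^{b·t} | unbounded (constant per-capita rate) |
| von Bertalanffy | y = K(1 − e^{−r(t−t0)}) | carrying capacity K |
| logistic | y = K / (1 + ((K−N0)/N0)e^{−r·t}) | carrying capacity K (symmetric sigmoid) |
| asymptotic | y = K + (N0−K)e^{−r·t} | carrying capacity K |
| Gompertz | y = K·e^{b·e^{r·t}} | carrying capacity K (asymmetric sigmoid) |
| Ricker | y = N0 + (a·t)e^{−b·t} | interior peak N0 + (a/b)e^{−1} at t = 1/b |

Two numerical conventions deserve note:

* **Gompertz sign constraint.** The printed form saturates at K only on the
  branch b < 0, r < 0 (then e^{r·t} → 0 and y → K from below). The fitter
  constrains both parameters to that branch, enforcing the family's
  ecological meaning of gradual approach to capacity; an unconstrained
  Gompertz with r ≥ 0 is classified `unbounded` with a warning.
* **von Bertalanffy / asymptotic equivalence.** The two families coincide
  under N0 = K(1 − e^{r·t0}); they are kept as distinct registry entries
  (each transcribed literally) and the test suite asserts that their
  minimal RSS agree, which doubles as an optimizer check.

## Fitting and model selection

Each family is fitted to the yearly means (unweighted; inverse-variance
weighting would change the estimand from "the mean trajectory" to something
SE-dependent, and the reference analysis fits the global means) by
Levenberg–Marquardt least squares. Start values are rule-based
(`initial_guess()`: K from 1.05× the series maximum, slopes from ordinary
least squares on y or log y), with up to 20 seeded, log-normally jittered
restarts; restarting stops early once three starts have converged. The
linear family is solved exactly by `lm()`. Series shorter than
n~params~ + 2 points yield a structured insufficient-data record instead of
a fit.

Selection uses AICc in its least-squares form

AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n − k − 1),

with k = n~params~ + 1, counting the estimated error variance — the
standard convention for nls-based selection (additive constants cancel in
ΔAICc). Fits within ΔAICc ≤ 2 of the best are treated as equivalently
supported, and among them the **greatest R²** (nonlinear R² = 1 − RSS/SStot)
is selected; residual ties break by lower AICc, then fewer parameters, so
selection is deterministic. Two consequences of the k convention are worth
knowing:

* a perfect fit (RSS numerically zero, which happens only on noiseless
  synthetic data) gets an explicit −∞ AICc sentinel and wins outright,
  flagged `perfect_fit`;
* a 4-point series (the 2015–2018 period) has n − k − 1 ≤ 0 for every
  family, so no model is rankable and the period's cells carry a structured
  skip. `fit_control(k_includes_sigma = FALSE)` restores ranking of
  2-parameter families on such short series for users who want the
  short-period trends anyway; the default stays with the conservative
  convention rather than changing the information criterion per period.

## Carrying capacity and the enforcement-lapse counterfactual

`capacity_from_fit()` maps the selected model's long-run behaviour to a
capacity estimate: K for saturating families (with the time to reach a
conventional, configurable 95% of it), the analytic peak for Ricker, and an
explicit "no finite capacity" record for growing linear/exponential
selections — absence of saturation is a result, not an error.

When the whole series saturates but the pre-lapse period (1996–2009) grew
exponentially, the question "what would capacity look like had enforcement
never lapsed?" is answered by `exponential_projection()`: the first-period
curve a·e^{b·t} evaluated at the whole-study horizon t = 23 years. The
horizon is exposed as a parameter because the underlying notion
("capacity from the initial exponential trend") admits more than one
reading; the output is always labelled `exponential_projection`, never
`asymptote`, so the two kinds of estimate cannot be silently mixed.

## The synthetic generator

`simulate_series()` draws yearly means around a known growth curve on the
real monitoring calendar (1996–2018 minus 1999, 2001, 2011, 2012 — 19
surveyed years). The default noise is multiplicative lognormal: biomass and
density series are positive and right-skewed, with scatter roughly
proportional to the level. σ = 0.05 on yearly means is the working regime
for the parameter-recovery experiments.

`simulate_survey()` generates the full design — years × sites × transects,
species drawn within trophic groups so that the group-aggregated expected
density tracks a configured trajectory exactly (species weights sum to the
group level; a mean-one lognormal transect effect adds realistic
overdispersion without biasing the expectation). Counts are emitted as
abundance classes via randomised rounding between adjacent class midpoints,
which makes the encode–decode cycle unbiased — a deliberate choice, since
naive binning of a Poisson count into the wide upper classes biases decoded
densities upward by tens of percent. Lengths are lognormal per species and
binned to the 2-cm/5-cm classes.

A surveillance lapse is modelled as a multiplicative depression of expected
levels during a year window (2010–2014, factor 0.3 by default). For the
series-level experiments the depression is *persistent*: growth resumes
after the lapse from the depressed level, which is how removal of standing
stock propagates, and it is the only reading consistent with whole-period
fits that saturate one to three orders of magnitude below the pre-lapse
exponential extrapolation. For survey-level simulation the lapse is
window-only by construction (the paired-simulation contract is that
affected years scale by the factor while others are untouched).

What the generator does *not* emulate: species-level population dynamics
(groups, not species, carry the signal), detectability and diver-avoidance
behaviour, size-structure dynamics (lengths are stationary per species),
and spatial structure beyond independent site/transect noise. Passing
recovery tests on synthetic data therefore validates the *estimation
chain*, not the ecological realism of any particular field series.

## Problem sizes and reproducibility

The Monte-Carlo experiments in the test suite and the acceptance script use
the scales at which the estimator behaviour stabilises while staying
desk-sized: 100 seeded replicates for parameter-recovery runs (median
recovered K within 5% of truth), 200 for the model-recovery rate (logistic
selected, or in the equivalent set, in ≥ 80% of replicates at σ = 0.05),
100 for the lapse experiment (pre-lapse exponential + whole-period
saturating in ≥ 70%), and 50 for the survey round-trip bias check
(mean relative bias < 10% at 9 transects/year). All randomness flows from
explicit integer seeds through an RNG-state-preserving wrapper; rerunning
any bundle with the same seed is byte-identical.

## Known limitations

* The abundance-class ladder is a configurable default, not the original
  protocol table; analyses of real data should substitute the protocol's
  class limits.
* Capacity estimates inherit every pathology of the selected curve: a
  Ricker selected on a still-rising series reports a peak that the data
  have not yet shown, and whole-period asymptotes estimated across a lapse
  are systematically low — which is precisely the effect the period
  analysis is designed to expose.
* The AICc k convention makes 4-point periods unrankable by default (see
  above).
* No formal protected-vs-control inference is attempted; control series
  are summaries for visual comparison, matching the reference analysis.
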