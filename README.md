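# mpagrowth

Growth-curve analysis of reef fish recovery inside marine protected areas
(MPAs), from underwater visual census (UVC) records to carrying-capacity
estimates.

## The problem

Inside a no-take MPA, fish density and biomass are expected to rebuild
towards the habitat's carrying capacity. Given annual belt-transect censuses
(species, nine-class ordinal abundances, 2-cm/5-cm visual length classes),
the analysis asks, per trophic group and response variable:

1. What is the shape of the recovery trajectory — still growing, or
   saturating?
2. If it saturates, at what level K and after how many years?
3. How does a mid-series enforcement lapse (poaching years) change the
   answer?

The pipeline converts sightings into per-transect density
(individuals·250 m⁻²) and biomass (g·250 m⁻², via the length-weight
relationship W = a·L^b), aggregates them into yearly mean ± SE series per
descriptor (total, total excluding pelagics, seven trophic groups), fits
seven population-growth families by nonlinear least squares —

- linear `y = a + m·t`, exponential `y = a·e^{b·t}` (unbounded),
- von Bertalanffy `y = K(1 − e^{−r(t−t₀)})`, logistic
  `y = K/(1 + ((K−N₀)/N₀)e^{−r·t})`, asymptotic `y = K + (N₀−K)e^{−r·t}`,
  Gompertz `y = K·e^{b·e^{r·t}}` (saturating at K),
- Ricker `y = N₀ + (a·t)e^{−b·t}` (interior peak) —

and selects the supported model by small-sample-corrected AIC,
`AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1)`, treating fits within
ΔAICc ≤ 2 as equivalently supported and picking the greatest
R² (= 1 − RSS/SStot) among them. Capacity estimates follow from the selected
family (asymptote K, Ricker peak, or an explicit "no finite capacity"), and
an exponential projection of the pre-lapse trend provides the
counterfactual capacity had enforcement never lapsed.

A synthetic-data module simulates both yearly descriptor series and full
transect-level survey datasets emulating the sampling design (19 surveyed
years over 1996–2018, multiple sites and transects, abundance-class
encoding, lapse windows), so every stage is testable without field data.

## Worked example

Simulate a biomass series from a known logistic trajectory on the real
monitoring calendar, fit all seven families, and recover the capacity:

```r
library(mpagrowth)

s <- simulate_series("logistic", c(K = 150000, N0 = 12000, r = 0.45),
                     sigma = 0.05, seed = 42, variable = "biomass")
sel <- select_growth(fit_all_growth(s, seed = 42))
sel
#> Model selection: logistic selected ( lowest_aicc )
#>           family    aicc  delta     r2
#>         logistic 354.204  0.000 0.9646
#>           ricker 357.300  3.096 0.9584
#>         gompertz 358.786  4.582 0.9550
#>  von_bertalanffy 369.020 14.817 0.9229
#>       asymptotic 369.020 14.817 0.9229
#>           linear 396.625 42.422 0.6086
#>      exponential 401.293 47.089 0.4996

capacity_from_fit(sel)
#> Capacity estimate [asymptote]: 147820  (reached ~10.93 y)  from logistic
```

The generating curve saturates at K = 150,000 g·250 m⁻²; with 5% lognormal
noise on 19 yearly means the pipeline selects the logistic (no other family
within ΔAICc ≤ 2) and recovers the capacity within 1.5%, reached to 95% at
about 11 years after protection.

## The analysis workflow

Numbered drivers under `analysis/` rerun the whole study shape on synthetic
data and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_survey.R` | simulate 23 years of transect censuses over the packaged 62-species community, with a 2010–2014 surveillance lapse |
| `02_build_series.R` | records → per-transect measures → yearly series for all descriptors, both areas |
| `03_fit_select.R` | fit + select per descriptor × variable × enforcement period (whole 1996–2018, pre-lapse 1996–2009, post-restoration 2015–2018) |
| `04_capacity.R` | capacity table, 95% recovery times, truth comparison |
| `05_lapse_experiment.R` | 100-replicate experiment: exponential growth with a persistent lapse — whole period saturates, pre-lapse stays exponential, and the pre-lapse projection exceeds the whole-period capacity by ~2 orders of magnitude |

Run them in order from the repository root after installing the package,
e.g. `Rscript analysis/01_simulate_survey.R`.

The packaged trait table (`species_traits()`) transcribes the study
community: 62 species in seven trophic groups, 19 pelagic, 52 also present
at the unprotected control area; `composition_summary()` reproduces the
published composition percentages from it.

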