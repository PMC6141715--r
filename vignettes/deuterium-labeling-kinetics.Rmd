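---
title: "Estimating lymphocyte turnover from heavy-water labeling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lymphocyte turnover from heavy-water labeling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(deulabel)
```

## The measurement and the question

When an animal drinks heavy water (²H₂O), deuterium equilibrates with its
body water and is incorporated into the deoxyribose of newly synthesized
DNA. Cells that divide during the labeling period become enriched in
deuterium; after label withdrawal, enrichment is diluted out as labeled
cells die and are replaced by unlabeled ones. The rise and fall of DNA
enrichment in a sorted cell population therefore encodes its turnover
rate — the fraction of cells replaced per day — and its reciprocal, the
expected lifespan.

`deulabel` implements this analysis for cross-sectional designs, in which
each animal is sacrificed at a single time point and the population curve
is assembled across animals: 4% heavy water for 28 days, 17 sacrifice
times spanning up- and down-labeling, two animals per time. The package
covers the full chain: body-water curve, granulocyte normalization,
kinetic-mixture fitting with stepwise model selection, residual-bootstrap
uncertainty, and a simulator that generates such studies with known
ground truth.

## The body-water curve

Plasma enrichment `S(t)` is the forcing function of every cell model.
During intake (`t ≤ τ`) it saturates toward a plateau `f` at the
body-water turnover rate `δ` (per day):

    S(t) = f (1 − exp(−δ t)),          t ≤ τ
    S(t) = f (1 − exp(−δ τ)) exp(−δ (t − τ)),   t > τ

After cessation the value reached at `τ` decays exponentially. We use the
frozen-at-`τ` form for the decay phase deliberately: it is the unique
reading under which the closed-form solutions below solve the label
differential equation exactly on both branches (we verified the agreement
numerically to ~1e-11), and it keeps `S` continuous at `τ`.

`τ` is an experimental constant and is never fitted. The plateau `f` is
*fitted* to plasma data by default (initialized at the nominal
drinking-water fraction 0.04), because the achieved plasma plateau can
undershoot the nominal fraction; `fix_f` in the configuration pins it to
the nominal value instead. Body-water fit uncertainty is not propagated:
the best-fit `S(t)` enters the cell models as a known function. With ~300
plasma observations against 2 parameters, its uncertainty is negligible
next to that of the cell fits.

## The cell-label model

Each sorted population is modeled as a mixture of kinetically homogeneous
subpopulations, a fraction `α_i` turning over at rate `p_i` per day.
Population sizes are assumed at steady state (production = loss), so each
subpopulation's enrichment `L_i` obeys

    dL_i/dt = p_i c S(t) − p_i L_i,  L_i(0) = 0,

where the amplification factor `c` accounts for the multiple hydrogen
positions of the adenosine deoxyribose moiety that can carry deuterium.
The closed-form solution during intake is

    L_i(t) = c f / (δ − p_i) [ δ(1 − e^{−p_i t}) − p_i(1 − e^{−δ t}) ],

with the matching decaying form after `τ`. Total enrichment is
`L(t) = Σ α_i L_i(t)`, the average turnover rate is `p = Σ α_i p_i`, and
the expected lifespan is `1/p`. Raw adenosine counts are never observed;
the model works entirely on the normalized enrichment fractions, so the
per-subpopulation amounts `l_i` and the total adenosine pool need no
representation of their own.

Two numerical points matter here:

* **Removable singularity at `p = δ`.** The prefactor `1/(δ − p)`
  cancels analytically but not in floating point. Within
  `|δ − p| < 1e-5 δ` the code evaluates a first-order series in
  `ε = δ − p` (`L = c f [1 − (1 + p t)e^{−p t}] + O(ε)` during intake),
  which keeps the curve smooth to ~1e-12 across the switch. A narrower
  band with the zeroth-order limit would leave cancellation noise of
  order 1e-9 just outside it.
* **Independent oracle.** `enrichment_ode()` integrates the differential
  form with `deSolve::lsoda`, piecewise over `[0, τ]` and `[τ, T]` so the
  kink in `S` at `τ` never degrades accuracy. The test suite holds the
  closed form to within 1e-6 of this oracle over random parameter draws;
  observed agreement is ~1e-10.

## Granulocyte normalization

Measured enrichment never reaches `c·f` on the fraction scale the GC/MS
calibration reports, and `c` and `f` are not separately identifiable from
cell data. Granulocytes resolve this: they turn over within days, so
their enrichment plateaus at the maximum any fully dividing population
could attain. `fit_granulocyte_asymptote()` fits a single homogeneous
population with free amplitude to the raw granulocyte curve; the fitted
amplitude is the asymptote, and `scale_enrichment()` divides all cell
observations by it. After scaling, every cell fit fixes `c·f ≡ 1`, so a
fully turned-over population plateaus at 1.

Design choices, each of which was genuinely open:

* The granulocyte model is the *minimal* one consistent with its purpose
  (asymptote estimation): one population, free amplitude, plus an
  optional maturation delay (`allow_delay`) that is off by default. On
  data generated without a delay, enabling it changes the asymptote by
  well under 1%.
* One pooled asymptote is used for the whole study, matching the
  cross-sectional design; per-animal asymptotes are not estimable from
  one granulocyte measurement per animal.
* Asymptote uncertainty is not propagated into cell fits; the scaling is
  a single constant. The pipeline can be repeated over granulocyte
  bootstrap replicates for sensitivity, but that is an analysis choice,
  not a default.

## Fitting, transform, and parameterization

All least squares are computed on arcsine-square-root transformed
fractions, `z = arcsin √x`: enrichment data are proportions, and this
transform approximately stabilizes their variance, which is also what
justifies pooling residuals in the bootstrap. Values pushed outside
[0, 1] by noise are preserved in the data layer and clamped only inside
the transform, with clamp counts logged.

The mixture parameters are estimated by multi-start local optimization:

* rates on a log scale, fractions by stick-breaking on a logistic scale,
  so positivity and the simplex constraint hold by construction and no
  constrained optimizer is needed;
* 25 quasi-random (Latin hypercube) starts by default, rates log-uniform
  on [1e-4, 1]/day, fractions uniform on the simplex — the RSS surface of
  exponential mixtures is multimodal and a single start is not
  trustworthy;
* Nelder–Mead per start with BFGS polish of the best candidates; the
  one-rate model uses Brent's method on an interval instead;
* for `n > 1`, additional *nested* starts derived from the `n − 1` fit:
  one duplicates the fastest subpopulation with its fraction split
  (leaving the objective value exactly unchanged), two probe a fast and a
  slow extra subpopulation at near-zero fraction. These guarantee that
  RSS is non-increasing in `n`, so nested-model tests are well posed.

Models are reported in canonical form (descending rate, ties by
descending fraction), which resolves label-switching when comparing fits.

## How many subpopulations?

The number of kinetically distinct subpopulations is chosen stepwise:
fit `n = 1`, then repeatedly ask whether `n + 1` is justified. The
stopping rule must operationalize "the average turnover rate no longer
changes significantly", and we use two criteria jointly, both
configurable:

1. a nested-model F-test on the transformed-scale RSS (2 extra
   parameters per added subpopulation) at α = 0.05, and
2. a relative change in average turnover of more than 5%.

The second guard matters in practice: on near-noiseless data the RSS of
an already-perfect fit is numerical noise, and the F-statistic between
two such fits is meaningless — but the average turnover barely moves, so
the guard correctly stops the search. Redundant subpopulations also
collapse on their own (fraction → 0 or coinciding rates), mirroring how
kinetically homogeneous populations behave under an over-specified model.

In the validation studies the selector's hypothesis space is {1, 2}
(`max_n = 2`): the scientific question there is one- versus
two-subpopulation kinetics, which is also the distinction that matters
for memory T-cell data of this design. The pipeline default is
`max_n = 3`.

## Bootstrap uncertainty

Confidence intervals come from a residual-resampling bootstrap:
transformed-scale residuals of the optimal fit are resampled with
replacement, added to the fitted transformed predictions,
back-transformed (`sin² z`, clamped to the transform's range, clamps
counted), and the model is refitted with the same `n`. 500 replicates by
default; 95% intervals are the 2.5th/97.5th percentiles of the replicate
estimates using inverse-ECDF (type-1) quantiles, so two replicates give
exactly (min, max). Replicate refits warm-start at the point estimate
plus 3 fresh quasi-random starts; failed refits are dropped and counted,
and more than 20% failures marks the result with a warning status.
Everything is driven by one seed, with per-replicate child seeds, so
results are bit-reproducible and independent of evaluation order.

Residuals are pooled across all observations of the fitted subset. That
assumes homoscedasticity on the transformed scale — which is precisely
what the variance-stabilizing transform is for — and is the reason the
simulator also injects noise on that scale.

`compare_turnover()` pairs independent replicates of two fits to form
the bootstrap distribution of the turnover-rate difference and reports
whether its 95% interval excludes zero. It is a screening device, not a
formal test.

## What the simulator emulates, and what it does not

`simulate_study()` reproduces the statistical structure the estimator
assumes: cross-sectional sacrifice (each animal contributes cell and
granulocyte observations at exactly one day), longitudinal plasma
sampling up to sacrifice, raw cell values generated from the mixture
model with the truth's amplification and plasma plateau, and Gaussian
noise of SD 0.02 on the arcsine-square-root scale. The default design —
17 sacrifice times at 4-day spacing from day 3 to 67, two animals each,
34 animals total, 4% heavy water for 28 days — mirrors the goat study
template; the actual sacrifice and plasma days of that study are not
published, so the schedule here is a stated placeholder with the same
structure. `goat_study_truth()` fixes plausible magnitudes: memory
T-cell lifespans of roughly 30–140 days, two-subpopulation kinetics for
CD4 memory cells everywhere and for blood CD8 memory cells, single
populations elsewhere, granulocyte turnover 0.3/day, amplification 1.7.

Deliberately **not** simulated: inter-animal random effects (the
estimator pools animals, so the generator does too), label recycling
from dying cells, thymic versus peripheral division for naive cells
(the fitted rate is total production), flow-sorting impurities, and
GC/MS calibration error beyond the transformed-scale noise. Passing
recovery tests therefore show the estimator is correct *under its own
assumptions*; they cannot show robustness to, say, animal-level
heterogeneity that the model ignores.

## Validation studies and their problem sizes

The test suite exercises the pipeline at the full study scale:

* oracle agreement over 100 random parameter draws × 200-point grids;
* noise-free end-to-end recovery of all 12 population lifespans of the
  goat-like truth within 1% (observed: ~1e-6 %);
* noisy recovery over 100 replicate studies with single-population
  truths spanning 30–140 days (median lifespan error observed ≈ 7–8%,
  required ≤ 15%);
* selection accuracy over 50 + 50 replicate studies (observed ≥ 96%
  correct at n = 1, moderate noise; 100% at n = 2 for well-separated
  rates under low noise);
* CI coverage over 200 studies with 100 bootstrap replicates each
  (observed ≈ 90%, required ≥ 85% — small-sample percentile bootstrap
  runs slightly below nominal).

These sizes are the package's validation design; `scripts/acceptance.R`
recomputes all of them from scratch at any seed.

## Known limitations

* At the realistic noise level, two-subpopulation kinetics with modest
  rate separation are sometimes indistinguishable from one population at
  n = 34; the selector then (correctly, by its criterion) returns the
  simpler model, and the lifespan estimate inherits a small bias. This
  is a property of the design, not of the optimizer.
* Percentile bootstrap intervals from 17 design points can exclude the
  point estimate in pathological fits; the package asserts only
  lower ≤ upper.
* The steady-state assumption is structural: if population sizes change
  materially during the study, the fitted rates are effective, not
  mechanistic.
* One granulocyte asymptote is shared across animals and days;
  systematic drift in maximum label availability would bias all scaled
  values coherently.
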