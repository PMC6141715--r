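# deulabel

Turnover rates and expected lifespans of leukocyte populations from
*in vivo* heavy-water (²H₂O) labeling studies.

When an animal drinks heavy water, dividing cells incorporate deuterium
into the deoxyribose of newly synthesized DNA. The rise of DNA enrichment
during labeling and its decay afterwards encode how fast a cell
population is replaced. `deulabel` turns cross-sectional enrichment
measurements — plasma body water, granulocytes, and sorted T-cell subsets
from blood, bone marrow (BM) and lymph node (LN) — into estimates of
average turnover rates and lifespans, with model selection for kinetic
heterogeneity and bootstrap confidence intervals. Because raw labeling
datasets of this kind are rarely deposited, the package ships a
simulator that generates complete studies with known ground truth, so
the whole pipeline is testable end to end.

## The model

Plasma enrichment follows a saturation/decay curve with plateau *f* and
body-water turnover δ (per day), label stopping at day τ:

    S(t) = f (1 − e^{−δt})                      t ≤ τ
    S(t) = f (1 − e^{−δτ}) e^{−δ(t−τ)}          t > τ

Each sorted population is a mixture of kinetically homogeneous
subpopulations (fraction α_i, turnover rate p_i) at steady state, whose
DNA enrichment obeys dL_i/dt = p_i·c·S(t) − p_i·L_i, with *c* an
amplification factor for the multiple labelable hydrogen positions of
adenosine deoxyribose. Fits use the closed-form solution; totals are
L(t) = Σ α_i L_i(t). The average turnover rate is p = Σ α_i p_i, and the
expected lifespan is 1/p (days).

All enrichment is normalized by the **granulocyte asymptote** — the
plateau of a fast, fully turning-over population — which absorbs *c·f*;
fitting is least squares on arcsin(√x)-transformed fractions; the number
of subpopulations is chosen stepwise (nested F-test at α = 0.05 plus a
5% minimum change in average turnover); 95% CIs come from resampling the
fit residuals 500 times.

## Worked example

Simulate a goat-like study (34 animals, 17 sacrifice times, 4% ²H₂O for
28 days, measurement noise SD 0.02 on the transformed scale), keep the
CD8 memory subsets, and run the full pipeline:

```r
library(deulabel)

design <- study_design(seed = 7L)
truth  <- goat_study_truth()
sim    <- simulate_study(design, truth)
obs    <- sim$observations
obs    <- obs[obs$subset %in% c("plasma", "granulocyte", "cd8_memory"), ]

report <- run_pipeline(obs[obs$subset == "plasma", ],
                       obs[obs$subset != "plasma", ],
                       run_config(n_boot = 500, seed = 7L))
print(report)
#> Labeling-kinetics pipeline report
#>   body water: f = 0.039689, delta = 0.10436 /day
#>   granulocyte asymptote: 0.073559
#>   blood:cd8_memory   n = 2, lifespan 39.6 d [23.87, 45.52]
#>   bm:cd8_memory      n = 1, lifespan 62.91 d [57.11, 74.38]
#>   ln:cd8_memory      n = 1, lifespan 140.2 d [119.8, 163.1]
```

Reading the output: the plasma plateau and body-water turnover are
re-estimated from the simulated plasma samples (truth: 0.04 and
0.1/day); every cell value is divided by the fitted granulocyte
asymptote; blood CD8 memory cells are best described by **two**
kinetically distinct subpopulations while BM and LN need only one; and
each lifespan carries a 95% residual-bootstrap interval in days. The
simulation truths for these three groups are 32, 54 and 136 days.
Compartments are compared by pairing bootstrap replicates:

```r
print(report$comparisons$cd8_memory$`blood vs bm`)
#> Turnover difference (A - B): 0.0093606 /day, 95% CI [0.0062165, 0.026339] (interval excludes 0)
```

`plot_fits(report, cells, "figures")` renders each fit over its scaled
data with the label-cessation day marked.

## Analysis scripts

The `analysis/` directory holds the study workflow as numbered drivers,
each a thin narrative over package functions, writing tables under
`results/`:

1. `01_simulate_study.R` — generate the cross-sectional study and its
   ground-truth sidecar
2. `02_fit_body_water.R` — plasma enrichment/decay curve
3. `03_granulocyte_scaling.R` — granulocyte asymptote and scaling
4. `04_fit_cell_kinetics.R` — stepwise fits + bootstrap for all
   (compartment, subset) groups
5. `05_compare_and_plot.R` — cross-compartment comparisons and figures

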