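#!/usr/bin/env Rscript
# Estimate the maximum attainable DNA enrichment from the granulocyte
# up-/down-labeling curve and scale all cell-subset observations by it.
# Granulocytes turn over within days, so their plateau marks the ceiling
# any fully dividing population could reach; scaling by it absorbs the
# amplification factor and the plasma plateau, letting cell fits fix
# that product to 1.

library(deulabel)

cells <- read_observations("results/data/cells.csv")
bwp <- jsonlite::read_json("results/body_water_fit.json",
                           simplifyVector = TRUE)
bw <- body_water_params(bwp$f, bwp$delta, bwp$tau)

gran <- fit_granulocyte_asymptote(cells, bw, seed = 3L)
print(gran)

truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)
cat(sprintf("True asymptote %.5f; estimated %.5f (%.2f%% off)\n",
            truth$granulocyte$asymptote, gran$asymptote,
            100 * abs(gran$asymptote - truth$granulocyte$asymptote) /
              truth$granulocyte$asymptote))

subsets <- cells[cells$subset != "granulocyte", ]
scaled <- scale_enrichment(subsets, gran)
write_observations(scaled, "results/cells_scaled.csv")
cat(sprintf("Scaled %d cell observations -> results/cells_scaled.csv\n",
            nrow(scaled)))
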