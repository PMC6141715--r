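#!/usr/bin/env Rscript
# Generate the cross-sectional heavy-water labeling study used by the
# downstream analysis scripts: 34 animals, 17 sacrifice times (day 3-67),
# 4% heavy water for 28 days, measurement noise SD 0.02 on the
# arcsine-square-root scale, with known ground-truth kinetics.

library(deulabel)

design <- study_design(seed = 20269L)
truth <- goat_study_truth()
print(design)
print(truth)

sim <- simulate_study(design, truth)
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
write_study(sim, "results/data")

obs <- sim$observations
write_observations(obs[obs$subset == "plasma", ],
                   "results/data/plasma.csv")
write_observations(obs[obs$subset != "plasma", ],
                   "results/data/cells.csv")

cat(sprintf(
  "\nWrote %d observations (%d plasma, %d granulocyte, %d cell-subset)\n",
  nrow(obs), sum(obs$subset == "plasma"),
  sum(obs$subset == "granulocyte"),
  sum(!obs$subset %in% c("plasma", "granulocyte"))))
cat("Truth sidecar in results/data/truth.json; observations in",
    "results/data/{plasma,cells}.csv\n")
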