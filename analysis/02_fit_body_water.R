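#!/usr/bin/env Rscript
# Fit the plasma body-water enrichment/decay curve S(t). Its best fit is
# the forcing function for every cell-population label model downstream;
# the plateau is fitted freely (initialised at the nominal 4%) and the
# cessation day tau = 28 is an experimental constant.

library(deulabel)

plasma <- read_observations("results/data/plasma.csv")
fit <- fit_body_water(plasma, tau = 28, seed = 2L)
print(fit)

truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)
cat(sprintf(
  "\nRecovery against simulation truth: f %.5f (true %.5f), delta %.5f (true %.5f)\n",
  fit$bw$f, truth$bw$f, fit$bw$delta, truth$bw$delta))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(f = fit$bw$f, delta = fit$bw$delta, tau = fit$bw$tau,
       rss = fit$rss, n_obs = fit$n_obs),
  "results/body_water_fit.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/body_water_fit.json\n")
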