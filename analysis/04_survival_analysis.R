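#!/usr/bin/env Rscript
# Survivorship, cumulative hazard (-ln S) and the Gompertz slope of the
# extracted lifespans.

suppressMessages(library(mpsr))

lifespans <- read.csv("results/extraction/lifespans.csv")
dir.create("results/survival", showWarnings = FALSE, recursive = TRUE)

sc <- survival_curves(lifespans$lifespan_h, lifespans$censored,
                      n_boot = 1000, seed = 21)
print(sc)
write.csv(sc$curve, "results/survival/survival.csv", row.names = FALSE)

gs <- gompertz_slope(sc, n_boot = 1000, seed = 22)
message(sprintf("Gompertz slope (ln cumulative hazard vs age): %.3f 1/h, 95%% CI [%.3f, %.3f], fit window %.0f-%.0f h",
                gs$slope, gs$ci[1], gs$ci[2], gs$fit_window[1],
                gs$fit_window[2]))
jsonlite::write_json(
  list(lifespan_mean = sc$lifespan_mean, lifespan_cv = sc$lifespan_cv,
       quantiles = as.list(sc$quantiles), gompertz_slope = gs$slope,
       gompertz_ci = gs$ci, fit_window = gs$fit_window),
  "results/survival/summary.json", auto_unbox = TRUE, digits = NA)
message("Wrote results/survival/")
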