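#!/usr/bin/env Rscript
# Cross-sectional damage statistics with bootstrap errors, the
# initial-condition analysis (do starting states predict lifespan?), damage
# autocorrelation, remaining-lifespan alignment and the twilight analysis.

suppressMessages(library(mpsr))

windows <- read.csv("results/extraction/windows.csv")
lifespans <- read.csv("results/extraction/lifespans.csv")
covariates <- read.csv("results/cohort/covariates.csv")
dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)

# ages with a usable population
life <- lifespans$lifespan_h[match(windows$cell_id, lifespans$cell_id)]
alive <- is.na(life) | life > windows$window_center_h
n_by_age <- tapply(alive & windows$valid, windows$window_center_h, sum)
ages <- as.numeric(names(n_by_age))[n_by_age >= 30]

cs <- cross_sectional_stats(windows, lifespans, ages = ages,
                            observable = "uptake", n_boot = 1000, seed = 11)
write.csv(cs, "results/stats/cross_sections.csv", row.names = FALSE)
message("Cross-sections (uptake): mean rises ",
        sprintf("%.2f -> %.2f", cs$mean[1], cs$mean[nrow(cs)]),
        "; CV falls ", sprintf("%.2f -> %.2f", cs$cv[1], cs$cv[nrow(cs)]),
        "; skewness falls ",
        sprintf("%.2f -> %.2f", cs$skewness[1], cs$skewness[nrow(cs)]))

ac <- do.call(rbind, lapply(head(ages, -1), function(a) {
  r <- tryCatch(damage_autocorrelation(windows, lifespans, a, n_boot = 1000,
                                       seed = 12), error = function(e) NULL)
  if (is.null(r)) NULL else
    data.frame(age_h = a, r = r$r, se = r$se, n_pairs = r$n_pairs)
}))
write.csv(ac, "results/stats/autocorrelation.csv", row.names = FALSE)
message(sprintf("Lag-7 h damage autocorrelation: %.2f at %g h -> %.2f at %g h",
                ac$r[1], ac$age_h[1], ac$r[nrow(ac)], ac$age_h[nrow(ac)]))

u0 <- setNames(covariates$initial_uptake, covariates$cell_id)
icr <- initial_condition_analysis(lifespans, u0, covariates, split = 4)
print(icr)
jsonlite::write_json(
  list(spearman = icr$spearman, split = icr$split, r_high = icr$r_high,
       r_low = icr$r_low, regression_r2_all = icr$regression_r2_all,
       regression_r2_low = icr$regression_r2_low),
  "results/stats/initial_conditions.json", auto_unbox = TRUE, digits = NA)

rl <- remaining_lifespan_view(windows, lifespans)
write.csv(rl, "results/stats/remaining_lifespan.csv", row.names = FALSE)
near <- rl$sd_damage[which.min(rl$time_before_death_h)]
far <- rl$sd_damage[which.max(rl$time_before_death_h)]
message(sprintf("Damage dispersion: sd(X) = %.2f at %g h before death vs %.2f at %g h",
                near, min(rl$time_before_death_h), far,
                max(rl$time_before_death_h)))

truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)
tw <- twilight(windows, lifespans, threshold_x = 2, x_c = truth$x_c,
               n_boot = 1000, seed = 13)
print(tw)
write.csv(tw$table, "results/stats/twilight.csv", row.names = FALSE)
message("Wrote results/stats/")
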