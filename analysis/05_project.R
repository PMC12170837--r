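#!/usr/bin/env Rscript
# Stage 5: burden projection to 2100.
#
# Runs the attribution-to-burden chain for every year of the warming
# trajectory, in the primary mode (2023 prevalence and population held
# constant) and the sensitivity mode (UN-style population forecast plus a
# linear ramp to +30% OSA prevalence by 2050).

suppressPackageStartupMessages(library(osaheat))
weather <- read_daily_series("results/weather.csv")
curve <- read_curve_csv("results/curve_osa.csv")
cp <- read_country_params("results/country_params.csv")[[1]]
cp$pop_forecast <- data.frame(year = 2023:2100,
                              apop = cp$apop * (1 + 0.002 * (0:77)))
clim <- climatology_1950_1990(weather)

fixed <- project_scenario(curve, weather, clim, cp, years = 2023:2100,
                          mode = "fixed")
sens <- project_scenario(curve, weather, clim, cp, years = 2023:2100,
                         mode = "sensitivity")
write.csv(fixed, "results/projection_fixed.csv", row.names = FALSE)
write.csv(sens, "results/projection_sensitivity.csv", row.names = FALSE)

b23 <- fixed$daly_mean[fixed$year == 2023]
b2100 <- mean(fixed$daly_mean[fixed$year >= 2096])
message(sprintf("DALYs per year, primary mode: %.0f (2023) -> %.0f (2096-2100 mean), a %.1f-fold increase",
                b23, b2100, b2100 / b23))
cum_fixed <- attr(fixed, "cumulative")
cum_sens <- attr(sens, "cumulative")
message(sprintf("Cumulative 2023-2100 DALYs: %.2f million (primary), %.2f million (sensitivity, +%.0f%%)",
                cum_fixed[["daly_mean"]] / 1e6, cum_sens[["daly_mean"]] / 1e6,
                100 * (cum_sens[["daly_mean"]] / cum_fixed[["daly_mean"]] - 1)))
message(sprintf("Cumulative labor loss: %.1f billion USD (primary)",
                cum_fixed[["labor_loss_mean"]] / 1e9))

write_manifest("results/manifest_05_project.json", "project",
               inputs = list(weather = "results/weather.csv",
                             curve = "results/curve_osa.csv"),
               config = list(years = c(2023, 2100), modes = c("fixed", "sensitivity")),
               seed = NA)
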