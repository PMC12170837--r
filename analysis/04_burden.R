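#!/usr/bin/env Rscript
# Stage 4: 2023 health and productivity burden.
#
# Converts the 2023 excess risk into years of life lost (via OSA-related
# fatal motor-vehicle accidents), years lived with disability, DALYs, their
# monetary value, and workplace presenteeism/absenteeism with the resulting
# labor loss. Parametric triplets (MVA risk ratio 0.5/1/1.5, disability
# weight 0.05/0.08/0.11, DALY value 1x/2x/3x GDP per capita) carry the
# wellbeing uncertainty; the curve's 95% CI envelope carries the
# productivity uncertainty.

suppressPackageStartupMessages(library(osaheat))
weather <- read_daily_series("results/weather.csv")
curve <- read_curve_csv("results/curve_osa.csv")
cp <- read_country_params("results/country_params.csv")[[1]]
clim <- climatology_1950_1990(weather)

ex <- daily_excess_risk(curve, weather, clim, year = 2023)
ex_lo <- osaheat:::excess_at_envelope(curve, weather, clim, 2023, "lower")
ex_hi <- osaheat:::excess_at_envelope(curve, weather, clim, 2023, "upper")
burden <- burden_for_year(ex, cp, burden_params(),
                          excess_lower = ex_lo, excess_upper = ex_hi)
write.csv(burden, "results/burden_2023.csv", row.names = FALSE)

fmt <- function(x) format(round(x), big.mark = ",", scientific = FALSE)
message(sprintf("2023 warming-attributable burden for %s:", cp$label))
message(sprintf("  excess OSA person-days: %s", fmt(burden$person_days)))
message(sprintf("  YLL:  %s (%s to %s)", fmt(burden$yll_mean),
                fmt(burden$yll_lower), fmt(burden$yll_upper)))
message(sprintf("  YLD:  %s (%s to %s)", fmt(burden$yld_mean),
                fmt(burden$yld_lower), fmt(burden$yld_upper)))
message(sprintf("  DALY: %s (%s to %s)", fmt(burden$daly_mean),
                fmt(burden$daly_lower), fmt(burden$daly_upper)))
message(sprintf("  wellbeing cost: %.2f (%.2f to %.2f) billion USD",
                burden$cost_mean / 1e9, burden$cost_lower / 1e9,
                burden$cost_upper / 1e9))
message(sprintf("  presenteeism: %s days; absenteeism: %s days",
                fmt(burden$presenteeism_mean), fmt(burden$absenteeism_mean)))
message(sprintf("  labor loss: %.2f (%.2f to %.2f) billion USD",
                burden$labor_loss_mean / 1e9, burden$labor_loss_lower / 1e9,
                burden$labor_loss_upper / 1e9))

write_manifest("results/manifest_04_burden.json", "burden",
               inputs = list(weather = "results/weather.csv",
                             curve = "results/curve_osa.csv",
                             params = "results/country_params.csv"),
               config = list(year = 2023), seed = NA)
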