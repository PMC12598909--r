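#!/usr/bin/env Rscript
# Mixed-effects ANOVA of fluxes and biomass: fertilization x plot fixed
# effects (year collapses to one level in a single-season run), chamber and
# measurement date as random intercepts, non-significant interactions
# pruned in one step.

library(peatflux)

camp <- readRDS("scratch/campaign.rds")
kept <- readRDS("scratch/kept_records.rds")

for (g in c("co2", "ch4", "n2o")) {
  d <- kept[kept$gas == g, ]
  d$date <- as.Date(d$timestamp)
  fit <- suppressMessages(fit_with_pruning(
    d, "flux", fixed = c("fertilization", "plot"),
    random = c("chamber_id", "date")))
  cat("\n==", toupper(g), "flux ==\n")
  print(fit)
  write.csv(fit$table, sprintf("results/anova_%s.csv", g),
            row.names = FALSE)
}

bio <- camp$biomass
bio$date <- bio$harvest_date
fit <- suppressMessages(fit_with_pruning(
  bio, "dry_biomass_t_ha", fixed = c("fertilization", "plot"),
  random = c("chamber_id", "date")))
cat("\n== Dry biomass ==\n")
print(fit)
write.csv(fit$table, "results/anova_biomass.csv", row.names = FALSE)
cat("written: results/anova_{co2,ch4,n2o,biomass}.csv\n")
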