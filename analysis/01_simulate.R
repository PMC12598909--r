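#!/usr/bin/env Rscript
# Generate the synthetic chamber campaign that stands in for the field data:
# 5 plots x 2 fertilization dosages x 3 chambers, 8-h closure cycle,
# May-October season at 69.5 deg N, 20% of scheduled closures observed.
# Writes the driver/truth/biomass tables under results/ and caches the full
# campaign (including 1-Hz traces) under scratch/ for the later stages.

library(peatflux)

seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

camp <- gen_campaign(campaign_config(seed = seed), seed = seed)

cat(sprintf("chambers: %d, retained closures: %d, trace samples: %d\n",
            nrow(camp$chambers), nrow(camp$measurements),
            nrow(camp$traces)))
cat(sprintf("season hours per plot: %d\n",
            nrow(camp$drivers) / camp$config$n_plots))
tru <- tapply(camp$truth$co2, camp$truth$chamber_id, sum) * 1e-5
cat("true seasonal CO2 budgets per plot (t/ha):\n")
print(round(tapply(tru, camp$chambers$plot[match(as.integer(names(tru)),
      camp$chambers$chamber_id)], mean), 2))

write.csv(camp$drivers, "results/drivers.csv", row.names = FALSE)
write.csv(camp$truth, "results/truth.csv", row.names = FALSE)
write.csv(camp$biomass, "results/biomass.csv", row.names = FALSE)
write.csv(camp$measurements, "results/measurements.csv", row.names = FALSE)
saveRDS(camp, "scratch/campaign.rds")
cat("written: results/{drivers,truth,biomass,measurements}.csv\n")
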