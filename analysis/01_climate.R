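#!/usr/bin/env Rscript
# Synthetic season: one smooth daily climate series (temperature + incident
# PAR) standing in for a multi-site, multi-year average, used by every
# simulation downstream. Writes results/climate.csv.

suppressPackageStartupMessages(library(canomix))
dir.create("results", showWarnings = FALSE)

SEED <- 1L
climate <- generate_climate(n_days = 330, seed = SEED)
write.csv(climate, "results/climate.csv", row.names = FALSE)

tt <- thermal_time(climate)
cat(sprintf("Season of %d days from sowing (seed %d)\n", nrow(climate), SEED))
cat(sprintf("  mean temperature     %.2f degC (min %.1f, max %.1f)\n",
            mean(climate$temp_c), min(climate$temp_c), max(climate$temp_c)))
cat(sprintf("  incident PAR         %.1f-%.1f mol m-2 d-1\n",
            min(climate$par_mol_m2_d), max(climate$par_mol_m2_d)))
cat(sprintf("  cumulative thermal time %.0f degCd (maturity needs ~%.0f)\n",
            max(tt), dev_defaults()$maturity_tt +
              max(dev_defaults()$emergence_delay_range)))
cat("Wrote results/climate.csv\n")
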