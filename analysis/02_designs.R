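#!/usr/bin/env Rscript
# Experiment designs: a 10-D maximin LHS over the ref/diff mixture space and
# a 5-D maximin LHS over plant-scale trait ranges for the pure stands (the
# reference experiment used 5,000 and 1,000 points; this desk-scale rerun
# uses 96 and 48). Writes results/design_mixture.csv / design_pure.csv.

suppressPackageStartupMessages(library(canomix))
dir.create("results", showWarnings = FALSE)

SEED <- 1L
designs <- make_designs(n_mixture = 96, n_pure = 48, seed = SEED)

for (k in c("mixture", "pure")) {
  d <- designs[[k]]
  write.csv(as.data.frame(d$points),
            sprintf("results/design_%s.csv", k), row.names = FALSE)
  cat(sprintf("%s design: %d points x %d dims, maximin min distance %.4f\n",
              k, nrow(d$points), ncol(d$points), d$min_dist))
}
cat("Wrote results/design_mixture.csv, results/design_pure.csv\n")
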