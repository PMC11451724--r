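#!/usr/bin/env Rscript
# Generate the working dataset: one draw from the two-lab factorial design
# (2 labs x 4 cohorts x 4 genotypes x 2 sexes x 2 diets, 125 flies/cell =
# 16,000 flies), Gompertz mortality, conditioned cohort frailty, 2%
# food-quality censoring. Writes results/event_table.csv.

library(drstoch)

seed <- 1L
params <- sim_params(seed = seed)
print(params)

records <- simulate_lifespans(params)
dir.create("results", showWarnings = FALSE)
write_event_table(records, "results/event_table.csv")

cat(sprintf("\nWrote %d records (%d censored, %.1f%%) to results/event_table.csv\n",
            nrow(records), sum(records$event == 0),
            100 * mean(records$event == 0)))
rc <- attr(records, "realized_components")
cat("Realized log-hazard variance shares of the generating design:\n")
print(round(rc / sum(rc), 4))
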