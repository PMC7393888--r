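#!/usr/bin/env Rscript
# Stage 1 — generate the study dataset.
#
# The five ingroup plastomes of the study clade are not re-sequenced here;
# instead a 20 kb plastome-like genome is generated and evolved along the
# fixed dated topology (crown ages 108.8 / 18.7 / 7.6 / 6.2 My) under the
# calibrated substitution and structural-mutation processes, emitting the
# true alignment, the reference annotation, the dated tree and a complete
# event log. Everything downstream consumes these four files.

library(plastmut)

seed <- 1L
sim <- simulate_plastomes(sim_config(), seed = seed)
paths <- write_simulation(sim, "results/fixture")

message(sprintf("simulated %d-column alignment of %d taxa (seed %d)",
                sim$aln$length, length(sim$aln$taxa), seed))
message(sprintf("truth log: %d events (%s)", nrow(sim$truth),
                paste(sprintf("%s=%d", names(table(sim$truth$kind)),
                              table(sim$truth$kind)), collapse = ", ")))
message("wrote ", paste(unlist(paths), collapse = ", "))
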