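#!/usr/bin/env Rscript
# Stage 2 — call and classify every mutation.
#
# Runs the full pipeline on the stage-1 fixture: stem-loop inversions are
# detected first (their loop columns are masked from the SNP census),
# polymorphic sites are mapped to branches by parsimony and polarized
# against the hierarchical outgroups, gap runs become classified
# indel/repeat/microsatellite events, and the report bundle is written.

library(plastmut)

res <- run_all(alignment = "results/fixture/alignment.fasta",
               annotation = "results/fixture/ref.gff3",
               tree = "results/fixture/tree.nwk",
               out_dir = "results/reports",
               reference = "Calycanthus_floridus")

snps <- res$snps
message(sprintf("%d polymorphic sites: %d biallelic, %d triallelic+, %d parallel",
                nrow(snps), sum(snps$allelism == 2), sum(snps$allelism > 2),
                sum(snps$parallel)))
message(sprintf("direction inferred for %d sites (%.1f%%)",
                sum(snps$direction_known),
                100 * mean(snps$direction_known)))
message(sprintf("structural events: %s",
                paste(sprintf("%s=%d", names(table(res$events$category)),
                              table(res$events$category)), collapse = ", ")))
dt <- res$structural$direction_tests
message(sprintf("indel deletions:insertions = %d:%d (exact p = %.2g)",
                dt$deletions[dt$category == "indel"],
                dt$insertions[dt$category == "indel"],
                dt$p_value[dt$category == "indel"]))
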