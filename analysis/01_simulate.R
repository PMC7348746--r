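#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a toy two-chromosome genome with 500
# genes, condition-level peak sets for the three marks across the 2x2
# age-by-group design (with planted bivalent promoters and transitions),
# differential-enrichment and expression tables with planted concordance
# classes, motif tables with planted persistence, and the truth manifests.
suppressMessages(library(chipintegrate))

seed <- 1
out <- "results/synthetic"
unlink(out, recursive = TRUE)

bundle <- simulate_bundle(out, seed = seed)

man <- bundle$peaks$manifest
cat("Wrote", length(bundle$paths), "files to", out, "\n")
cat("Genes:", nrow(bundle$annotation$genes),
    "| poised somewhere:", sum(man$state_code != "0000"),
    "| active never-poised:", sum(man$active), "\n")
print(table(man$state_code))
cat("Planted regulation classes:\n")
print(table(bundle$regulation$manifest$class))
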