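#!/usr/bin/env Rscript
# Classify motif-enrichment gains and losses in IUGR per mark and age and
# detect motifs whose change persists from 2 to 10 weeks; run both on the
# synthetic tables and on the bundled islet motif table.
suppressMessages({
  library(chipintegrate)
  library(dplyr)
})

src <- "results/synthetic"
marks <- c("H3K4me3", "H3K27me3")

motifs <- bind_rows(lapply(design_ages(), function(age) {
  bind_rows(lapply(design_groups(), function(grp) {
    bind_rows(lapply(marks, function(mk) {
      read_motif_table(
        file.path(src, paste0("motifs_", mk, "_", age, "_", grp, ".tsv")),
        mk, age, grp
      )
    }))
  }))
}))

calls2 <- classify_motif_change(motifs[motifs$age == "2wk", ])
calls10 <- classify_motif_change(motifs[motifs$age == "10wk", ])
persistent <- bind_rows(lapply(marks, function(mk) {
  persistent_motifs(calls2, calls10, mk)
}))

write_results(
  list(motif_changes = bind_rows(calls2, calls10),
       persistent_motifs = persistent),
  "results/motifs", params = list(sig_alpha = 1e-4, ns_floor = 0.05),
  seed = 1, force = TRUE
)

cat("Synthetic persistent motifs per mark:\n")
print(table(persistent$mark, persistent$change))

recs <- motif_table_to_records(islet_persistent_motifs())
i2 <- classify_motif_change(recs[recs$age == "2wk", ])
i10 <- classify_motif_change(recs[recs$age == "10wk", ])
cat("Bundled islet table, persistent H3K4me3 motifs:\n")
print(persistent_motifs(i2, i10, "H3K4me3")$motif_name)
cat("Bundled islet table, persistent H3K27me3 motifs:\n")
print(persistent_motifs(i2, i10, "H3K27me3")$motif_name)
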