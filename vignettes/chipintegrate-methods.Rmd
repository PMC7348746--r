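---
title: "Methods: integrating histone-mark ChIP-seq with expression in a 2x2 design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating histone-mark ChIP-seq with expression in a 2x2 design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipintegrate)
```

## The analysis problem

Intrauterine growth restriction (IUGR) leaves persistent epigenetic traces
on pancreatic islets. A typical study design assays three histone marks —
H3K4me3 and H3K27Ac (activating) and H3K27me3 (repressive) — by ChIP-seq in
control and IUGR animals at two ages (2 and 10 weeks), alongside gene-level
RNA-seq. Upstream tools produce per-condition peak calls, window-based
differential-enrichment tables and differential-expression tables;
`chipintegrate` implements everything downstream of those calls:

1. a genomic-region taxonomy and nearest-TSS annotation of peaks and sites;
2. assignment of differential sites to genes within 5 kb of a TSS and
   classification of mark-vs-expression **sign concordance**;
3. **bivalent (poised) promoter** calling from overlapping H3K4me3 and
   H3K27me3 peaks, and classification of poised-state transitions across
   the four conditions;
4. **motif-enrichment persistence** calls from IUGR-vs-control enrichment
   p-values at the two ages;
5. input-normalised TSS metaprofiles; and
6. a synthetic-data generator with a ground-truth manifest that carries the
   statistical structure the analysis assumes, so every stage can be tested
   by exact recovery.

The package never computes peak calls or differential statistics itself —
those are consumed as inputs in their standard formats (BED/narrowPeak,
diffReps-like and HOMER-knownResults-like TSVs, refFlat/GTF annotations).

## Coordinate conventions and the region taxonomy

All coordinates are 0-based, half-open (the BED convention); the refFlat
reader keeps them as stored and the GTF reader converts on input. The TSS
is the strand-aware 5' end of the gene body (`start` for `+` genes,
`end - 1` for `-` genes).

Each genomic point receives exactly one category. Windows are strand
oriented around the TSS: **TSS** spans 100 bp upstream to 1 kb downstream,
**Promoter-TSS** spans 1 kb upstream to 100 bp downstream. Inside a gene
body, exonic sequence 5' of the CDS is **5'UTR**, 3' of the CDS **3'UTR**,
remaining exonic sequence **Exon**, intragenic non-exonic sequence
**Intron**, and the body of a gene without a CDS is **NonCoding**.
Everything else is **Intergenic**. Two tie-break rules make the
classification a partition:

* when several genes could claim a point, the gene with the nearest TSS
  wins, exact ties going to the lexicographically smallest gene id;
* within a gene the fixed precedence
  PromoterTSS > TSS > UTR5 > UTR3 > Exon > Intron > NonCoding applies, so
  a point in the 200 bp where the two TSS-proximal windows overlap is
  Promoter-TSS.

Peaks are classified by their midpoint (`floor((start + end) / 2)`); how a
peak spanning category boundaries should be attributed is not otherwise
well defined, and the midpoint matches common annotator behaviour. Signed
TSS distances are reported in gene orientation (positive downstream);
"within 5 kb" always means `|d| <= 5000`. Distance summaries use the bands
<=1 kb, 1–5 kb and >5 kb. Distances are measured to TSSs by default;
`distance_to_nearest_tss(..., to = "gene_body")` measures the gap to gene
bodies instead, for describing how distal marks sit relative to genes.

## Concordance of mark and expression changes

Differential sites are filtered to FDR <= 0.05 (a configurable default;
window-based callers report an adjusted p-value per site) and assigned to
every gene whose TSS lies within 5 kb of the site midpoint. Per gene, mark
and age a single site is kept — nearest TSS first, then larger `|log2FC|`,
then smaller start — because the downstream contract is one fold-change
per gene and mark.

For genes with a significant expression change (RNA FDR <= 0.05), each
mark is scored:

* H3K4me3, H3K27Ac: concordant iff `sign(mark log2FC) == sign(RNA log2FC)`;
* H3K27me3: concordant iff the signs are opposite;
* a zero fold-change on either side cannot correlate and is discordant.

`count_regulated_genes()` tabulates per-mark totals with up/down splits and
an `all_3_marks` row (genes concordant for every mark).
`persistent_mark_genes()` intersects the two ages, requiring the same
concordant mark and expression direction at both — the operation behind
"persistently reduced H3K27Ac at persistently down-regulated genes".

## Bivalent promoters and transitions

A promoter is called poised in a condition when an H3K4me3 peak and an
H3K27me3 peak overlap by at least `min_overlap = 5` bp and the midpoint of
their overlap lies within `promoter_window` of the gene's TSS. The 5 bp
floor is the operational definition of bivalency adopted here; the
promoter window defaults to ±5 kb, the same TSS window the integration
step uses, and both are configurable. Peaks are condition-level (replicate
merging happens upstream); mixed-condition inputs are rejected.

The four per-condition boolean calls per gene form a state vector ordered
(2wk control, 2wk IUGR, 10wk control, 10wk IUGR). `classify_transition()`
is a pure function of the 16 possible vectors with named aliases for the
biologically salient patterns — `stable_poised` (1111), `never_poised`
(0000), `gained_in_IUGR_2wk` (01··), `lost_in_IUGR_2wk` (10··),
`control_resolved_IUGR_repoised` (1101) and
`control_de_novo_IUGR_resolved` (0010) — and the raw 4-bit code for the
rest. The exhaustive 16-state behaviour is pinned by a lookup-table test.
All four cells are kept independent; no agreement between the two 2-wk
groups is assumed.

Because a poised promoter should be transcriptionally quiet,
`filter_poised_by_expression()` flags each call by whether the gene's mean
abundance in that condition's group is below `max_abundance` (default 1.0
on the abundance scale of the expression table, i.e. essentially silent on
a CPM-like scale). Inconsistent calls are retained and flagged rather than
removed — lowly-but-detectably expressed bivalent genes are biologically
real; the flag supports filtering, not a hard rule. No peak q-value
threshold beyond the upstream caller's own cutoff is applied.

## Motif persistence

For each motif, mark and age, the IUGR and control enrichment p-values are
compared with two thresholds: significance `sig_alpha = 1e-4` and a
non-significance floor `ns_floor = 0.05`. A motif is `gained_in_IUGR` when
it clears `sig_alpha` in IUGR while staying above `ns_floor` in control;
`lost_in_IUGR` is the mirror; both significant is `both_enriched`;
anything else `neither`. Requiring `sig_alpha < ns_floor` makes the
classes disjoint, and the call is monotone in each p-value. Typical
published tables separate the two sides by dozens of orders of magnitude
(enriched p-values of 1e-6 and below against control p-values of 0.1 or
1), so any thresholds in that range give the same calls; the defaults sit
comfortably inside it. A motif *persists* when it carries the same
directional change at both ages. `both_enriched` is deliberately treated
as neutral for persistence: it reports enrichment in both groups, not a
group difference. Motif names are matched case-insensitively; consensus
strings (IUPAC alphabet) are carried through verbatim.

## TSS metaprofiles

Browser-style tracks are modelled as fixed-bin coverage vectors with a
library depth. `normalize_log2_ratio()` computes
`log2(((s_i/S) + p) / ((c_i/C) + p))` per bin with pseudocount
`p = 1e-6`, which is finite everywhere and exactly zero when sample and
input agree. `tss_metaprofile()` averages such a track over ±5 kb windows
(100 bp bins by default) centred on every TSS, flipping minus-strand genes
so positive offsets always point downstream; the result is invariant to
gene order and to mirror-flipping the genome.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture: it emulates the
*structure* of the study inputs with a per-gene truth manifest so every
pipeline stage can be checked by exact recovery.

* **Genome**: 2 chromosomes x 500 genes by default (runs in seconds),
  gene bodies 2–10 kb with 12–20 kb gaps. The minimum gap keeps every TSS
  more than 5 kb from any neighbouring gene, so each planted signal maps
  to exactly one gene and recovery tests are unambiguous. 80% of genes are
  coding; both strands are always represented.
* **Peaks**: each gene draws a 4-condition bivalency state vector. The
  default fractions place 10% of genes as stably poised — echoing a study
  scale where bivalent promoters number in the low thousands over ~20k
  genes — and roughly 1% in each altered-transition class, so every named
  transition label occurs at the default scale. Poised gene-conditions get
  an H3K4me3/H3K27me3 pair overlapping by 50 bp (the 5 bp floor plus a
  45 bp margin) centred on the TSS; poised-elsewhere conditions keep only
  H3K4me3; half of never-poised genes are "active" with H3K4me3 + H3K27Ac
  promoter peaks; background H3K27me3 peaks sit mid-gap between genes.
  `jitter_sd` adds Gaussian noise to every peak boundary, eroding overlaps
  so recall degrades smoothly; the suite checks monotone degradation in
  expectation over 20 seeds.
* **Differential sites and expression**: genes draw regulation classes
  (all-3-concordant up/down at 1% each, partial and discordant classes,
  the rest null). Planted sites fall within 4 kb of the TSS with FDRs
  below 0.05 and fold-change magnitudes of 0.5–2 (typical log2 effect
  sizes for such designs); nulls get no site or a non-significant one.
  FDRs are planted, never computed — the pipeline consumes differential
  statistics, it does not produce them. Genes poised anywhere are given
  mean abundances below 1 so the poised-expression filter is exercised.
* **Motifs**: planted persistence classes generate p-values on the two
  sides of the thresholds (enriched: 1e-6 to 1e-60; not enriched: 0.1
  or 1), mirroring the separation seen in real enrichment tables.

One master seed drives a named pseudorandom stream per artifact type, so
enlarging the gene set does not reshuffle the motif tables, and
`simulate_bundle()` writes byte-identical bundles for identical seeds.

What the generator does **not** emulate: read-level noise, fragment-size
effects, replicate variability, peak-caller boundary uncertainty beyond
the Gaussian jitter, correlated marks at shared enhancers, or realistic
genome composition. Passing recovery tests therefore demonstrates the
correctness of the downstream logic under its stated assumptions, not
performance on real ChIP-seq data.

## Numerical and degenerate-input choices

* Printed scientific notation in p-value columns ("1.00 × 10^−43^",
  Unicode minus, caret superscripts) is normalised to plain floats on
  read; unparseable rows are dropped with a logged count, never silently.
* Ties are broken deterministically everywhere (lexicographic gene ids,
  larger `|log2FC|`, smaller start coordinate), so outputs are
  byte-reproducible and `write_results()` emits sorted tables plus a
  run-metadata file.
* Empty inputs: empty peak files parse to empty tables with a log message;
  an empty result set writes a header-only TSV; `summarize_distance_bins`
  on zero points and metaprofiles with no covered TSS are errors.
* A chromosome absent from the annotation is an error (it signals a
  peak/annotation mismatch), while a chromosome bearing no genes returns
  the "no gene" sentinel with infinite distance.

## Scale of the shipped analyses

The numbered scripts under `analysis/` run the whole pipeline on a
generated bundle at the default 500-gene scale and write their tables
under `results/`; the test suite uses 40–500 gene genomes. These sizes
were chosen so each script and the full suite complete in seconds to a
couple of minutes while still exercising every planted class at least
three times.

## Known limitations

* The region taxonomy classifies points, not intervals; a broad domain is
  represented only by its midpoint.
* Bivalency uses a single qualifying peak pair per gene (the largest
  overlap); breadth or multi-peak structure of H3K27me3 domains is out of
  scope.
* The transition classifier is defined only on the fixed 2x2 design;
  other designs are rejected at read time.
* Expression-consistency of poised calls depends on the abundance scale
  of the supplied table; the 1.0 default assumes a CPM-like scale and
  should be adjusted for other units.
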