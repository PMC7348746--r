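# Hand-built two-gene annotation used across interval tests:
#   gA: + strand, chr1 [10000, 16000), coding (CDS [11500, 14500)),
#       exons [10000,11000) [12000,13000) [14000,16000); TSS = 10000
#   gB: - strand, chr1 [30000, 36000), coding (CDS [31500, 34500)),
#       exons [30000,31000) [32000,33000) [34000,36000); TSS = 35999
#   gN: + strand, chr2 [5000, 8000), non-coding single exon; TSS = 5000
tiny_annotation <- function() {
  genome_annotation(
    tibble::tibble(
      gene_id = c("gA", "gB", "gN"),
      chrom = c("chr1", "chr1", "chr2"),
      start = c(10000, 30000, 5000),
      end = c(16000, 36000, 8000),
      strand = c("+", "-", "+"),
      cds_start = c(11500, 31500, NA),
      cds_end = c(14500, 34500, NA),
      exon_starts = list(c(10000, 12000, 14000), c(30000, 32000, 34000),
                         5000),
      exon_ends = list(c(11000, 13000, 16000), c(31000, 33000, 36000),
                       8000)
    ),
    c(chr1 = 2e6, chr2 = 1e6)
  )
}

# Minimal peak tibble builder for one condition.
make_peaks <- function(chrom, start, end, mark, age = "2wk",
                       group = "control") {
  tibble::tibble(
    chrom = chrom, start = start, end = end, mark = mark,
    age = age, group = group,
    score = NA_real_, qvalue = NA_real_, qvalue_scale = NA_character_
  )
}

# Independent brute-force region classifier: plain loops over every gene,
# no shared code with assign_region_category.
brute_region_category <- function(chrom, pos, annotation) {
  genes <- annotation$genes
  best_cat <- "Intergenic"
  best_d <- Inf
  best_id <- ""
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != chrom) next
    d <- if (g$strand == "+") pos - g$tss else g$tss - pos
    cat <- NA
    if (d >= -1000 && d < 100) {
      cat <- "PromoterTSS"
    } else if (d >= -100 && d < 1000) {
      cat <- "TSS"
    } else if (pos >= g$start && pos < g$end) {
      if (is.na(g$cds_start)) {
        cat <- "NonCoding"
      } else {
        es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
        inexon <- FALSE
        for (k in seq_along(es)) if (pos >= es[k] && pos < ee[k]) inexon <- TRUE
        if (!inexon) {
          cat <- "Intron"
        } else if (g$strand == "+") {
          cat <- if (pos < g$cds_start) "UTR5"
                 else if (pos >= g$cds_end) "UTR3" else "Exon"
        } else {
          cat <- if (pos >= g$cds_end) "UTR5"
                 else if (pos < g$cds_start) "UTR3" else "Exon"
        }
      }
    }
    if (!is.na(cat)) {
      ad <- abs(pos - g$tss)
      if (ad < best_d || (ad == best_d && g$gene_id < best_id)) {
        best_d <- ad; best_cat <- cat; best_id <- g$gene_id
      }
    }
  }
  best_cat
}

# Brute-force per-condition bivalency: every (k4, k27) pair, every gene.
brute_bivalent_genes <- function(k4, k27, annotation, min_overlap = 5,
                                 promoter_window = 5000) {
  genes <- annotation$genes
  hit <- character(0)
  for (i in seq_len(nrow(k4))) {
    for (j in seq_len(nrow(k27))) {
      if (k4$chrom[i] != k27$chrom[j]) next
      ov <- min(k4$end[i], k27$end[j]) - max(k4$start[i], k27$start[j])
      if (ov < min_overlap) next
      mid <- floor((max(k4$start[i], k27$start[j]) +
                      min(k4$end[i], k27$end[j])) / 2)
      for (gi in seq_len(nrow(genes))) {
        if (genes$chrom[gi] == k4$chrom[i] &&
            abs(mid - genes$tss[gi]) <= promoter_window) {
          hit <- c(hit, genes$gene_id[gi])
        }
      }
    }
  }
  sort(unique(hit))
}

# Run the four per-condition bivalency calls on a generated peak set.
call_all_conditions <- function(peaks, annotation, ...) {
  out <- lapply(design_conditions(), function(cond) {
    parts <- strsplit(cond, "_", fixed = TRUE)[[1]]
    sel <- peaks$age == parts[1] & peaks$group == parts[2]
    call_bivalent_promoters(peaks[sel & peaks$mark == "H3K4me3", ],
                            peaks[sel & peaks$mark == "H3K27me3", ],
                            annotation, ...)
  })
  dplyr::bind_rows(out)
}
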