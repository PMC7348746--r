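#' Overlap length of two genomic intervals
#'
#' Length in bp of the intersection of two 0-based half-open intervals.
#' Intervals on different chromosomes, adjacent intervals and disjoint
#' intervals all return 0. Vectorised; arguments are recycled.
#'
#' @param chrom_a,start_a,end_a First interval(s).
#' @param chrom_b,start_b,end_b Second interval(s).
#' @return Integer vector of overlap lengths (>= 0).
#' @examples
#' overlap_length("chr1", 0, 10, "chr1", 5, 20)  # 5
#' overlap_length("chr1", 0, 10, "chr1", 10, 20) # 0 (adjacent)
#' @export
overlap_length <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  ov <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  ov[rep_len(chrom_a, length(ov)) != rep_len(chrom_b, length(ov))] <- 0
  as.integer(ov)
}

region_categories <- function() {
  c("PromoterTSS", "TSS", "UTR5", "UTR3", "Exon", "Intron", "NonCoding",
    "Intergenic")
}

# Category of `pos` relative to one gene model, or NA if the point touches
# none of the gene's features. Windows are in gene orientation: promoter =
# [-1000, +100) around the TSS, TSS = [-100, +1000); the promoter window wins
# where they overlap. Within the gene body, coding genes split exonic
# sequence into 5'UTR / 3'UTR / Exon around the CDS and non-exonic sequence
# is Intron; a gene without a CDS is NonCoding throughout its body.
category_for_gene <- function(pos, gene,
                              promoter_up = 1000, promoter_down = 100,
                              tss_up = 100, tss_down = 1000) {
  d <- if (gene$strand == "+") pos - gene$tss else gene$tss - pos
  if (d >= -promoter_up && d < promoter_down) return("PromoterTSS")
  if (d >= -tss_up && d < tss_down) return("TSS")
  if (pos < gene$start || pos >= gene$end) return(NA_character_)
  if (is.na(gene$cds_start)) return("NonCoding")
  es <- gene$exon_starts[[1]]
  ee <- gene$exon_ends[[1]]
  exonic <- any(pos >= es & pos < ee)
  if (!exonic) return("Intron")
  if (gene$strand == "+") {
    if (pos < gene$cds_start) return("UTR5")
    if (pos >= gene$cds_end) return("UTR3")
  } else {
    if (pos >= gene$cds_end) return("UTR5")
    if (pos < gene$cds_start) return("UTR3")
  }
  "Exon"
}

#' Classify genomic points into the region taxonomy
#'
#' Assigns each point exactly one of the categories PromoterTSS, TSS, 5'UTR,
#' 3'UTR, Exon, Intron, NonCoding or Intergenic. Windows are strand-aware:
#' TSS is 100 bp upstream to 1 kb downstream of the transcription start
#' site and Promoter-TSS is 1 kb upstream to 100 bp downstream. When several
#' genes could claim a point, the gene whose TSS is nearest wins (ties by
#' lexicographically smallest `gene_id`); within a gene the fixed precedence
#' PromoterTSS > TSS > UTR5 > UTR3 > Exon > Intron > NonCoding applies.
#' Points touching no gene feature are Intergenic.
#'
#' @param chrom,pos Point coordinates (vectors, recycled to equal length);
#'   `pos` is 0-based.
#' @param annotation A [genome_annotation()].
#' @return A tibble with columns `chrom`, `pos`, `category` (factor over the
#'   taxonomy), `gene_id` (`NA` for Intergenic).
#' @export
assign_region_category <- function(chrom, pos, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  unknown <- setdiff(unique(chrom), names(annotation$chrom_sizes))
  if (length(unknown) > 0) {
    stop("points on chromosome(s) absent from the annotation: ",
         paste(unknown, collapse = ", "),
         " - peak files and annotation disagree", call. = FALSE)
  }
  genes <- annotation$genes
  # candidate span per gene: gene body plus the widest TSS-centred window
  cand <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(
      start = pmax(0, pmin(genes$start, genes$tss - 1000)) + 1L,
      end = pmax(genes$end, genes$tss + 1000)
    )
  )
  pts <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(pts, cand, ignore.strand = TRUE)
  category <- rep("Intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (length(hits) > 0) {
    pi <- S4Vectors::queryHits(hits)
    gi <- S4Vectors::subjectHits(hits)
    cat_pair <- character(length(pi))
    for (k in seq_along(pi)) {
      cat_pair[k] <- category_for_gene(pos[pi[k]], genes[gi[k], ])
    }
    keep <- !is.na(cat_pair)
    if (any(keep)) {
      pairs <- tibble::tibble(
        point = pi[keep],
        gene_id = genes$gene_id[gi[keep]],
        category = cat_pair[keep],
        abs_d = abs(pos[pi[keep]] - genes$tss[gi[keep]])
      )
      best <- pairs |>
        dplyr::arrange(.data$point, .data$abs_d, .data$gene_id) |>
        dplyr::distinct(.data$point, .keep_all = TRUE)
      category[best$point] <- best$category
      gene_id[best$point] <- best$gene_id
    }
  }
  tibble::tibble(
    chrom = chrom, pos = pos,
    category = factor(category, levels = region_categories()),
    gene_id = gene_id
  )
}

#' Signed distance from points to the nearest transcription start site
#'
#' Distance is measured in gene orientation: positive values lie downstream
#' of the TSS (inside or past the gene), negative values upstream. The
#' nearest gene is chosen by absolute distance over all TSS on the point's
#' chromosome; exact ties go to the lexicographically smallest `gene_id`.
#'
#' @inheritParams assign_region_category
#' @param to `"tss"` (default) measures to transcription start sites;
#'   `"gene_body"` measures the unsigned gap to the nearest gene body
#'   (0 for points inside a gene).
#' @return A tibble with columns `chrom`, `pos`, `gene_id`, `distance`.
#'   Points on chromosomes bearing no genes get `gene_id = NA` and infinite
#'   distance.
#' @export
distance_to_nearest_tss <- function(chrom, pos, annotation,
                                    to = c("tss", "gene_body")) {
  stopifnot(inherits(annotation, "genome_annotation"))
  to <- match.arg(to)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  genes <- annotation$genes
  out_gene <- rep(NA_character_, n)
  out_dist <- rep(Inf, n)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    g <- genes[genes$chrom == cc, ]
    if (nrow(g) == 0) next
    for (i in idx) {
      p <- pos[i]
      if (to == "tss") {
        ad <- abs(p - g$tss)
      } else {
        ad <- pmax(0, pmax(g$start - p, p - (g$end - 1)))
      }
      dmin <- min(ad)
      ties <- which(ad == dmin)
      j <- ties[order(g$gene_id[ties])][1]
      out_gene[i] <- g$gene_id[j]
      if (to == "tss") {
        out_dist[i] <- if (g$strand[j] == "+") p - g$tss[j] else g$tss[j] - p
      } else {
        out_dist[i] <- dmin
      }
    }
  }
  tibble::tibble(chrom = chrom, pos = pos, gene_id = out_gene,
                 distance = out_dist)
}

#' Summarise TSS-distance of points into distance bins
#'
#' Bins points by absolute distance to the nearest TSS into <=1 kb, 1-5 kb
#' and >5 kb, the bands used to describe how histone-mark loci distribute
#' around genes.
#'
#' @inheritParams assign_region_category
#' @param to Passed to [distance_to_nearest_tss()].
#' @return A tibble with columns `bin`, `n`, `fraction`; fractions sum to 1.
#' @export
summarize_distance_bins <- function(chrom, pos, annotation,
                                    to = c("tss", "gene_body")) {
  if (length(pos) == 0 || length(chrom) == 0) {
    stop("no points supplied", call. = FALSE)
  }
  d <- distance_to_nearest_tss(chrom, pos, annotation, to = to)
  ad <- abs(d$distance)
  bins <- cut(ad, breaks = c(-Inf, 1000, 5000, Inf),
              labels = c("<=1kb", "1-5kb", ">5kb"))
  tab <- table(bins)
  tibble::tibble(
    bin = names(tab),
    n = as.integer(tab),
    fraction = as.integer(tab) / length(ad)
  )
}
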