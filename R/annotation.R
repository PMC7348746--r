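#' Construct a genome annotation
#'
#' A `genome_annotation` holds gene models and chromosome sizes and backs all
#' region classification, nearest-TSS and metaprofile queries. Coordinates
#' are 0-based half-open (BED convention) throughout the package; readers for
#' 1-based formats convert on input.
#'
#' @param genes A data frame with one row per gene and columns `gene_id`
#'   (unique, non-empty), `chrom`, `start`, `end` (0-based half-open),
#'   `strand` (`"+"` or `"-"`), optional `cds_start`/`cds_end` (genomic
#'   coordinates, `NA` for non-coding genes) and optional list columns
#'   `exon_starts`/`exon_ends` (sorted, non-overlapping, within the gene
#'   body). When exon columns are absent each gene becomes a single exon
#'   spanning its body.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return A `genome_annotation` object: a list with tibble `genes` (with
#'   derived `tss` and `tes` point coordinates) and `chrom_sizes`.
#' @examples
#' ann <- genome_annotation(
#'   data.frame(gene_id = "g1", chrom = "chr1", start = 1000, end = 5000,
#'              strand = "+"),
#'   c(chr1 = 10000)
#' )
#' ann$genes$tss
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  genes <- tibble::as_tibble(genes)
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    stop("annotation genes lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("gene_ids must be unique", call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  if (any(genes$start < 0) || any(genes$end <= genes$start)) {
    stop("gene intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector", call. = FALSE)
  }
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    stop("genes on chromosomes absent from chrom_sizes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(genes$end > chrom_sizes[genes$chrom])) {
    stop("gene interval extends beyond its chromosome", call. = FALSE)
  }
  if (!"cds_start" %in% names(genes)) genes$cds_start <- NA_real_
  if (!"cds_end" %in% names(genes)) genes$cds_end <- NA_real_
  if (!"exon_starts" %in% names(genes)) {
    genes$exon_starts <- as.list(genes$start)
    genes$exon_ends <- as.list(genes$end)
  }
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]
    ee <- genes$exon_ends[[i]]
    if (length(es) != length(ee) || length(es) == 0) {
      stop("gene ", genes$gene_id[i], ": malformed exon lists", call. = FALSE)
    }
    if (any(ee <= es) || is.unsorted(es, strictly = TRUE) ||
        any(utils::head(ee, -1) > utils::tail(es, -1))) {
      stop("gene ", genes$gene_id[i],
           ": exons must be sorted, non-overlapping intervals", call. = FALSE)
    }
    if (es[1] < genes$start[i] || ee[length(ee)] > genes$end[i]) {
      stop("gene ", genes$gene_id[i], ": exons outside gene body",
           call. = FALSE)
    }
    cs <- genes$cds_start[i]
    if (!is.na(cs) && (cs < genes$start[i] || genes$cds_end[i] > genes$end[i] ||
                       genes$cds_end[i] <= cs)) {
      stop("gene ", genes$gene_id[i], ": CDS outside gene body", call. = FALSE)
    }
  }
  # strand-aware 5'/3' point coordinates
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  structure(list(genes = genes, chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

is_coding <- function(genes) !is.na(genes$cds_start)

annotation_granges <- function(annotation) {
  g <- annotation$genes
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand,
    gene_id = g$gene_id
  )
}

tss_granges <- function(annotation) {
  g <- annotation$genes
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$tss + 1L, width = 1L),
    strand = g$strand,
    gene_id = g$gene_id
  )
}
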