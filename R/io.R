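#' Parse p-values written in printed scientific notation
#'
#' Accepts plain numbers alongside typeset forms such as
#' `"1.00 × 10^-43^"` (multiplication sign, caret-marked superscripts,
#' Unicode minus). Unparseable entries return `NA`.
#'
#' @param x Character (or numeric) vector.
#' @return Numeric vector.
#' @export
parse_scientific <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x0 <- gsub("−", "-", trimws(as.character(x)))
  v <- suppressWarnings(as.numeric(x0))
  pat <- "^([0-9]*\\.?[0-9]+)\\s*[×xX*]\\s*10\\^?([-+]?[0-9]+)\\^?$"
  idx <- which(is.na(v) & grepl(pat, x0))
  if (length(idx) > 0) {
    mant <- as.numeric(sub(pat, "\\1", x0[idx]))
    expo <- as.numeric(sub(pat, "\\2", x0[idx]))
    v[idx] <- mant * 10^expo
  }
  v
}

read_table_checked <- function(path, required, aliases = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  nm <- names(tab)
  for (canon in names(aliases)) {
    if (!canon %in% nm) {
      hit <- intersect(aliases[[canon]], nm)
      if (length(hit) > 0) {
        names(tab)[match(hit[1], names(tab))] <- canon
        nm <- names(tab)
      }
    }
  }
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Read a peak file (BED3+ or narrowPeak)
#'
#' Rows are validated as genomic intervals; a malformed row stops with an
#' error naming its line. narrowPeak q-values are `-log10`-scaled and the
#' returned `qvalue_scale` column records that.
#'
#' @param path Path to a tab-separated BED3+ or 10-column narrowPeak file
#'   (no header).
#' @param mark Histone mark label (one of [histone_marks()]).
#' @param age,group Condition labels (see [design_ages()],
#'   [design_groups()]).
#' @return A tibble of peaks: `chrom`, `start`, `end`, `mark`, `age`,
#'   `group`, `score`, `qvalue`, `qvalue_scale`.
#' @export
read_peaks <- function(path, mark, age, group) {
  check_mark(mark); check_age(age); check_group(group)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    message("read_peaks: ", path, " is empty; returning 0 peaks")
    return(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      mark = character(), age = character(), group = character(),
      score = numeric(), qvalue = numeric(), qvalue_scale = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("peak file ", path, ": fewer than 3 columns on line ",
         which(nf < 3)[1], call. = FALSE)
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad) > 0) {
    stop("peak file ", path, ": malformed coordinates on line ", bad[1],
         call. = FALSE)
  }
  narrow <- all(nf >= 10)
  score <- if (all(nf >= 5)) {
    suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 5)))
  } else rep(NA_real_, length(lines))
  qvalue <- if (narrow) {
    suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 9)))
  } else rep(NA_real_, length(lines))
  tibble::tibble(
    chrom = chrom, start = start, end = end,
    mark = mark, age = age, group = group,
    score = score, qvalue = qvalue,
    qvalue_scale = if (narrow) "-log10" else NA_character_
  )
}

#' Write peaks as BED
#'
#' @param peaks A peak tibble (as from [read_peaks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(
    chrom = peaks$chrom,
    start = format(peaks$start, scientific = FALSE, trim = TRUE),
    end = format(peaks$end, scientific = FALSE, trim = TRUE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-enrichment table
#'
#' Consumes window-based differential-caller output (diffReps-style TSV with
#' a header). Column aliases `Chrom/Start/End`, `logFC`, `pval` and `padj`
#' are recognised.
#'
#' @param path Path to the TSV.
#' @param mark,age Labels attached to every row.
#' @param fdr_required If `TRUE` (default) a missing `fdr` column is an
#'   error.
#' @return A tibble of differential sites: `chrom`, `start`, `end`, `mark`,
#'   `age`, `log2FC`, `pvalue`, `fdr`.
#' @export
read_diff_table <- function(path, mark, age, fdr_required = TRUE) {
  check_mark(mark); check_age(age)
  req <- c("chrom", "start", "end", "log2FC", "pvalue")
  if (fdr_required) req <- c(req, "fdr")
  tab <- read_table_checked(
    path, req,
    aliases = list(chrom = c("Chrom", "chr", "Chr"),
                   start = "Start", end = "End",
                   log2FC = c("logFC", "log2FoldChange"),
                   pvalue = c("pval", "p.value", "P-value"),
                   fdr = c("padj", "FDR", "qvalue"))
  )
  n0 <- nrow(tab)
  tab$pvalue <- parse_scientific(tab$pvalue)
  tab$fdr <- if ("fdr" %in% names(tab)) parse_scientific(tab$fdr) else NA_real_
  keep <- !is.na(tab$log2FC) & is.finite(tab$log2FC) &
    !is.na(tab$start) & !is.na(tab$end) & tab$end > tab$start
  if (any(!keep)) {
    message("read_diff_table: dropped ", sum(!keep), " of ", n0,
            " rows with missing or malformed values from ", path)
  }
  tab <- tab[keep, ]
  if (nrow(tab) == 0 && n0 == 0) {
    message("read_diff_table: ", path, " holds a header but no rows")
  }
  tibble::tibble(
    chrom = tab$chrom, start = as.numeric(tab$start),
    end = as.numeric(tab$end), mark = mark, age = age,
    log2FC = as.numeric(tab$log2FC), pvalue = tab$pvalue, fdr = tab$fdr
  )
}

#' Read a gene-level expression table
#'
#' @param path Path to a TSV with header columns `gene`, `log2FC`, `fdr`
#'   (aliases `gene_id`, `logFC`, `FDR`/`padj` accepted) and optional
#'   per-group mean abundances `mean_abundance_control` /
#'   `mean_abundance_IUGR` (aliases `mean_control` / `mean_IUGR`).
#' @param age Age label attached to every row.
#' @return A tibble: `gene_id`, `age`, `log2FC`, `fdr`,
#'   `mean_abundance_control`, `mean_abundance_IUGR`.
#' @export
read_expression <- function(path, age) {
  check_age(age)
  tab <- read_table_checked(
    path, c("gene", "log2FC", "fdr"),
    aliases = list(gene = c("gene_id", "Gene", "Genes"),
                   log2FC = c("logFC", "RNASeqlogFC", "RNAseqlogFC"),
                   fdr = c("FDR", "padj", "RNASeqFDR", "RNAseqFDR"),
                   mean_abundance_control = "mean_control",
                   mean_abundance_IUGR = "mean_IUGR")
  )
  n0 <- nrow(tab)
  tab$fdr <- parse_scientific(tab$fdr)
  tab$log2FC <- parse_scientific(tab$log2FC)
  keep <- !is.na(tab$gene) & !is.na(tab$log2FC) & !is.na(tab$fdr) &
    tab$fdr > 0 & tab$fdr <= 1
  if (any(!keep)) {
    message("read_expression: dropped ", sum(!keep), " of ", n0,
            " rows with missing or out-of-range values from ", path)
  }
  tab <- tab[keep, ]
  if (n0 == 0) message("read_expression: ", path, " holds no data rows")
  getcol <- function(nm) {
    if (nm %in% names(tab)) as.numeric(tab[[nm]]) else rep(NA_real_, nrow(tab))
  }
  tibble::tibble(
    gene_id = tab$gene, age = age,
    log2FC = tab$log2FC, fdr = tab$fdr,
    mean_abundance_control = getcol("mean_abundance_control"),
    mean_abundance_IUGR = getcol("mean_abundance_IUGR")
  )
}

#' Read a motif-enrichment results table
#'
#' Consumes HOMER-knownResults-like TSVs. Printed scientific notation in the
#' p-value column (for example `"1.00 × 10^-17^"`) is normalised to
#' plain floats on read; rows whose p-value cannot be parsed are dropped
#' with a logged count.
#'
#' @param path Path to the TSV with header columns `motif_name`,
#'   `consensus`, `pvalue` (aliases `Motif Name`, `Consensus`, `P-value`).
#' @param mark,age,group Labels attached to every row.
#' @return A tibble: `motif_name`, `consensus`, `mark`, `age`, `group`,
#'   `pvalue`.
#' @export
read_motif_table <- function(path, mark, age, group) {
  check_mark(mark); check_age(age); check_group(group)
  tab <- read_table_checked(
    path, c("motif_name", "consensus", "pvalue"),
    aliases = list(motif_name = c("Motif Name", "Motif", "motif"),
                   consensus = "Consensus",
                   pvalue = c("P-value", "p-value", "p", "pval"))
  )
  n0 <- nrow(tab)
  p <- parse_scientific(tab$pvalue)
  ok_cons <- grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn:]+$", tab$consensus)
  keep <- !is.na(p) & p > 0 & p <= 1 & ok_cons
  if (any(!keep)) {
    message("read_motif_table: dropped ", sum(!keep), " of ", n0,
            " rows with unparseable p-values or consensus from ", path)
  }
  tibble::tibble(
    motif_name = tab$motif_name[keep],
    consensus = tab$consensus[keep],
    mark = mark, age = age, group = group,
    pvalue = p[keep]
  )
}

#' Read chromosome sizes
#'
#' @param path Two-column TSV (chromosome, length), no header.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$size, tab$chrom)
}

#' Read gene models from a refFlat-style table
#'
#' refFlat columns: geneName, name, chrom, strand, txStart, txEnd, cdsStart,
#' cdsEnd, exonCount, exonStarts, exonEnds (0-based half-open, exon lists
#' comma-separated). `cdsStart == cdsEnd` marks a non-coding gene.
#'
#' @param path Path to the refFlat file (no header).
#' @param chrom_sizes Named vector of chromosome lengths, or a path passed
#'   to [read_chrom_sizes()].
#' @return A [genome_annotation()].
#' @export
read_annotation_refflat <- function(path, chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  cols <- c("geneName", "name", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = cols, stringsAsFactors = FALSE)
  split_pos <- function(x) lapply(strsplit(x, ",", fixed = TRUE), as.numeric)
  noncoding <- tab$cdsStart == tab$cdsEnd
  genes <- tibble::tibble(
    gene_id = tab$geneName,
    chrom = tab$chrom,
    start = tab$txStart,
    end = tab$txEnd,
    strand = tab$strand,
    cds_start = ifelse(noncoding, NA_real_, tab$cdsStart),
    cds_end = ifelse(noncoding, NA_real_, tab$cdsEnd),
    exon_starts = split_pos(tab$exonStarts),
    exon_ends = split_pos(tab$exonEnds)
  )
  genome_annotation(genes, chrom_sizes)
}

#' Write gene models as a refFlat-style table
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_refflat <- function(annotation, path) {
  g <- annotation$genes
  join_pos <- function(x) {
    vapply(x, function(v) paste0(paste(format(v, scientific = FALSE,
                                              trim = TRUE),
                                       collapse = ","), ","), character(1))
  }
  df <- data.frame(
    geneName = g$gene_id, name = g$gene_id, chrom = g$chrom,
    strand = g$strand, txStart = g$start, txEnd = g$end,
    cdsStart = ifelse(is.na(g$cds_start), g$start, g$cds_start),
    cdsEnd = ifelse(is.na(g$cds_start), g$start, g$cds_end),
    exonCount = lengths(g$exon_starts),
    exonStarts = join_pos(g$exon_starts),
    exonEnds = join_pos(g$exon_ends)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Requires the rtracklayer package. Exon and CDS features are grouped by
#' their `gene_id` attribute; 1-based GTF coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @inheritParams read_annotation_refflat
#' @return A [genome_annotation()].
#' @export
read_annotation_gtf <- function(path, chrom_sizes) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF requires the rtracklayer package", call. = FALSE)
  }
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) stop("GTF holds no exon features", call. = FALSE)
  cds <- gr[gr$type == "CDS"]
  ex_by <- S4Vectors::split(ex, ex$gene_id)
  cds_range <- if (length(cds) > 0) {
    range(S4Vectors::split(cds, cds$gene_id))
  } else NULL
  ids <- names(ex_by)
  rows <- lapply(ids, function(id) {
    e <- GenomicRanges::reduce(ex_by[[id]])
    e <- GenomicRanges::sort(e, ignore.strand = TRUE)
    cs <- ce <- NA_real_
    if (!is.null(cds_range) && id %in% names(cds_range)) {
      cr <- cds_range[[id]]
      cs <- GenomicRanges::start(cr)[1] - 1
      ce <- GenomicRanges::end(cr)[1]
    }
    tibble::tibble(
      gene_id = id,
      chrom = as.character(GenomicRanges::seqnames(e))[1],
      start = min(GenomicRanges::start(e)) - 1,
      end = max(GenomicRanges::end(e)),
      strand = as.character(GenomicRanges::strand(e))[1],
      cds_start = cs, cds_end = ce,
      exon_starts = list(GenomicRanges::start(e) - 1),
      exon_ends = list(GenomicRanges::end(e))
    )
  })
  genome_annotation(dplyr::bind_rows(rows), chrom_sizes)
}

#' Read a fixed-bin bedGraph into a signal track
#'
#' @param path bedGraph path (chrom, start, end, value; no header). All rows
#'   must sit on one chromosome with `end - start == bin_size` and
#'   bin-aligned starts; uncovered bins are 0.
#' @param bin_size Bin width in bp.
#' @param total_depth Library depth to attach to the track.
#' @param chrom_length Optional chromosome length (default: last covered
#'   bin).
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, bin_size, total_depth, chrom_length = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"))
  if (length(unique(tab$chrom)) != 1) {
    stop("bedGraph must cover exactly one chromosome", call. = FALSE)
  }
  if (any(tab$end - tab$start != bin_size) || any(tab$start %% bin_size != 0)) {
    stop("bedGraph bins do not match bin_size ", bin_size, call. = FALSE)
  }
  len <- if (is.null(chrom_length)) max(tab$end) else chrom_length
  values <- numeric(ceiling(len / bin_size))
  values[tab$start / bin_size + 1] <- tab$value
  signal_track(tab$chrom[1], bin_size, values, total_depth, chrom_length = len)
}

#' Write result tables with a run-metadata file
#'
#' Writes each table as a TSV with a stable column order, rows sorted by
#' their first column (then the second, when present), plus a
#' `run_metadata.tsv` recording parameters and seed so identical inputs and
#' configuration produce byte-identical output.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param params Named list of run parameters recorded in the metadata file.
#' @param seed Seed recorded in the metadata file.
#' @param force Overwrite existing files (default `FALSE`; collisions are an
#'   error otherwise).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(tables, out_dir, params = list(), seed = NA,
                          force = FALSE) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(out_dir, paste0(names(tables), ".tsv"))
  meta_file <- file.path(out_dir, "run_metadata.tsv")
  existing <- c(files, meta_file)[file.exists(c(files, meta_file))]
  if (length(existing) > 0 && !force) {
    stop("output file(s) exist (use force = TRUE): ",
         paste(basename(existing), collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(tables)) {
    tab <- as.data.frame(tables[[i]])
    if (nrow(tab) > 1) {
      ord <- if (ncol(tab) >= 2) order(tab[[1]], tab[[2]]) else order(tab[[1]])
      tab <- tab[ord, , drop = FALSE]
    }
    readr::write_tsv(tab, files[i], progress = FALSE)
  }
  meta <- data.frame(
    key = c("seed", names(params)),
    value = c(as.character(seed),
              vapply(params, function(p) paste(as.character(p),
                                               collapse = ","),
                     character(1)))
  )
  readr::write_tsv(meta, meta_file, progress = FALSE)
  invisible(c(files, meta_file))
}
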