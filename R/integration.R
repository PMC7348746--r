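#' Assign differential histone sites to genes near their TSS
#'
#' Each significant differential site (FDR at or below `fdr_max`) is a
#' candidate for every gene whose TSS lies within `window` bp of the site
#' midpoint. Per gene, mark and age, a single site is kept: the one with the
#' smallest absolute TSS distance, ties broken by larger `|log2FC|`, then by
#' smaller start coordinate.
#'
#' @param diff Tibble of differential sites (see [read_diff_table()]).
#' @param annotation A [genome_annotation()].
#' @param window Maximum absolute TSS distance in bp (default 5000).
#' @param fdr_max Differential-site FDR cutoff (default 0.05); sites with
#'   `NA` FDR are kept only when `fdr_max` is `NA`.
#' @return A tibble of assignments: `gene_id`, `mark`, `age`, `log2FC`,
#'   `fdr`, `distance` (signed bp in gene orientation), `chrom`, `start`,
#'   `end`.
#' @export
assign_diff_sites <- function(diff, annotation, window = 5000,
                              fdr_max = 0.05) {
  stopifnot(inherits(annotation, "genome_annotation"))
  empty <- tibble::tibble(
    gene_id = character(), mark = character(), age = character(),
    log2FC = numeric(), fdr = numeric(), distance = numeric(),
    chrom = character(), start = numeric(), end = numeric()
  )
  if (nrow(diff) == 0) return(empty)
  if (!is.na(fdr_max)) diff <- diff[!is.na(diff$fdr) & diff$fdr <= fdr_max, ]
  if (nrow(diff) == 0) return(empty)
  mid <- floor((diff$start + diff$end) / 2)
  site_gr <- GenomicRanges::GRanges(
    seqnames = diff$chrom,
    ranges = IRanges::IRanges(start = mid + 1L, width = 1L)
  )
  tssg <- tss_granges(annotation)
  win <- GenomicRanges::resize(tssg, width = 2L * window + 1L, fix = "center")
  hits <- GenomicRanges::findOverlaps(site_gr, win, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  genes <- annotation$genes
  d <- ifelse(genes$strand[gi] == "+",
              mid[si] - genes$tss[gi],
              genes$tss[gi] - mid[si])
  cand <- tibble::tibble(
    gene_id = genes$gene_id[gi],
    mark = diff$mark[si], age = diff$age[si],
    log2FC = diff$log2FC[si], fdr = diff$fdr[si],
    distance = d,
    chrom = diff$chrom[si], start = diff$start[si], end = diff$end[si]
  )
  cand <- cand[abs(cand$distance) <= window, ]
  cand |>
    dplyr::arrange(.data$gene_id, .data$mark, .data$age,
                   abs(.data$distance), dplyr::desc(abs(.data$log2FC)),
                   .data$start) |>
    dplyr::distinct(.data$gene_id, .data$mark, .data$age, .keep_all = TRUE)
}

# Sign-concordance rule: activating marks (H3K4me3, H3K27Ac) must move with
# expression; the repressive mark H3K27me3 must move against it. A zero
# log2FC on either side cannot correlate and is discordant.
mark_concordant <- function(mark, mark_lfc, rna_lfc) {
  s <- sign(mark_lfc) * sign(rna_lfc)
  ifelse(mark == "H3K27me3", s == -1, s == 1)
}

#' Classify mark-expression concordance per gene and age
#'
#' Joins TSS-window mark assignments with significantly differentially
#' expressed genes and scores each mark as concordant, discordant or absent.
#' H3K4me3 and H3K27Ac changes are concordant when their log2 fold-change
#' has the same sign as the RNA change; H3K27me3 is concordant when the
#' signs are opposite. Genes without a significant expression change are
#' dropped (with a logged count): concordance is only defined for expressed,
#' differentially regulated genes.
#'
#' @param assignments Output of [assign_diff_sites()] (possibly several ages
#'   bound together).
#' @param expression Expression tibble (see [read_expression()]).
#' @param rna_fdr_max Expression FDR cutoff (default 0.05).
#' @return A tibble with one row per gene and age: `gene_id`, `age`,
#'   `rna_log2FC`, `rna_direction` (`"up"`/`"down"`), per-mark status
#'   columns `H3K4me3`, `H3K27me3`, `H3K27Ac` (each `"concordant"`,
#'   `"discordant"` or `"absent"`) and `n_concordant_marks`.
#' @export
classify_concordance <- function(assignments, expression,
                                 rna_fdr_max = 0.05) {
  expr <- expression[!is.na(expression$fdr) &
                       expression$fdr <= rna_fdr_max, ]
  n_lost <- length(setdiff(
    unique(assignments$gene_id[assignments$age %in% expr$age]),
    expr$gene_id
  ))
  if (n_lost > 0) {
    message("classify_concordance: ", n_lost,
            " assigned gene(s) lack a significant expression change",
            " and were dropped")
  }
  joined <- dplyr::inner_join(
    assignments,
    dplyr::select(expr, "gene_id", "age", rna_log2FC = "log2FC"),
    by = c("gene_id", "age")
  )
  joined$status <- ifelse(
    mark_concordant(joined$mark, joined$log2FC, joined$rna_log2FC),
    "concordant", "discordant"
  )
  wide <- joined |>
    dplyr::select("gene_id", "age", "rna_log2FC", "mark", "status") |>
    tidyr::pivot_wider(names_from = "mark", values_from = "status",
                       values_fill = "absent")
  for (m in histone_marks()) {
    if (!m %in% names(wide)) wide[[m]] <- "absent"
  }
  # expressed genes with no assigned mark still appear downstream as
  # all-absent only if they had at least one assignment; genes without any
  # assignment are out of scope here
  wide$rna_direction <- ifelse(wide$rna_log2FC > 0, "up",
                               ifelse(wide$rna_log2FC < 0, "down", "none"))
  wide$n_concordant_marks <- Reduce(
    `+`, lapply(histone_marks(),
                function(m) as.integer(wide[[m]] == "concordant"))
  )
  dplyr::select(wide, "gene_id", "age", "rna_log2FC", "rna_direction",
                dplyr::all_of(histone_marks()), "n_concordant_marks") |>
    dplyr::arrange(.data$age, .data$gene_id)
}

#' Count genes potentially regulated by histone modifications
#'
#' Per age, totals and up/down splits of genes concordant for each mark,
#' plus an `all_3_marks` row counting genes concordant for every mark.
#'
#' @param calls Output of [classify_concordance()].
#' @return A tibble: `age`, `row` (mark name or `"all_3_marks"`), `total`,
#'   `up`, `down`; `up + down == total` in every row.
#' @export
count_regulated_genes <- function(calls) {
  rows <- c(histone_marks(), "all_3_marks")
  out <- tidyr::expand_grid(age = unique(calls$age), row = rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(age = character(), row = character(),
                          total = integer(), up = integer(),
                          down = integer()))
  }
  count_one <- function(age, row) {
    sub <- calls[calls$age == age, ]
    hit <- if (row == "all_3_marks") {
      sub$n_concordant_marks == 3
    } else {
      sub[[row]] == "concordant"
    }
    c(total = sum(hit),
      up = sum(hit & sub$rna_direction == "up"),
      down = sum(hit & sub$rna_direction == "down"))
  }
  counts <- t(mapply(count_one, out$age, out$row))
  out$total <- as.integer(counts[, "total"])
  out$up <- as.integer(counts[, "up"])
  out$down <- as.integer(counts[, "down"])
  out
}

#' Genes with a persistent concordant mark change at both ages
#'
#' A gene is retained when it is concordant for `mark` with the requested
#' expression direction at both 2 and 10 weeks — e.g. persistently reduced
#' H3K27Ac at persistently down-regulated genes.
#'
#' @param calls_2wk,calls_10wk [classify_concordance()] outputs for the two
#'   ages.
#' @param mark Histone mark to test.
#' @param direction Required RNA direction, `"up"` or `"down"`.
#' @return Sorted character vector of gene ids.
#' @export
persistent_mark_genes <- function(calls_2wk, calls_10wk, mark,
                                  direction = c("down", "up")) {
  check_mark(mark)
  direction <- match.arg(direction)
  pick <- function(calls) {
    calls$gene_id[calls[[mark]] == "concordant" &
                    calls$rna_direction == direction]
  }
  sort(intersect(pick(calls_2wk), pick(calls_10wk)))
}
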