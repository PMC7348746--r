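#' Call bivalent (poised) promoters for one condition
#'
#' A gene is called bivalent when an H3K4me3 peak and an H3K27me3 peak from
#' the same condition overlap by at least `min_overlap` bp and the midpoint
#' of their overlap region lies within `promoter_window` bp of the gene's
#' TSS. Among qualifying peak pairs the one with the largest overlap is
#' recorded (ties by smaller peak start coordinates).
#'
#' @param k4,k27 Peak tibbles (see [read_peaks()]) for H3K4me3 and H3K27me3
#'   respectively, both from a single condition.
#' @param annotation A [genome_annotation()].
#' @param min_overlap Minimum peak overlap in bp (default 5).
#' @param promoter_window Maximum absolute distance from overlap midpoint to
#'   TSS in bp (default 5000).
#' @return A tibble with one row per bivalent gene: `gene_id`, `age`,
#'   `group`, `condition`, `overlap_bp`, `k4_start`, `k4_end`, `k27_start`,
#'   `k27_end`, `tss_distance`.
#' @export
call_bivalent_promoters <- function(k4, k27, annotation, min_overlap = 5,
                                    promoter_window = 5000) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (min_overlap < 1) stop("min_overlap must be >= 1", call. = FALSE)
  conds <- unique(c(condition_label(k4$age, k4$group),
                    condition_label(k27$age, k27$group)))
  if (length(conds) > 1) {
    stop("peaks from mixed conditions: ", paste(conds, collapse = ", "),
         call. = FALSE)
  }
  empty <- tibble::tibble(
    gene_id = character(), age = character(), group = character(),
    condition = character(), overlap_bp = integer(),
    k4_start = numeric(), k4_end = numeric(),
    k27_start = numeric(), k27_end = numeric(), tss_distance = numeric()
  )
  if (nrow(k4) == 0 || nrow(k27) == 0) return(empty)
  gr4 <- GenomicRanges::GRanges(k4$chrom,
                                IRanges::IRanges(k4$start + 1L, k4$end))
  gr27 <- GenomicRanges::GRanges(k27$chrom,
                                 IRanges::IRanges(k27$start + 1L, k27$end))
  hits <- GenomicRanges::findOverlaps(gr4, gr27,
                                      minoverlap = as.integer(min_overlap))
  if (length(hits) == 0) return(empty)
  i4 <- S4Vectors::queryHits(hits)
  i27 <- S4Vectors::subjectHits(hits)
  ov_start <- pmax(k4$start[i4], k27$start[i27])
  ov_end <- pmin(k4$end[i4], k27$end[i27])
  ov_mid <- floor((ov_start + ov_end) / 2)
  # a pair can poise every gene whose TSS falls within the promoter window
  mid_gr <- GenomicRanges::GRanges(
    k4$chrom[i4], IRanges::IRanges(ov_mid + 1L, width = 1L)
  )
  win <- GenomicRanges::resize(tss_granges(annotation),
                               width = 2L * promoter_window + 1L,
                               fix = "center")
  gh <- GenomicRanges::findOverlaps(mid_gr, win, ignore.strand = TRUE)
  if (length(gh) == 0) return(empty)
  pk <- S4Vectors::queryHits(gh)
  gn <- S4Vectors::subjectHits(gh)
  genes <- annotation$genes
  d <- ifelse(genes$strand[gn] == "+",
              ov_mid[pk] - genes$tss[gn],
              genes$tss[gn] - ov_mid[pk])
  keep <- abs(d) <= promoter_window
  if (!any(keep)) return(empty)
  pairs <- tibble::tibble(
    gene_id = genes$gene_id[gn][keep],
    overlap_bp = as.integer(ov_end - ov_start)[pk][keep],
    k4_start = k4$start[i4][pk][keep], k4_end = k4$end[i4][pk][keep],
    k27_start = k27$start[i27][pk][keep], k27_end = k27$end[i27][pk][keep],
    tss_distance = d[keep]
  )
  best <- pairs |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$overlap_bp),
                   .data$k4_start, .data$k27_start) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  tibble::tibble(
    gene_id = best$gene_id,
    age = k4$age[1], group = k4$group[1], condition = conds,
    overlap_bp = best$overlap_bp,
    k4_start = best$k4_start, k4_end = best$k4_end,
    k27_start = best$k27_start, k27_end = best$k27_end,
    tss_distance = best$tss_distance
  )
}

#' Flag poised calls consistent with low expression
#'
#' A bivalent promoter marks a transcriptionally silent but activation-ready
#' gene, so a poised call is consistent with very low expression. The flag
#' is `TRUE` when the gene's mean abundance in the call's group is below
#' `max_abundance`, `FALSE` when it is not, and `NA` (logged) when no
#' abundance is available.
#'
#' @param calls Output of [call_bivalent_promoters()] (any number of
#'   conditions bound together).
#' @param expression Expression tibble with per-group mean abundances (see
#'   [read_expression()]).
#' @param max_abundance Abundance ceiling for a poised-consistent call
#'   (default 1.0 on the expression table's scale).
#' @return `calls` with added columns `mean_abundance` and
#'   `poised_expression_consistent`.
#' @export
filter_poised_by_expression <- function(calls, expression,
                                        max_abundance = 1.0) {
  abundance <- vapply(seq_len(nrow(calls)), function(i) {
    row <- expression[expression$gene_id == calls$gene_id[i] &
                        expression$age == calls$age[i], ]
    if (nrow(row) == 0) return(NA_real_)
    col <- paste0("mean_abundance_", calls$group[i])
    row[[col]][1]
  }, numeric(1))
  n_missing <- sum(is.na(abundance))
  if (n_missing > 0) {
    message("filter_poised_by_expression: ", n_missing,
            " call(s) without abundance; flag set to NA")
  }
  calls$mean_abundance <- abundance
  calls$poised_expression_consistent <- abundance < max_abundance
  calls
}

#' Build the per-gene bivalency state matrix
#'
#' Collects bivalency calls from all four conditions into one logical state
#' vector per gene, ordered (2wk control, 2wk IUGR, 10wk control,
#' 10wk IUGR). Genes bivalent in no condition are omitted; a missing call
#' in a condition is `FALSE`.
#'
#' @param calls Bivalency calls for the four conditions bound into one
#'   tibble (duplicate gene x condition rows are an error).
#' @return A tibble: `gene_id`, `s_2wk_control`, `s_2wk_IUGR`,
#'   `s_10wk_control`, `s_10wk_IUGR`.
#' @export
build_state_matrix <- function(calls) {
  if (nrow(calls) == 0) {
    out <- tibble::tibble(gene_id = character())
    for (cond in design_conditions()) out[[paste0("s_", cond)]] <- logical()
    return(out)
  }
  if (anyDuplicated(calls[, c("gene_id", "condition")])) {
    dup <- calls[duplicated(calls[, c("gene_id", "condition")]), ]
    stop("duplicate bivalency call for gene x condition: ",
         dup$gene_id[1], " / ", dup$condition[1], call. = FALSE)
  }
  genes <- sort(unique(calls$gene_id))
  out <- tibble::tibble(gene_id = genes)
  for (cond in design_conditions()) {
    out[[paste0("s_", cond)]] <-
      genes %in% calls$gene_id[calls$condition == cond]
  }
  out
}

#' Label a 4-condition bivalency state vector
#'
#' Maps the 16 possible poised/not-poised state vectors (ordered 2wk
#' control, 2wk IUGR, 10wk control, 10wk IUGR) to named transition classes:
#' `stable_poised` (1111), `never_poised` (0000),
#' `control_resolved_IUGR_repoised` (1101: poised early in both groups,
#' resolved in adult controls but re-poised in adult IUGR),
#' `control_de_novo_IUGR_resolved` (0010: de novo poised only in adult
#' controls), `gained_in_IUGR_2wk` (01xx) and `lost_in_IUGR_2wk` (10xx).
#' Any remaining vector is returned as its raw 4-bit code (e.g. `"0011"`).
#'
#' @param states A logical vector of length 4, or a 4-column logical matrix
#'   / the output of [build_state_matrix()] for vectorised use.
#' @return Character vector of labels.
#' @export
classify_transition <- function(states) {
  if (is.data.frame(states)) {
    states <- as.matrix(states[, paste0("s_", design_conditions())])
  }
  if (is.vector(states)) states <- matrix(states, nrow = 1)
  stopifnot(ncol(states) == 4)
  code <- apply(states, 1, function(s) paste(as.integer(s), collapse = ""))
  label <- code
  label[code == "1111"] <- "stable_poised"
  label[code == "0000"] <- "never_poised"
  label[code == "1101"] <- "control_resolved_IUGR_repoised"
  label[code == "0010"] <- "control_de_novo_IUGR_resolved"
  named <- label != code
  label[!named & substr(code, 1, 2) == "01"] <- "gained_in_IUGR_2wk"
  label[!named & substr(code, 1, 2) == "10"] <- "lost_in_IUGR_2wk"
  label
}

#' Summarise bivalency transitions
#'
#' @param matrix Output of [build_state_matrix()].
#' @return A list with `label_counts` (tibble `label`, `n`, summing to the
#'   number of genes) and `n_discordant_10wk`, the number of genes whose
#'   10-wk control and 10-wk IUGR states differ.
#' @export
summarize_transitions <- function(matrix) {
  labels <- classify_transition(matrix)
  tab <- table(labels)
  list(
    label_counts = tibble::tibble(label = names(tab), n = as.integer(tab)),
    n_discordant_10wk = sum(matrix$s_10wk_control != matrix$s_10wk_IUGR)
  )
}
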