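example_path <- function(name) {
  system.file("extdata", name, package = "chipintegrate", mustWork = TRUE)
}

#' Bundled islet example tables
#'
#' Small gene-level summary tables from a ChIP-seq/RNA-seq study of
#' pancreatic islets in a rat model of intrauterine growth restriction,
#' bundled as worked examples for the integration, persistence, motif and
#' bivalency classifiers.
#'
#' * `islet_allmarks_genes()`: six 10-wk genes with log2 fold-changes for
#'   all three histone marks plus the RNA change and FDR.
#' * `islet_k27ac_persistent_genes()`: twenty genes with reduced H3K27Ac
#'   and reduced expression at both ages.
#' * `islet_persistent_motifs()`: motif-enrichment p-values per mark, age
#'   and group for the persistently changed binding motifs.
#' * `islet_bivalency_states()`: the poised/not-poised state of six genes
#'   across the four conditions (logical columns in condition order).
#'
#' @return A tibble (see each description).
#' @export
islet_allmarks_genes <- function() {
  readr::read_tsv(example_path("islet_allmarks_genes.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname islet_allmarks_genes
#' @export
islet_k27ac_persistent_genes <- function() {
  readr::read_tsv(example_path("islet_k27ac_persistent_genes.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname islet_allmarks_genes
#' @export
islet_persistent_motifs <- function() {
  readr::read_tsv(example_path("islet_persistent_motifs.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname islet_allmarks_genes
#' @export
islet_bivalency_states <- function() {
  tab <- readr::read_tsv(example_path("islet_bivalency_states.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(gene_id = tab$gene)
  for (cond in design_conditions()) {
    out[[paste0("s_", cond)]] <- tab[[paste0("b_", cond)]] == "+"
  }
  out
}

#' Expand a gene-level mark/expression summary into classifier inputs
#'
#' Converts wide per-gene tables (one log2 fold-change per mark plus an RNA
#' change, as in [islet_allmarks_genes()]) into the mark-assignment and
#' expression tibbles consumed by [classify_concordance()]. Site FDRs and
#' TSS distances are not part of such summaries; assignments get
#' `distance = 0` and `fdr = NA`.
#'
#' @param genes Tibble with columns `gene`, `rna_log2FC`, `rna_fdr` and one
#'   `<mark>_log2FC` column per available mark.
#' @param age Age label for all rows.
#' @return A list with `assignments` and `expression` tibbles.
#' @export
marks_table_to_inputs <- function(genes, age) {
  check_age(age)
  mark_cols <- intersect(paste0(histone_marks(), "_log2FC"), names(genes))
  assignments <- purrr::map_dfr(mark_cols, function(col) {
    mk <- sub("_log2FC$", "", col)
    tibble::tibble(
      gene_id = genes$gene, mark = mk, age = age,
      log2FC = genes[[col]], fdr = NA_real_, distance = 0,
      chrom = NA_character_, start = NA_real_, end = NA_real_
    )
  })
  expression <- tibble::tibble(
    gene_id = genes$gene, age = age,
    log2FC = genes$rna_log2FC, fdr = genes$rna_fdr,
    mean_abundance_control = NA_real_, mean_abundance_IUGR = NA_real_
  )
  list(assignments = assignments, expression = expression)
}

#' Expand the two-age H3K27Ac persistence table into classifier inputs
#'
#' @param genes Tibble shaped like [islet_k27ac_persistent_genes()].
#' @return A named list with per-age `assignments` and `expression`
#'   tibbles (`age2 = "2wk"`, `age10 = "10wk"`).
#' @export
k27ac_table_to_inputs <- function(genes) {
  one_age <- function(age, lfc, fdr, k27ac) {
    marks_table_to_inputs(
      tibble::tibble(gene = genes$gene, rna_log2FC = genes[[lfc]],
                     rna_fdr = genes[[fdr]], H3K27Ac_log2FC = genes[[k27ac]]),
      age
    )
  }
  list(
    age2 = one_age("2wk", "rna_log2FC_2wk", "rna_fdr_2wk",
                   "k27ac_log2FC_2wk"),
    age10 = one_age("10wk", "rna_log2FC_10wk", "rna_fdr_10wk",
                    "k27ac_log2FC_10wk")
  )
}

#' Reshape a wide motif p-value table into per-record motif rows
#'
#' @param motifs Tibble shaped like [islet_persistent_motifs()]: columns
#'   `mark`, `motif_name`, `consensus` and `p_<age>_<group>` p-value
#'   columns.
#' @return A motif-record tibble as produced by [read_motif_table()].
#' @export
motif_table_to_records <- function(motifs) {
  purrr::map_dfr(design_ages(), function(age) {
    purrr::map_dfr(design_groups(), function(grp) {
      p <- motifs[[paste0("p_", age, "_", grp)]]
      tibble::tibble(
        motif_name = motifs$motif_name,
        consensus = motifs$consensus,
        mark = motifs$mark, age = age, group = grp,
        pvalue = p
      )
    })
  })
}
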