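#' Classify a motif's IUGR-vs-control enrichment change
#'
#' Compares a motif's enrichment p-value in IUGR against control peaks of
#' the same mark and age. A motif is `gained_in_IUGR` when it is strongly
#' enriched in IUGR (`p_iugr <= sig_alpha`) while clearly non-significant in
#' control (`p_control >= ns_floor`); `lost_in_IUGR` is the mirror image;
#' `both_enriched` when both p-values clear `sig_alpha`; `neither`
#' otherwise. `sig_alpha` must be below `ns_floor`, so the classes are
#' disjoint.
#'
#' @param motifs Tibble of motif records (see [read_motif_table()]) covering
#'   both groups for at least one mark and age; rows are paired by
#'   (`motif_name`, `mark`, `age`), case-insensitively on name. A motif
#'   present in only one group is an error.
#' @param sig_alpha Enrichment significance threshold (default `1e-4`).
#' @param ns_floor Non-significance floor (default `0.05`).
#' @return A tibble: `motif_name`, `consensus`, `mark`, `age`, `p_iugr`,
#'   `p_control`, `change`.
#' @export
classify_motif_change <- function(motifs, sig_alpha = 1e-4,
                                  ns_floor = 0.05) {
  if (sig_alpha >= ns_floor) {
    stop("sig_alpha must be below ns_floor", call. = FALSE)
  }
  motifs$key <- toupper(motifs$motif_name)
  iugr <- motifs[motifs$group == "IUGR", ]
  ctrl <- motifs[motifs$group == "control", ]
  merged <- dplyr::inner_join(
    dplyr::select(iugr, "key", "motif_name", "consensus", "mark", "age",
                  p_iugr = "pvalue"),
    dplyr::select(ctrl, "key", "mark", "age", p_control = "pvalue"),
    by = c("key", "mark", "age")
  )
  unmatched <- nrow(iugr) + nrow(ctrl) - 2 * nrow(merged)
  if (unmatched != 0) {
    only <- setdiff(union(iugr$key, ctrl$key), merged$key)
    stop("motif(s) present in only one group for a mark/age: ",
         paste(utils::head(sort(only), 5), collapse = ", "), call. = FALSE)
  }
  merged$change <- dplyr::case_when(
    merged$p_iugr <= sig_alpha & merged$p_control <= sig_alpha ~
      "both_enriched",
    merged$p_iugr <= sig_alpha & merged$p_control >= ns_floor ~
      "gained_in_IUGR",
    merged$p_control <= sig_alpha & merged$p_iugr >= ns_floor ~
      "lost_in_IUGR",
    TRUE ~ "neither"
  )
  dplyr::select(merged, "motif_name", "consensus", "mark", "age",
                "p_iugr", "p_control", "change")
}

#' Motifs with a persistent enrichment change at both ages
#'
#' A motif persists when it carries the same directional change
#' (`gained_in_IUGR` or `lost_in_IUGR`) at both 2 and 10 weeks for the given
#' mark. `both_enriched` and `neither` are neutral and never persist.
#'
#' @param calls_2wk,calls_10wk [classify_motif_change()] outputs for the two
#'   ages.
#' @param mark Histone mark to test.
#' @return A tibble: `motif_name`, `consensus`, `mark`, `change`, sorted by
#'   motif name.
#' @export
persistent_motifs <- function(calls_2wk, calls_10wk, mark) {
  check_mark(mark)
  directional <- c("gained_in_IUGR", "lost_in_IUGR")
  pick <- function(calls) {
    calls <- calls[calls$mark == mark & calls$change %in% directional, ]
    tibble::tibble(key = toupper(calls$motif_name),
                   motif_name = calls$motif_name,
                   consensus = calls$consensus,
                   change = calls$change)
  }
  a <- pick(calls_2wk)
  b <- pick(calls_10wk)
  merged <- dplyr::inner_join(a, dplyr::select(b, "key", change_10 = "change"),
                              by = "key")
  merged <- merged[merged$change == merged$change_10, ]
  tibble::tibble(
    motif_name = merged$motif_name,
    consensus = merged$consensus,
    mark = mark,
    change = merged$change
  ) |> dplyr::arrange(.data$motif_name)
}
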