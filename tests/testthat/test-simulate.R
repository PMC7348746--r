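test_that("generators are deterministic given the seed and streams are independent", {
  a1 <- generate_annotation(n_genes = 30, seed = 99)
  a2 <- generate_annotation(n_genes = 30, seed = 99)
  expect_equal(a1$genes, a2$genes)
  expect_equal(a1$chrom_sizes, a2$chrom_sizes)
  p1 <- generate_condition_peaks(a1, seed = 99)
  p2 <- generate_condition_peaks(a2, seed = 99)
  expect_equal(p1$peaks, p2$peaks)
  m1 <- generate_motif_tables(default_motif_spec(), seed = 99)
  m2 <- generate_motif_tables(default_motif_spec(), seed = 99)
  expect_equal(m1$motifs, m2$motifs)
  expect_false(isTRUE(all.equal(
    generate_annotation(n_genes = 30, seed = 100)$genes, a1$genes)))
})

test_that("generated annotations have unique ids, both strands and wide spacing", {
  ann <- generate_annotation(n_genes = 100, n_chroms = 2, seed = 2)
  g <- ann$genes
  expect_equal(length(unique(g$gene_id)), 100)
  expect_setequal(unique(g$strand), c("+", "-"))
  # pairwise scan: with >= 12 kb gaps every TSS is > 5 kb from any other
  # gene's body
  for (cc in unique(g$chrom)) {
    sub <- g[g$chrom == cc, ]
    for (i in seq_len(nrow(sub))) {
      others <- sub[-i, ]
      gap <- pmax(others$start - sub$tss[i], sub$tss[i] - (others$end - 1))
      expect_true(all(gap > 5000))
    }
  }
  expect_error(generate_annotation(n_genes = 100, chrom_length = 1e5,
                                   seed = 2),
               "capacity exceeded")
})

test_that("noise-free planted bivalency is recovered exactly, per condition and state", {
  ann <- generate_annotation(n_genes = 120, seed = 6)
  pk <- generate_condition_peaks(ann, jitter_sd = 0, seed = 6)
  calls <- call_all_conditions(pk$peaks, ann)
  man <- pk$manifest
  for (cond in design_conditions()) {
    planted <- sort(man$gene_id[man[[paste0("planted_", cond)]]])
    called <- sort(calls$gene_id[calls$condition == cond])
    expect_equal(called, planted)  # precision and recall both 1
  }
  sm <- build_state_matrix(calls)
  truth <- man[man$state_code != "0000", ]
  expect_equal(sort(sm$gene_id), sort(truth$gene_id))
  codes <- apply(as.matrix(sm[, paste0("s_", design_conditions())]), 1,
                 function(s) paste(as.integer(s), collapse = ""))
  expect_equal(unname(codes[match(truth$gene_id, sm$gene_id)]),
               truth$state_code)
  # planted state fractions drive classifier label counts
  n1101 <- sum(truth$state_code == "1101")
  s <- summarize_transitions(sm)
  expect_equal(
    s$label_counts$n[s$label_counts$label ==
                       "control_resolved_IUGR_repoised"], n1101)
})

test_that("zero planted bivalency yields zero bivalent calls", {
  ann <- generate_annotation(n_genes = 60, seed = 14)
  pk <- generate_condition_peaks(ann, state_fractions = numeric(0),
                                 seed = 14)
  expect_equal(nrow(call_all_conditions(pk$peaks, ann)), 0)
})

test_that("planted all-3 concordance with 3 up and 3 down is recovered as (6, 3, 3)", {
  ann <- generate_annotation(n_genes = 300, seed = 12)
  de <- generate_diff_and_expression(
    ann, class_fractions = c(all3_up = 0.01, all3_down = 0.01),
    noise_sd = 0, seed = 12
  )
  expect_equal(sum(de$manifest$class == "all3_up"), 3)
  calls <- classify_concordance(assign_diff_sites(de$diff, ann),
                                de$expression)
  counts <- count_regulated_genes(calls)
  for (age in design_ages()) {
    all3 <- counts[counts$age == age & counts$row == "all_3_marks", ]
    expect_equal(c(all3$total, all3$up, all3$down), c(6L, 3L, 3L))
  }
})

test_that("planted discordant genes never reach the all-3 row", {
  ann <- generate_annotation(n_genes = 200, seed = 15)
  de <- generate_diff_and_expression(
    ann, class_fractions = c(discordant = 0.05), seed = 15
  )
  calls <- classify_concordance(assign_diff_sites(de$diff, ann),
                                de$expression)
  counts <- count_regulated_genes(calls)
  expect_true(all(counts$total[counts$row == "all_3_marks"] == 0))
  expect_true(all(counts$total[counts$row == "H3K4me3"] > 0))
})

test_that("concordance recovery matches the regulation manifest exactly without noise", {
  ann <- generate_annotation(n_genes = 250, seed = 18)
  de <- generate_diff_and_expression(ann, noise_sd = 0, seed = 18)
  calls <- classify_concordance(assign_diff_sites(de$diff, ann),
                                de$expression)
  man <- de$manifest
  for (age in design_ages()) {
    sub <- calls[calls$age == age, ]
    all3 <- sub$gene_id[sub$n_concordant_marks == 3]
    expect_setequal(all3, man$gene_id[man$class %in%
                                        c("all3_up", "all3_down")])
    up3 <- sub$gene_id[sub$n_concordant_marks == 3 &
                         sub$rna_direction == "up"]
    expect_setequal(up3, man$gene_id[man$class == "all3_up"])
  }
})

test_that("planted motif persistence classes are recovered and reproducible", {
  spec <- default_motif_spec()
  mo <- generate_motif_tables(spec, seed = 77)
  calls2 <- classify_motif_change(mo$motifs[mo$motifs$age == "2wk", ])
  calls10 <- classify_motif_change(mo$motifs[mo$motifs$age == "10wk", ])
  gains <- persistent_motifs(calls2, calls10, "H3K4me3")
  expect_equal(sum(grepl("^GAIN", gains$motif_name)), 9)
  expect_true(all(gains$change[grepl("^GAIN", gains$motif_name)] ==
                    "gained_in_IUGR"))
  expect_false(any(grepl("^TRAN|^BOTH|^NULL", gains$motif_name)))
  losses <- persistent_motifs(calls2, calls10, "H3K27me3")
  expect_equal(sort(losses$motif_name), sort(paste0("LOSS", 1:3)))
  # only neutral classes planted -> empty persistence
  neutral <- generate_motif_tables(
    tibble::tibble(motif_name = c("X1", "X2"), mark = "H3K4me3",
                   class = c("both_enriched", "none")),
    seed = 5
  )
  c2 <- classify_motif_change(neutral$motifs[neutral$motifs$age == "2wk", ])
  c10 <- classify_motif_change(neutral$motifs[neutral$motifs$age == "10wk", ])
  expect_equal(nrow(persistent_motifs(c2, c10, "H3K4me3")), 0)
})

test_that("boundary jitter degrades bivalency recall monotonically in expectation", {
  jitters <- c(0, 30, 1000)
  mean_recall <- vapply(jitters, function(js) {
    recalls <- vapply(1:20, function(s) {
      ann <- generate_annotation(n_genes = 40, seed = s)
      pk <- generate_condition_peaks(ann, jitter_sd = js, seed = s)
      man <- pk$manifest
      planted <- sum(vapply(design_conditions(), function(cond) {
        sum(man[[paste0("planted_", cond)]])
      }, numeric(1)))
      if (planted == 0) return(NA_real_)
      calls <- call_all_conditions(pk$peaks, ann)
      hit <- sum(vapply(design_conditions(), function(cond) {
        length(intersect(calls$gene_id[calls$condition == cond],
                         man$gene_id[man[[paste0("planted_", cond)]]]))
      }, numeric(1)))
      hit / planted
    }, numeric(1))
    mean(recalls, na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean_recall[1], 1)
  expect_true(all(diff(mean_recall) < 0))
  expect_true(all(mean_recall >= 0))
})

test_that("the simulate bundle round-trips through the package readers", {
  dir <- withr::local_tempdir()
  bundle <- simulate_bundle(dir, seed = 3, n_genes = 80)
  ann <- read_annotation_refflat(file.path(dir, "annotation.refFlat"),
                                 file.path(dir, "chrom.sizes"))
  expect_equal(ann$genes$gene_id, bundle$annotation$genes$gene_id)
  pk <- read_peaks(file.path(dir, "peaks_H3K4me3_2wk_control.bed"),
                   "H3K4me3", "2wk", "control")
  orig <- bundle$peaks$peaks
  orig <- orig[orig$mark == "H3K4me3" & orig$age == "2wk" &
                 orig$group == "control", ]
  expect_equal(nrow(pk), nrow(orig))
  expect_setequal(pk$start, orig$start)
  d <- read_diff_table(file.path(dir, "diff_H3K27Ac_10wk.tsv"),
                       "H3K27Ac", "10wk")
  expect_gt(nrow(d), 0)
  e <- read_expression(file.path(dir, "expression_2wk.tsv"), "2wk")
  expect_equal(nrow(e), 80)
  expect_false(any(is.na(e$mean_abundance_IUGR)))
  m <- read_motif_table(file.path(dir, "motifs_H3K4me3_2wk_IUGR.tsv"),
                        "H3K4me3", "2wk", "IUGR")
  expect_gt(nrow(m), 0)
  manifest <- readr::read_tsv(
    file.path(dir, "manifest_bivalency.tsv"),
    col_types = readr::cols(state_code = readr::col_character(),
                            .default = readr::col_guess())
  )
  expect_equal(manifest$gene_id, bundle$peaks$manifest$gene_id)
  expect_equal(manifest$state_code, bundle$peaks$manifest$state_code)
  expect_error(simulate_bundle(dir, seed = 3, n_genes = 80), "exists")
})
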