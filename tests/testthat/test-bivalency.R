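test_that("the 5 bp minimum overlap boundary separates bivalent from not", {
  ann <- genome_annotation(
    tibble::tibble(gene_id = "g1", chrom = "chr1", start = 200, end = 2000,
                   strand = "+"),
    c(chr1 = 10000)
  )
  k4 <- make_peaks("chr1", 100, 300, "H3K4me3")
  k27_5 <- make_peaks("chr1", 295, 400, "H3K27me3")
  call <- call_bivalent_promoters(k4, k27_5, ann)
  expect_equal(call$gene_id, "g1")
  expect_equal(call$overlap_bp, 5L)
  k27_4 <- make_peaks("chr1", 296, 400, "H3K27me3")
  expect_equal(nrow(call_bivalent_promoters(k4, k27_4, ann)), 0)
})

test_that("overlap midpoint must fall within the promoter window of the TSS", {
  ann <- genome_annotation(
    tibble::tibble(gene_id = "g1", chrom = "chr1", start = 50000,
                   end = 60000, strand = "+"),
    c(chr1 = 100000)
  )
  # overlap [10000,10100): midpoint 10050, 39950 bp from the TSS
  k4 <- make_peaks("chr1", 9000, 10100, "H3K4me3")
  k27 <- make_peaks("chr1", 10000, 11000, "H3K27me3")
  expect_equal(nrow(call_bivalent_promoters(k4, k27, ann)), 0)
  expect_equal(
    call_bivalent_promoters(k4, k27, ann, promoter_window = 50000)$gene_id,
    "g1"
  )
})

test_that("mixed-condition peak sets are rejected", {
  ann <- tiny_annotation()
  k4 <- make_peaks("chr1", 9000, 11000, "H3K4me3", age = "2wk")
  k27 <- make_peaks("chr1", 9000, 11000, "H3K27me3", age = "10wk")
  expect_error(call_bivalent_promoters(k4, k27, ann), "mixed conditions")
})

test_that("the bivalent gene set is unchanged when the two mark lists are swapped", {
  ann <- generate_annotation(n_genes = 80, seed = 19)
  pk <- generate_condition_peaks(ann, seed = 19)
  sel <- pk$peaks$age == "2wk" & pk$peaks$group == "control"
  k4 <- pk$peaks[sel & pk$peaks$mark == "H3K4me3", ]
  k27 <- pk$peaks[sel & pk$peaks$mark == "H3K27me3", ]
  a <- call_bivalent_promoters(k4, k27, ann)
  k4s <- k27; k4s$mark <- "H3K4me3"
  k27s <- k4; k27s$mark <- "H3K27me3"
  b <- call_bivalent_promoters(k4s, k27s, ann)
  expect_equal(sort(a$gene_id), sort(b$gene_id))
  expect_equal(a$overlap_bp[order(a$gene_id)],
               b$overlap_bp[order(b$gene_id)])
})

test_that("per-condition calls match the brute-force pair scan", {
  ann <- generate_annotation(n_genes = 40, seed = 29)
  pk <- generate_condition_peaks(ann, jitter_sd = 40, seed = 29)
  for (cond in c("2wk_control", "10wk_IUGR")) {
    parts <- strsplit(cond, "_", fixed = TRUE)[[1]]
    sel <- pk$peaks$age == parts[1] & pk$peaks$group == parts[2]
    k4 <- pk$peaks[sel & pk$peaks$mark == "H3K4me3", ]
    k27 <- pk$peaks[sel & pk$peaks$mark == "H3K27me3", ]
    got <- call_bivalent_promoters(k4, k27, ann)
    expect_equal(sort(got$gene_id), brute_bivalent_genes(k4, k27, ann))
  }
})

test_that("poised calls are flagged consistent only at very low expression", {
  calls <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), age = "2wk", group = "control",
    condition = "2wk_control", overlap_bp = 50L,
    k4_start = 0, k4_end = 100, k27_start = 50, k27_end = 150,
    tss_distance = 0
  )
  expr <- tibble::tibble(
    gene_id = c("g1", "g2"), age = "2wk", log2FC = 0, fdr = 0.5,
    mean_abundance_control = c(0, 500), mean_abundance_IUGR = c(0, 400)
  )
  expect_message(out <- filter_poised_by_expression(calls, expr),
                 "without abundance")
  expect_equal(out$poised_expression_consistent, c(TRUE, FALSE, NA))
  expect_equal(nrow(out), 3)  # inconsistent calls are retained, flagged
})

test_that("the state matrix collects the four conditions and drops never-bivalent genes", {
  calls <- tibble::tibble(
    gene_id = c("Acod1", "Acod1", "Acod1", "Cdh16"),
    age = c("2wk", "2wk", "10wk", "10wk"),
    group = c("control", "IUGR", "IUGR", "control"),
    condition = c("2wk_control", "2wk_IUGR", "10wk_IUGR", "10wk_control"),
    overlap_bp = 10L, k4_start = 0, k4_end = 1, k27_start = 0, k27_end = 1,
    tss_distance = 0
  )
  sm <- build_state_matrix(calls)
  expect_equal(sm$gene_id, c("Acod1", "Cdh16"))
  expect_equal(unlist(sm[sm$gene_id == "Acod1", -1], use.names = FALSE),
               c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(unlist(sm[sm$gene_id == "Cdh16", -1], use.names = FALSE),
               c(FALSE, FALSE, TRUE, FALSE))
  expect_error(build_state_matrix(calls[c(1, 1), ]), "duplicate")
  expect_equal(nrow(build_state_matrix(calls[0, ])), 0)
})

test_that("transition labels agree with an exhaustive 16-state lookup oracle", {
  lookup <- c(
    "0000" = "never_poised",
    "0001" = "0001",
    "0010" = "control_de_novo_IUGR_resolved",
    "0011" = "0011",
    "0100" = "gained_in_IUGR_2wk",
    "0101" = "gained_in_IUGR_2wk",
    "0110" = "gained_in_IUGR_2wk",
    "0111" = "gained_in_IUGR_2wk",
    "1000" = "lost_in_IUGR_2wk",
    "1001" = "lost_in_IUGR_2wk",
    "1010" = "lost_in_IUGR_2wk",
    "1011" = "lost_in_IUGR_2wk",
    "1100" = "1100",
    "1101" = "control_resolved_IUGR_repoised",
    "1110" = "1110",
    "1111" = "stable_poised"
  )
  for (code in names(lookup)) {
    bits <- as.integer(strsplit(code, "")[[1]]) == 1
    expect_equal(classify_transition(bits), unname(lookup[code]),
                 info = code)
  }
  # the published six-gene patterns
  expect_equal(classify_transition(c(TRUE, TRUE, FALSE, TRUE)),
               "control_resolved_IUGR_repoised")
  expect_equal(classify_transition(c(FALSE, FALSE, TRUE, FALSE)),
               "control_de_novo_IUGR_resolved")
})

test_that("transition summaries tally labels and 10-wk discordance", {
  sm <- islet_bivalency_states()
  s <- summarize_transitions(sm)
  expect_equal(s$n_discordant_10wk, 6L)
  expect_equal(
    s$label_counts$n[s$label_counts$label ==
                       "control_resolved_IUGR_repoised"], 3L)
  expect_equal(
    s$label_counts$n[s$label_counts$label ==
                       "control_de_novo_IUGR_resolved"], 3L)
  all_poised <- sm
  for (cond in design_conditions()) all_poised[[paste0("s_", cond)]] <- TRUE
  expect_equal(summarize_transitions(all_poised)$n_discordant_10wk, 0L)
  # random matrices agree with an exhaustive tally
  withr::with_seed(41, {
    rnd <- tibble::tibble(gene_id = sprintf("g%03d", 1:200))
    for (cond in design_conditions()) {
      rnd[[paste0("s_", cond)]] <- sample(c(TRUE, FALSE), 200,
                                          replace = TRUE)
    }
  })
  s <- summarize_transitions(rnd)
  expect_equal(sum(s$label_counts$n), 200L)
  labels <- classify_transition(rnd)
  for (k in seq_len(nrow(s$label_counts))) {
    expect_equal(s$label_counts$n[k],
                 sum(labels == s$label_counts$label[k]))
  }
  expect_equal(s$n_discordant_10wk,
               sum(rnd$s_10wk_control != rnd$s_10wk_IUGR))
})
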