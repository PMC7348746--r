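make_diff <- function(chrom, start, end, mark = "H3K27Ac", age = "10wk",
                      log2FC = 1, pvalue = 0.001, fdr = 0.01) {
  tibble::tibble(chrom = chrom, start = start, end = end, mark = mark,
                 age = age, log2FC = log2FC, pvalue = pvalue, fdr = fdr)
}

test_that("diff sites are assigned within the 5 kb TSS window only", {
  ann <- tiny_annotation()  # gA TSS at 10000 (+ strand)
  # midpoint 4.9 kb upstream -> assigned
  near <- make_diff("chr1", 5100 - 200, 5100 + 200)
  expect_equal(assign_diff_sites(near, ann)$gene_id, "gA")
  expect_equal(assign_diff_sites(near, ann)$distance, -4900)
  # midpoint 5.1 kb upstream -> outside the window
  far <- make_diff("chr1", 4900 - 200, 4900 + 200)
  expect_equal(nrow(assign_diff_sites(far, ann)), 0)
  # non-significant FDR excluded
  ns <- make_diff("chr1", 9900, 10100, fdr = 0.2)
  expect_equal(nrow(assign_diff_sites(ns, ann)), 0)
  expect_equal(nrow(assign_diff_sites(ns, ann, fdr_max = NA)), 1)
})

test_that("among candidate sites the nearest wins, then larger effect, then start", {
  ann <- tiny_annotation()
  two <- dplyr::bind_rows(
    make_diff("chr1", 11000 - 100, 11000 + 100, log2FC = 0.5),  # 1 kb
    make_diff("chr1", 13000 - 100, 13000 + 100, log2FC = 2.0)   # 3 kb
  )
  got <- assign_diff_sites(two, ann)
  expect_equal(nrow(got), 1)
  expect_equal(got$distance, 1000)
  expect_equal(got$log2FC, 0.5)
  tied <- dplyr::bind_rows(
    make_diff("chr1", 9000 - 100, 9000 + 100, log2FC = 0.5),    # -1 kb
    make_diff("chr1", 11000 - 100, 11000 + 100, log2FC = -2.0)  # +1 kb
  )
  got <- assign_diff_sites(tied, ann)
  expect_equal(got$log2FC, -2)  # equal |distance|, larger |log2FC| wins
})

test_that("assignment agrees with a brute-force scan on synthetic sites", {
  ann <- generate_annotation(n_genes = 100, seed = 21)
  de <- generate_diff_and_expression(ann, seed = 21)
  got <- assign_diff_sites(de$diff, ann, window = 5000, fdr_max = 0.05)
  expect_gt(nrow(got), 25)
  # brute force: per gene x mark x age, scan all significant sites
  sig <- de$diff[de$diff$fdr <= 0.05, ]
  mid <- floor((sig$start + sig$end) / 2)
  for (r in sample(seq_len(nrow(got)), 25)) {
    row <- got[r, ]
    g <- ann$genes[ann$genes$gene_id == row$gene_id, ]
    cand <- which(sig$mark == row$mark & sig$age == row$age &
                    sig$chrom == g$chrom & abs(mid - g$tss) <= 5000)
    expect_true(length(cand) >= 1)
    best <- cand[order(abs(mid[cand] - g$tss), -abs(sig$log2FC[cand]),
                       sig$start[cand])][1]
    expect_equal(row$start, sig$start[best])
  }
})

test_that("concordance follows the activating/repressive sign rules", {
  genes <- islet_allmarks_genes()
  inputs <- marks_table_to_inputs(genes, "10wk")
  calls <- classify_concordance(inputs$assignments, inputs$expression)
  expect_equal(nrow(calls), 6)
  expect_true(all(calls$n_concordant_marks == 3))
  expect_equal(sort(calls$gene_id[calls$rna_direction == "up"]),
               c("Mcf2l", "Tfam", "Trpm5"))
  expect_equal(sort(calls$gene_id[calls$rna_direction == "down"]),
               c("Mpz", "Slc28a2", "Tnf"))
  # repressive mark moving with expression is discordant
  asn <- tibble::tibble(gene_id = "gX", mark = "H3K27me3", age = "10wk",
                        log2FC = 1, fdr = 0.01, distance = 0,
                        chrom = "chr1", start = 0, end = 10)
  expr <- tibble::tibble(gene_id = "gX", age = "10wk", log2FC = 1,
                         fdr = 0.01, mean_abundance_control = NA_real_,
                         mean_abundance_IUGR = NA_real_)
  expect_equal(classify_concordance(asn, expr)$H3K27me3, "discordant")
  # a zero change cannot correlate
  asn$log2FC <- 0
  expect_equal(classify_concordance(asn, expr)$H3K27me3, "discordant")
  asn$mark <- "H3K4me3"
  expect_equal(classify_concordance(asn, expr)$H3K4me3, "discordant")
})

test_that("genes without significant expression are dropped with a log message", {
  asn <- tibble::tibble(gene_id = c("g1", "g2"), mark = "H3K4me3",
                        age = "10wk", log2FC = 1, fdr = 0.01, distance = 0,
                        chrom = "chr1", start = 0, end = 10)
  expr <- tibble::tibble(gene_id = "g1", age = "10wk", log2FC = 1,
                         fdr = 0.01, mean_abundance_control = NA_real_,
                         mean_abundance_IUGR = NA_real_)
  expect_message(calls <- classify_concordance(asn, expr), "dropped")
  expect_equal(calls$gene_id, "g1")
})

test_that("regulated-gene counts split by direction and respect the all-3 rule", {
  genes <- islet_allmarks_genes()
  inputs <- marks_table_to_inputs(genes, "10wk")
  calls <- classify_concordance(inputs$assignments, inputs$expression)
  counts <- count_regulated_genes(calls)
  all3 <- counts[counts$row == "all_3_marks", ]
  expect_equal(all3$total, 6L)
  expect_equal(all3$up, 3L)
  expect_equal(all3$down, 3L)
  expect_true(all(counts$up + counts$down == counts$total))
  # order invariance
  counts2 <- count_regulated_genes(calls[sample(nrow(calls)), ])
  expect_equal(dplyr::arrange(counts2, age, row),
               dplyr::arrange(counts, age, row))
  # empty input
  empty <- count_regulated_genes(calls[0, ])
  expect_equal(nrow(empty), 0)
  # a 2-of-3 gene is excluded from the all-3 row but counted per mark
  two <- calls[1, ]
  two$H3K27me3 <- "discordant"
  two$n_concordant_marks <- 2
  c2 <- count_regulated_genes(two)
  expect_equal(c2$total[c2$row == "all_3_marks"], 0L)
  expect_equal(c2$total[c2$row == "H3K4me3"], 1L)
  expect_equal(c2$total[c2$row == "H3K27Ac"], 1L)
})

test_that("the all-3-marks set is contained in every per-mark set", {
  ann <- generate_annotation(n_genes = 200, seed = 8)
  de <- generate_diff_and_expression(ann, seed = 8)
  calls <- classify_concordance(assign_diff_sites(de$diff, ann),
                                de$expression)
  all3 <- calls$gene_id[calls$n_concordant_marks == 3]
  for (m in histone_marks()) {
    expect_true(all(all3 %in% calls$gene_id[calls[[m]] == "concordant"]))
  }
})

test_that("persistence requires the same concordant change at both ages", {
  tab <- islet_k27ac_persistent_genes()
  inputs <- k27ac_table_to_inputs(tab)
  calls2 <- classify_concordance(inputs$age2$assignments,
                                 inputs$age2$expression)
  calls10 <- classify_concordance(inputs$age10$assignments,
                                  inputs$age10$expression)
  kept <- persistent_mark_genes(calls2, calls10, "H3K27Ac", "down")
  expect_equal(kept, sort(tab$gene))  # all 20 transcribed genes persist
  expect_true(all(c("Bcat2", "Dram1", "Ulk1") %in% kept))
  # flipping the 10-wk H3K27Ac sign of one gene rejects exactly that gene
  flipped <- tab
  flipped$k27ac_log2FC_10wk[flipped$gene == "Bcat2"] <- 0.88
  inputs_f <- k27ac_table_to_inputs(flipped)
  kept_f <- persistent_mark_genes(
    classify_concordance(inputs_f$age2$assignments,
                         inputs_f$age2$expression),
    classify_concordance(inputs_f$age10$assignments,
                         inputs_f$age10$expression),
    "H3K27Ac", "down"
  )
  expect_equal(setdiff(kept, kept_f), "Bcat2")
  # a gene significant at one age only does not persist
  only2 <- tab
  only2$rna_fdr_10wk[only2$gene == "Xbp1"] <- 0.5
  inputs_o <- k27ac_table_to_inputs(only2)
  kept_o <- persistent_mark_genes(
    classify_concordance(inputs_o$age2$assignments,
                         inputs_o$age2$expression),
    classify_concordance(inputs_o$age10$assignments,
                         inputs_o$age10$expression),
    "H3K27Ac", "down"
  )
  expect_false("Xbp1" %in% kept_o)
})
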