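test_that("priority selection is the conjunction over VUS records", {
  th <- threshold_pair(1.8, 25.7)
  tab <- variant_table(
    gene = "G", protein_change = sprintf("p.Ala%dVal", 1:3),
    classification = "VUS",
    ddg_fold = c(2.0, 2.0, 1.5), cadd = c(26.0, 25.0, 30.0))
  sel <- select_priority_vus(tab, th)
  expect_equal(sel$protein_change, "p.Ala1Val")

  no_vus <- variant_table("G", "p.Ala1Val", "P", ddg_fold = 3, cadd = 30)
  expect_equal(nrow(select_priority_vus(no_vus, th)), 0)
})

test_that("priority selection equals a brute-force row scan", {
  tab <- generate_variant_table(generator_config(50000, seed = 7))
  th <- threshold_pair(1.8, 25.7)
  sel <- select_priority_vus(tab, th)
  brute <- tab[tab$classification == "VUS" & !is.na(tab$ddg_fold) &
                 !is.na(tab$cadd) & tab$ddg_fold > 1.8 &
                 tab$cadd > 25.7, ]
  expect_equal(sel, brute)
  expect_lte(nrow(sel), sum(tab$classification == "VUS"))
})

test_that("gene summaries reproduce printed densities from counts", {
  # (count, length) pairs from the published per-gene summary
  expect_equal(variant_density(143, 2344), 61.0)
  expect_equal(variant_density(17, 513), 33.1)
  expect_equal(variant_density(30, 1000), 30.0)

  ref <- utils::read.delim(extdata("prioritized_gene_summary.tsv"))
  # expand each gene's count into that many prioritized records and run
  # the summary end to end
  recs <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    n <- ref$n_prioritized[i]
    variant_table(gene = ref$gene[i],
                  protein_change = sprintf("p.Ala%dVal", seq_len(n)),
                  classification = "VUS",
                  ddg_fold = 2.5, cadd = 28)
  }))
  lengths <- data.frame(gene = ref$gene, length = ref$protein_length)
  summ <- summarize_genes(recs, lengths, min_density = 30)
  expect_equal(nrow(summ), 39)
  expect_equal(summ$gene, sort(ref$gene))
  expect_equal(summ$variant_density,
               ref$variant_density[match(summ$gene, ref$gene)])
})

test_that("boundary density is included and missing genes are an error", {
  recs <- variant_table(gene = rep("AAA", 30),
                        protein_change = sprintf("p.Ala%dVal", 1:30),
                        classification = "VUS", ddg_fold = 2, cadd = 27)
  lengths <- data.frame(gene = "AAA", length = 1000L)
  summ <- summarize_genes(recs, lengths, min_density = 30)
  expect_equal(summ$variant_density, 30.0)      # "30 or more" includes 30
  expect_error(summarize_genes(recs, data.frame(gene = "BBB",
                                                length = 10L)), "AAA")
})

test_that("class statistics give exact fractions and means on toy input", {
  tab <- variant_table(gene = "G", protein_change = sprintf("p.A%dV", 1:5),
                       classification = c("P", "P", "P", "B", "B"),
                       ddg_fold = c(1, -1, 0, 0.10, 0.16))
  s <- suppressWarnings(class_statistics(tab))
  p <- s[s$class == "P", ]
  expect_equal(c(p$fraction_destabilizing, p$fraction_stabilizing,
                 p$fraction_neutral), c(1, 1, 1) / 3)
  expect_equal(p$mean_ddg, 0)
  expect_equal(s$mean_ddg[s$class == "B"], 0.13)
  expect_s3_class(attr(s, "b_vs_p_test"), "htest")
})

test_that("class statistics recover the generator's ddG means", {
  tab <- generate_variant_table(generator_config(50000, seed = 7))
  s <- class_statistics(tab)
  for (cl in c("B", "P")) {
    mu <- c(B = 0.13, P = 0.80)[cl]
    sd_cl <- c(B = 0.8, P = 1.2)[cl]
    row <- s[s$class == cl, ]
    # mixture mean: the zero atom shrinks the Gaussian mean
    expected <- mu * (1 - 0.14)
    se <- sd_cl / sqrt(row$n)
    expect_lt(abs(row$mean_ddg - expected), 2 * se + 0.02)
  }
  # confidence grouping splits every class at the cutoff
  g <- class_statistics(tab, group_by = "confidence")
  expect_true(all(g$group %in% c("high", "low")))
  expect_equal(sum(g$n), sum(!is.na(tab$ddg_fold) &
                               !is.na(tab$confidence)))
})

test_that("cross-tabulation percentages and margins are conserved", {
  tab <- variant_table(gene = "G", protein_change = sprintf("p.A%dV", 1:4),
                       classification = c("B", "B", "P", "P"),
                       confidence = c(40, 95, 40, 95))
  ct <- cross_tabulate(tab, "classification", "confidence_bin")
  expect_equal(unname(ct$counts["Total", "Total"]), 4)
  expect_true(all(ct$percent[c("B", "P"), c("<50", ">90")] == 25.0))

  big <- generate_variant_table(generator_config(10000, seed = 2))
  ct2 <- cross_tabulate(big, "classification", "confidence_bin")
  m <- ct2$counts
  expect_equal(unname(m["Total", "Total"]), 10000)
  expect_equal(unname(rowSums(m[classification_labels(), 1:4])),
               unname(m[classification_labels(), "Total"]))
})

test_that("cell proportions recover the configured confidence strata", {
  tab <- generate_variant_table(generator_config(50000, seed = 7))
  ct <- cross_tabulate(tab, "classification", "confidence_bin")
  # reference class-by-confidence counts, restated independently here
  counts <- rbind(
    B = c(719, 231, 506, 269), LB = c(15395, 3153, 5973, 3386),
    VUS = c(25707, 10306, 30106, 23647), LP = c(579, 203, 827, 832),
    P = c(1201, 470, 2084, 2573))
  target <- 100 * counts / sum(counts)
  got <- 100 * ct$counts[rownames(counts), 1:4] / 50000
  expect_lt(max(abs(got - target)), 0.5)
})

test_that("hidden-pathogenic extrapolation follows its identity", {
  res <- estimate_hidden_pathogenic(6328, 793, 3456)
  expect_equal(res$misfolding_fraction, 0.125)
  expect_equal(res$estimated_non_misfolding_pathogenic, 24192)
  expect_equal(res$estimated_total_hidden_pathogenic,
               res$estimated_non_misfolding_pathogenic + 3456)
  # unrounded variant: 3456 * (6328/793 - 1)
  expect_equal(res$estimated_non_misfolding_pathogenic_unrounded,
               3456 * (6328 / 793 - 1), tolerance = 1e-12)
  expect_equal(round(res$estimated_non_misfolding_pathogenic_unrounded),
               24122)

  simple <- estimate_hidden_pathogenic(100, 50, 10)
  expect_equal(simple$misfolding_fraction, 0.5)
  expect_equal(simple$estimated_non_misfolding_pathogenic, 10)
  expect_error(estimate_hidden_pathogenic(100, 0, 10), "undefined")
})
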