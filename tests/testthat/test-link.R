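link_ann <- data.frame(
  cpg_id = c("cg_p1", "cg_p2", "cg_b1", "cg_ig", "cg_p3"),
  chrom = "chr1", pos = c(100L, 200L, 2100L, 9000L, 300L),
  gene = c("GENE_A", "GENE_A", "GENE_A", "", "GENE_B"),
  context = c("promoter", "promoter", "gene_body", "intergenic", "promoter"),
  stringsAsFactors = FALSE)

test_that("the promoter/gene-body direction rule classifies links", {
  de <- data.frame(feature_id = "GENE_A", effect = -1)   # down in females
  dm <- data.frame(feature_id = c("cg_p1", "cg_b1"), effect = c(0.2, 0.2))
  links <- directional_link(dm, de, link_ann)
  # promoter hyper_F + down_F -> consistent; gene body hyper_F + down_F -> not
  expect_true(links$consistent[links$cpg_id == "cg_p1"])
  expect_false(links$consistent[links$cpg_id == "cg_b1"])

  de_up <- data.frame(feature_id = "GENE_A", effect = 1)
  links_up <- directional_link(dm, de_up, link_ann)
  expect_false(links_up$consistent[links_up$cpg_id == "cg_p1"])
  expect_true(links_up$consistent[links_up$cpg_id == "cg_b1"])

  # a transcript is linked with >= 1 consistent record even when other
  # records disagree
  expect_equal(linked_transcripts(links), "GENE_A")

  # CpGs without annotation are skipped and counted
  dm2 <- rbind(dm, data.frame(feature_id = "cg_unknown", effect = 0.5))
  links2 <- directional_link(dm2, de, link_ann)
  expect_equal(attr(links2, "n_unannotated"), 1)
})

test_that("hypermethylation summary reproduces counts and handles edge cases", {
  s <- hypermethylation_summary(c(0.1, 0.2, -0.1, 0.3))
  expect_equal(s$n_hyper_F, 3)
  expect_equal(s$pct_hyper_F, 75)
  expect_equal(hypermethylation_summary(c(-1, -2))$pct_hyper_F, 0)
  expect_error(hypermethylation_summary(numeric(0)), "no differential")
})

test_that("protein linking separates methylation-linked from the full chain", {
  gene_map <- data.frame(protein_id = c("P_A", "P_B", "P_C"),
                         gene = c("GENE_A", "GENE_B", "GENE_C"),
                         stringsAsFactors = FALSE)
  de <- data.frame(feature_id = "GENE_A", effect = -1)
  dm <- data.frame(feature_id = c("cg_p1", "cg_p3"), effect = c(0.2, 0.2))
  links <- directional_link(dm, de, link_ann)
  dp <- data.frame(feature_id = c("P_A", "P_B", "P_D"), effect = c(-0.5, 0.3, 1))
  pl <- link_proteins(links, dp, gene_map, de, dm, link_ann)
  # P_A: gene has DM CpG, gene DE with matching direction -> linked + chain
  expect_true("P_A" %in% pl$linked)
  expect_true("P_A" %in% pl$chain)
  # P_B: gene carries a DM CpG but is not DE -> linked only
  expect_true("P_B" %in% pl$linked)
  expect_false("P_B" %in% pl$chain)
  # unmapped protein is excluded and counted
  expect_equal(pl$n_unmapped, 1)
  expect_true(all(pl$chain %in% pl$linked))
})

test_that("DMR-transcript concordance applies the promoter rule", {
  dmrs <- data.frame(chrom = "chr1", start = 50L, end = 250L, n_cpgs = 2,
                     mean_delta_beta = 0.2, area = 0.4, direction = "hyper_F",
                     p_value = 0.005, fwer_rank = 1,
                     cpg_ids = "cg_p1,cg_p2", stringsAsFactors = FALSE)
  down <- data.frame(feature_id = "GENE_A", effect = -2)
  up <- data.frame(feature_id = "GENE_A", effect = 2)
  expect_true(link_dmrs_to_transcripts(dmrs, down, link_ann)$concordant)
  expect_false(link_dmrs_to_transcripts(dmrs, up, link_ann)$concordant)
  none <- data.frame(feature_id = "GENE_Z", effect = 1)
  expect_equal(nrow(link_dmrs_to_transcripts(dmrs, none, link_ann)), 0)
})

test_that("integration summary respects containment and survives empty inputs", {
  gene_map <- data.frame(protein_id = "P_A", gene = "GENE_A", stringsAsFactors = FALSE)
  de <- data.frame(feature_id = "GENE_A", effect = -1)
  dm <- data.frame(feature_id = "cg_p1", effect = 0.2)
  dp <- data.frame(feature_id = "P_A", effect = -0.5)
  links <- directional_link(dm, de, link_ann)
  pl <- link_proteins(links, dp, gene_map, de, dm, link_ann)
  s <- summarize_overlap(dm, de, dp, links, pl, link_ann, gene_map)
  expect_lte(s$n_linked_transcripts, s$n_de_transcripts)
  expect_lte(s$n_chain_proteins, s$n_linked_proteins)
  expect_lte(s$n_linked_proteins, s$n_dp_proteins)
  expect_equal(s$venn$meth_txn_prot, 1)

  # empty link table: zero percentages, no division error
  empty_dm <- dm[0, ]; empty_links <- directional_link(empty_dm, de, link_ann)
  pl0 <- link_proteins(empty_links, dp, gene_map, de, empty_dm, link_ann)
  s0 <- summarize_overlap(empty_dm, de, dp, empty_links, pl0, link_ann, gene_map)
  expect_equal(s0$pct_linked_transcripts, 0)
  expect_equal(s0$n_linked_proteins, 0)
})

test_that("flipping sex labels flips every direction and preserves counts", {
  sim <- simulate_cohort(small_config(seed = 19))
  sheet_flip <- sim$sheet
  sheet_flip$sex <- ifelse(sheet_flip$sex == "F", "M", "F")
  res <- sex_contrast(sim$transcriptome, sim$sheet, "baseline")
  res_flip <- sex_contrast(sim$transcriptome, sheet_flip, "baseline")
  expect_equal(res_flip$table$effect, -res$table$effect, tolerance = 1e-10)
  expect_equal(res_flip$table$p, res$table$p, tolerance = 1e-10)

  mres <- sex_contrast(sim$methylome, sim$sheet, "baseline")
  mres_flip <- sex_contrast(sim$methylome, sheet_flip, "baseline")
  dm <- significant_features(mres); dm_f <- significant_features(mres_flip)
  de <- significant_features(res); de_f <- significant_features(res_flip)
  links <- directional_link(dm, de, sim$annotation$cpg)
  links_f <- directional_link(dm_f, de_f, sim$annotation$cpg)
  expect_equal(nrow(links), nrow(links_f))
  expect_equal(sum(links$consistent), sum(links_f$consistent))
  expect_equal(links$meth_direction,
               ifelse(links_f$meth_direction == "hyper_F", "hypo_F", "hyper_F"))
})

test_that("linked-transcript fraction tracks the planted coupling fraction", {
  sim <- simulate_cohort(sim_config(seed = 23))
  res_t <- sex_contrast(sim$transcriptome, sim$sheet, "baseline")
  res_m <- sex_contrast(sim$methylome, sim$sheet, "baseline")
  de <- significant_features(res_t)
  dm <- significant_features(res_m)
  links <- directional_link(dm, de, sim$annotation$cpg)
  pct <- 100 * length(linked_transcripts(links)) / nrow(de)
  planted <- 100 * nrow(sim$truth$coupled_gene) / nrow(sim$truth$de_gene)
  expect_lt(abs(pct - planted), 10)
})
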