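test_that("fiber classification follows argmax, tie and pooling rules", {
  ref <- data.frame(protein_id = c("A", "B", "C"),
                    pct_type1 = c(70, 34, 10),
                    pct_type2a = c(20, 33, 45),
                    pct_type2x = c(10, 33, 45), stringsAsFactors = FALSE)
  calls <- classify_fiber_proteins(ref)
  expect_equal(calls$dominant_type[calls$protein_id == "A"], "type1")
  expect_equal(calls$dominant_type[calls$protein_id == "B"], "unclassified")

  pooled <- classify_fiber_proteins(ref, pool_type2 = TRUE)
  expect_equal(pooled$dominant_type[pooled$protein_id == "C"], "type2")

  # pure function of the row: order-independent
  calls_rev <- classify_fiber_proteins(ref[3:1, ])
  expect_equal(calls_rev$dominant_type[calls_rev$protein_id == "A"], "type1")
})

test_that("fiber enrichment p matches exact hypergeometric enumeration", {
  # perfectly separated 2x2 ((8,0),(0,8)): p = 2 / C(16,8)
  ref <- data.frame(protein_id = sprintf("P%02d", 1:16),
                    pct_type1 = rep(c(10, 80), each = 8),
                    pct_type2a = rep(c(60, 10), each = 8),
                    pct_type2x = rep(c(30, 10), each = 8), stringsAsFactors = FALSE)
  calls <- classify_fiber_proteins(ref, pool_type2 = TRUE)
  dp <- data.frame(feature_id = ref$protein_id,
                   effect = rep(c(-1, 1), each = 8))   # males higher on type2
  enr <- fiber_enrichment_of_diff(dp, calls)
  expect_equal(enr$p, 2 / choose(16, 8), tolerance = 1e-12)
  expect_gt(enr$odds_ratio, 1)  # Haldane-corrected, finite
  expect_true(is.finite(enr$odds_ratio))
  expect_equal(unname(enr$table["male_higher", "type2"]), 8)

  # independent enumeration oracle for a mixed table
  dp2 <- data.frame(feature_id = ref$protein_id,
                    effect = c(rep(-1, 5), rep(1, 3), rep(-1, 2), rep(1, 6)))
  enr2 <- fiber_enrichment_of_diff(dp2, calls)
  tab <- enr2$table
  # two-sided Fisher p by summing all tables as or less probable
  k_obs <- tab[1, 1]; R1 <- sum(tab[1, ]); C1 <- sum(tab[, 1]); N <- sum(tab)
  probs <- dhyper(0:min(R1, C1), C1, N - C1, R1)
  p_manual <- sum(probs[probs <= dhyper(k_obs, C1, N - C1, R1) * (1 + 1e-7)])
  expect_equal(enr2$p, p_manual, tolerance = 1e-9)
})

test_that("fiber enrichment recovers the planted male fast-fiber excess", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_cohort(small_config(seed = 60 + s))
    prep <- prep_proteome(sim$proteome, sim$sheet)
    dp <- significant_features(sex_contrast(prep$matrix, sim$sheet, "baseline"))
    calls <- classify_fiber_proteins(sim$annotation$fiber_reference, pool_type2 = TRUE)
    enr <- fiber_enrichment_of_diff(dp, calls)
    enr$odds_ratio > 1 && enr$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("equalization is a set rule and antisymmetric in timepoints", {
  rec <- equalization_analysis(c("A", "B", "C"), "B")
  expect_setequal(rec$protein_id[rec$equalized], c("A", "C"))
  expect_false(rec$equalized[rec$protein_id == "B"])

  # identical sets: nothing equalized
  rec2 <- equalization_analysis(c("A", "B"), c("A", "B"))
  expect_false(any(rec2$equalized))

  # swapping the timepoints inverts the classification of shared features
  fwd <- equalization_analysis(c("A", "B"), c("B", "C"))
  rev <- equalization_analysis(c("B", "C"), c("A", "B"))
  expect_true(fwd$equalized[fwd$protein_id == "A"])
  expect_false(rev$equalized[rev$protein_id == "B"])
  expect_true(rev$equalized[rev$protein_id == "C"])

  expect_equal(nrow(equalization_analysis(character(0), "B")), 0)
})

test_that("training shrinks the planted male fast-fiber excess", {
  sim <- simulate_cohort(small_config(seed = 29))
  prep <- prep_proteome(sim$proteome, sim$sheet)
  base_dp <- significant_features(sex_contrast(prep$matrix, sim$sheet, "baseline"))
  trained_dp <- significant_features(sex_contrast(prep$matrix, sim$sheet, "trained"))
  train_m <- paired_contrast(prep$matrix, sim$sheet, "baseline", "trained", sex = "M")
  train_f <- paired_contrast(prep$matrix, sim$sheet, "baseline", "trained", sex = "F")
  calls <- classify_fiber_proteins(sim$annotation$fiber_reference, pool_type2 = TRUE)
  rec <- equalization_analysis(intersect(base_dp$feature_id, calls$protein_id),
                               intersect(trained_dp$feature_id, calls$protein_id),
                               male_response = train_m, female_response = train_f)
  planted_fast <- intersect(sim$truth$equalized_protein_ids,
                            sim$truth$type2_protein_ids)
  hit <- rec[rec$protein_id %in% planted_fast, ]
  expect_gte(sum(hit$equalized) / length(planted_fast), 0.7)
  expect_true(all(hit$male_change_direction == "down"))
  # slow-fiber equalization goes the other way: males fill the deficit
  planted_slow <- intersect(sim$truth$equalized_protein_ids,
                            sim$truth$type1_protein_ids)
  hit1 <- rec[rec$protein_id %in% planted_slow, ]
  expect_true(all(hit1$male_change_direction == "up"))
})

test_that("mitochondrial annotation is exact with near-miss reporting", {
  mito <- c("CS", "SDHA", "MT-CO1")
  flags <- annotate_mito(c("CS", "ACTB"), mito)
  expect_true(flags[["CS"]])
  expect_false(flags[["ACTB"]])
  expect_warning(f2 <- annotate_mito(c("cs", "SDHA"), mito), "case")
  expect_false(f2[["cs"]])
  expect_equal(attr(f2, "near_miss"), "cs")

  # planted training response concentrates on mitochondrial proteins
  sim <- simulate_cohort(small_config(seed = 33))
  prep <- prep_proteome(sim$proteome, sim$sheet)
  tf <- significant_features(paired_contrast(prep$matrix, sim$sheet, "baseline", "trained", sex = "F"))
  tm <- significant_features(paired_contrast(prep$matrix, sim$sheet, "baseline", "trained", sex = "M"))
  up_both <- intersect(tf$feature_id[tf$effect > 0], tm$feature_id[tm$effect > 0])
  frac_up <- mean(up_both %in% sim$annotation$mito_list)
  background <- mean(rownames(prep$matrix$values) %in% sim$annotation$mito_list)
  expect_gte(frac_up, 2 * background)
})
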