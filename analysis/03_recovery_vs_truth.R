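#!/usr/bin/env Rscript
# Stage 3 — score the pipeline's calls against the planted ground truth
# of the stage-1 cohort: sensitivity and FDR of the differential stages,
# DMR block detection, chain recovery, acute partition purity and
# equalization. Writes results/recovery.json.

library(sexomics)

truth <- read_json_artifact("results/cohort/truth.json")
dir.create("results", showWarnings = FALSE)

out <- run_pipeline(pipeline_config(sim = sim_config(), seed = 1))

de_bh <- significant_features(out$results$transcriptome, adjusted = TRUE)
dm_bh <- significant_features(out$results$methylome, p = 0.01, adjusted = TRUE)
dp_raw <- out$sig$dp

tr_de <- truth$de_gene$gene
tr_dm <- truth$dm_cpg$cpg_id
tr_dp <- truth$dp_protein$protein_id

dmr_tr <- truth$dmr_intervals
sig_dmrs <- out$dmrs[out$dmrs$p_value <= 0.05, ]
block_hit <- vapply(seq_len(nrow(dmr_tr)), function(i)
  any(sig_dmrs$chrom == dmr_tr$chrom[i] & sig_dmrs$start <= dmr_tr$end[i] &
        sig_dmrs$end >= dmr_tr$start[i]), TRUE)

rec <- list(
  de_sensitivity = mean(tr_de %in% de_bh$feature_id),
  de_fdr = mean(!de_bh$feature_id %in% tr_de),
  dm_sensitivity = mean(tr_dm %in% dm_bh$feature_id),
  dp_sensitivity = mean(tr_dp %in% dp_raw$feature_id),
  chain_sensitivity = mean(truth$chain_protein_ids %in% out$protein_links$chain),
  chain_fdr = mean(!out$protein_links$chain %in% truth$chain_protein_ids),
  dmr_block_detection = mean(block_hit),
  acute_male_only_purity = mean(out$acute$up$male_only %in% truth$acute_male_gene_ids),
  acute_male_only_sensitivity = mean(truth$acute_male_gene_ids %in% out$acute$up$male_only),
  hyper_F_pct_recovered = hypermethylation_summary(dm_bh)$pct_hyper_F,
  chrX_dmr_fraction = out$report$dmr$chrX_fraction)

write_json_artifact(rec, "results/recovery.json")
cat("recovery vs planted truth (results/recovery.json):\n")
for (nm in names(rec)) cat(sprintf("  %-28s %.3f\n", nm, rec[[nm]]))
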