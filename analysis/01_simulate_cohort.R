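#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study cohort.
#
# Emits the full cohort at the default study conditions (16 F / 9 M,
# three timepoints, 2,000 genes, planted sex effects on all three omics
# layers) under results/cohort/, in the same on-disk formats the
# file-mode pipeline consumes, plus the ground truth of every planted
# effect as JSON.

library(sexomics)

seed <- 1
out <- "results/cohort"

sim <- simulate_cohort(sim_config(seed = seed))
write_cohort(sim, out)

cat("cohort written to", out, "\n")
cat(sprintf("  %d samples (%d F / %d M subjects), %d CpGs, %d transcripts, %d proteins\n",
            nrow(sim$sheet),
            length(unique(sim$sheet$subject_id[sim$sheet$sex == "F"])),
            length(unique(sim$sheet$subject_id[sim$sheet$sex == "M"])),
            nrow(sim$methylome$values), nrow(sim$transcriptome$values),
            nrow(sim$proteome$values)))
cat(sprintf("  planted: %d DM CpGs (%.1f%% hyper-F), %d DE transcripts, %d DP proteins, %d DMR blocks\n",
            nrow(sim$truth$dm_cpg), 100 * mean(sim$truth$dm_cpg$direction > 0),
            nrow(sim$truth$de_gene), nrow(sim$truth$dp_protein),
            nrow(sim$truth$dmr_intervals)))
cat(sprintf("  proteome missingness: %.2f%% observed vs %.2f%% expected under the MNAR model\n",
            100 * mean(is.na(sim$proteome$values)),
            100 * sim$truth$expected_missing_rate))
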