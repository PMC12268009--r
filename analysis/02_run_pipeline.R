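#!/usr/bin/env Rscript
# Stage 2 — run the full analysis pipeline on the cohort written by
# stage 1 (file mode), persisting every stage artifact under
# results/pipeline/: per-layer differential tables, the DMR BED, link
# tables, acute and training responses, enrichment tables, and the
# study-shaped report (JSON + markdown digest).

library(sexomics)

cohort <- "results/cohort"
stopifnot(file.exists(file.path(cohort, "sample_sheet.csv")))

cfg <- pipeline_config(
  paths = list(
    sample_sheet = file.path(cohort, "sample_sheet.csv"),
    methylome = file.path(cohort, "methylome_beta.tsv"),
    transcriptome = file.path(cohort, "transcriptome_log2.tsv"),
    proteome = file.path(cohort, "proteome_raw.tsv"),
    cpg_annotation = file.path(cohort, "cpg_annotation.tsv"),
    protein_gene_map = file.path(cohort, "protein_gene_map.tsv"),
    fiber_reference = file.path(cohort, "fiber_reference.tsv"),
    mito_list = file.path(cohort, "mito_list.txt"),
    gene_sets = file.path(cohort, "gene_sets.gmt")),
  seed = 1, dmr_B = 200, out_dir = "results/pipeline")

out <- run_pipeline(cfg)
writeLines(report_digest(out$report))
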