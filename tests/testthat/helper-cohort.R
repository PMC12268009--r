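# Shared fixtures: a small cohort config keeps simulation-driven tests
# fast while preserving the full data structure (three layers, DMR
# blocks, fiber/mito labels).

small_config <- function(seed = 1, ...) {
  sim_config(n_genes = 300, n_proteins = 80, n_intergenic_cpgs = 60,
             n_dmr_blocks = 4, n_mito_proteins = 20,
             n_type1_proteins = 6, n_type2_proteins = 6,
             acute_stress_genes = 15, seed = seed, ...)
}

# tiny deterministic sample sheet for unit tests that do not need a
# simulated cohort
toy_sheet <- function(n_f = 3, n_m = 3, timepoints = "baseline") {
  subj <- sprintf("s%02d", seq_len(n_f + n_m))
  sex <- c(rep("F", n_f), rep("M", n_m))
  age <- seq(25, by = 2, length.out = n_f + n_m)
  do.call(rbind, lapply(timepoints, function(tp)
    data.frame(sample_id = paste(subj, tp, sep = "_"), subject_id = subj,
               sex = sex, age = age, timepoint = tp,
               stringsAsFactors = FALSE)))
}

toy_matrix <- function(values, feature_ids, sample_ids, layer = "transcript_log2") {
  m <- matrix(values, nrow = length(feature_ids),
              dimnames = list(feature_ids, sample_ids))
  omics_matrix(m, layer)
}
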