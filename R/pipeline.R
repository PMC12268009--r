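# End-to-end orchestration: proteome prep -> per-layer differential
# statistics -> DMR detection -> multi-omics linking -> fiber-type /
# mitochondrial scoring and equalization -> acute-response partition ->
# enrichment -> study-shaped report.

#' Pipeline configuration
#'
#' Exactly one of `sim` (a [sim_config()], synthetic mode) or `paths`
#' (named list of input files: `sample_sheet`, `methylome`,
#' `transcriptome`, `proteome`, `cpg_annotation`, `protein_gene_map`,
#' and optionally `fiber_reference`, `mito_list`, `gene_sets`) must be
#' given.
#'
#' @param sim a [sim_config()] or `NULL`.
#' @param paths named list of input paths or `NULL`.
#' @param p_threshold raw-p threshold for the headline sex-difference
#'   sets.
#' @param p_adj_threshold BH threshold for the acute response sets.
#' @param completeness_threshold proteome group-completeness threshold.
#' @param impute imputation spec, see [impute_spec()].
#' @param dmr_maxgap,dmr_cutoff_quantile,dmr_min_cpgs,dmr_B DMR
#'   parameters; `dmr_B = 200` resamplings is the desk-scale default
#'   (detectors run standalone default to 1000).
#' @param ora_min_size minimum gene-set size.
#' @param seed master seed for permutation and imputation streams.
#' @param out_dir if non-NULL, every stage artifact is persisted there.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            p_threshold = 0.05, p_adj_threshold = 0.05,
                            completeness_threshold = 0.90,
                            impute = impute_spec(),
                            dmr_maxgap = 300, dmr_cutoff_quantile = 0.99,
                            dmr_min_cpgs = 2, dmr_B = 200,
                            ora_min_size = 3,
                            seed = 1, out_dir = NULL) {
  if (is.null(sim) == is.null(paths))
    stopf("exactly one of 'sim' (synthetic mode) or 'paths' (file mode) must be given")
  for (nm in c("p_threshold", "p_adj_threshold", "completeness_threshold"))
    if (get(nm) < 0 || get(nm) > 1) stopf("%s must be in [0,1]", nm)
  structure(as.list(environment()), class = "pipeline_config")
}

load_inputs <- function(cfg) {
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    return(simulate_cohort(sim))
  }
  p <- cfg$paths
  list(
    sheet = read_sample_sheet(p$sample_sheet),
    methylome = read_omics_matrix(p$methylome, "methylation_beta"),
    transcriptome = read_omics_matrix(p$transcriptome, "transcript_log2"),
    proteome = read_omics_matrix(p$proteome, "protein_raw"),
    annotation = list(
      cpg = read_cpg_annotation(p$cpg_annotation),
      protein_gene_map = utils::read.delim(p$protein_gene_map, stringsAsFactors = FALSE),
      fiber_reference = if (!is.null(p$fiber_reference)) read_fiber_reference(p$fiber_reference),
      mito_list = if (!is.null(p$mito_list)) readLines(p$mito_list, warn = FALSE),
      gene_sets = if (!is.null(p$gene_sets)) read_gmt(p$gene_sets)),
    truth = NULL)
}

#' Partition acute transcriptional responses by sex
#'
#' Splits the features each sex regulates after acute exercise into
#' shared, female-only and male-only sets, separately for up- and
#' down-regulation.
#'
#' @param female_ids,male_ids regulated feature sets (same universe).
#' @return list: `shared`, `female_only`, `male_only`.
#' @export
acute_response_partition <- function(female_ids, male_ids) {
  list(shared = sort(intersect(female_ids, male_ids)),
       female_only = sort(setdiff(female_ids, male_ids)),
       male_only = sort(setdiff(male_ids, female_ids)))
}

#' Run the full analysis pipeline
#'
#' Sequences every stage on synthetic or file inputs and returns the
#' study-shaped report: per-layer baseline sex-difference counts, the
#' integration summary (linked transcripts/proteins, chain, Venn), the
#' DMR summary with direction-concordant transcript links, the acute
#' response partition, the training responses with mitochondrial
#' annotation, the fiber-type enrichment and equalization tables, and
#' enrichment (ORA) of the headline sets. Deterministic under
#' `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return report list; when `config$out_dir` is set, stage artifacts
#'   (TSV/JSON) are persisted there and the report JSON written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    t0 <<- Sys.time()
  }
  dat <- load_inputs(config)
  sheet <- dat$sheet
  ann <- dat$annotation$cpg
  gene_map <- dat$annotation$protein_gene_map
  tick("load")

  ## proteome preprocessing ------------------------------------------
  config$impute$seed <- child_seed(config$seed, 101)
  prep <- prep_proteome(dat$proteome, sheet,
                        threshold = config$completeness_threshold,
                        spec = config$impute)
  prot <- prep$matrix
  tick("proteome_prep")

  ## baseline sex contrasts ------------------------------------------
  meth_res <- sex_contrast(dat$methylome, sheet, timepoint = "baseline")
  txn_res <- sex_contrast(dat$transcriptome, sheet, timepoint = "baseline")
  prot_res <- sex_contrast(prot, sheet, timepoint = "baseline")
  dm <- significant_features(meth_res, config$p_threshold)
  de <- significant_features(txn_res, config$p_threshold)
  dp <- significant_features(prot_res, config$p_threshold)
  tick("diffstats_baseline")

  ## DMR detection ----------------------------------------------------
  dmrs <- detect_dmrs(dat$methylome, sheet, ann,
                      maxgap = config$dmr_maxgap,
                      cutoff_quantile = config$dmr_cutoff_quantile,
                      min_cpgs = config$dmr_min_cpgs,
                      B = config$dmr_B, seed = child_seed(config$seed, 202))
  sig_dmrs <- dmrs[dmrs$p_value <= 0.05, , drop = FALSE]
  dmr_summary <- if (nrow(sig_dmrs)) summarize_dmrs(sig_dmrs, ann) else
    list(n_dmrs = 0L, chrX_fraction = NA_real_, n_gene_proximal = 0L,
         n_intergenic = 0L, n_genes = 0L)
  dmr_txn <- link_dmrs_to_transcripts(sig_dmrs, de, ann)
  tick("dmr")

  ## multi-omics linking ----------------------------------------------
  links <- directional_link(dm, de, ann)
  plinks <- link_proteins(links, dp, gene_map, de, dm, ann)
  integration <- summarize_overlap(dm, de, dp, links, plinks, ann, gene_map)
  tick("linking")

  ## acute response ----------------------------------------------------
  acute <- NULL
  if (all(c("baseline", "acute") %in% sheet$timepoint)) {
    acute_f <- paired_contrast(dat$transcriptome, sheet, "baseline", "acute", sex = "F")
    acute_m <- paired_contrast(dat$transcriptome, sheet, "baseline", "acute", sex = "M")
    up_f <- acute_f$table$feature_id[!is.na(acute_f$table$p_adj) &
                                       acute_f$table$p_adj < config$p_adj_threshold &
                                       acute_f$table$effect > 0]
    up_m <- acute_m$table$feature_id[!is.na(acute_m$table$p_adj) &
                                       acute_m$table$p_adj < config$p_adj_threshold &
                                       acute_m$table$effect > 0]
    down_f <- acute_f$table$feature_id[!is.na(acute_f$table$p_adj) &
                                         acute_f$table$p_adj < config$p_adj_threshold &
                                         acute_f$table$effect < 0]
    down_m <- acute_m$table$feature_id[!is.na(acute_m$table$p_adj) &
                                         acute_m$table$p_adj < config$p_adj_threshold &
                                         acute_m$table$effect < 0]
    acute <- list(up = acute_response_partition(up_f, up_m),
                  down = acute_response_partition(down_f, down_m),
                  female = acute_f, male = acute_m)
  }
  tick("acute")

  ## training response, fiber type, equalization ----------------------
  training <- NULL
  if (all(c("baseline", "trained") %in% sheet$timepoint)) {
    train_f <- paired_contrast(prot, sheet, "baseline", "trained", sex = "F")
    train_m <- paired_contrast(prot, sheet, "baseline", "trained", sex = "M")
    up_both <- intersect(
      significant_features(train_f, config$p_threshold)$feature_id[
        significant_features(train_f, config$p_threshold)$effect > 0],
      significant_features(train_m, config$p_threshold)$feature_id[
        significant_features(train_m, config$p_threshold)$effect > 0])
    mito <- dat$annotation$mito_list
    mito_stats <- NULL
    if (!is.null(mito) && length(up_both)) {
      flags_up <- annotate_mito(up_both, mito)
      flags_all <- annotate_mito(rownames(prot$values), mito)
      mito_stats <- list(
        n_up_both = length(up_both),
        n_up_mito = attr(flags_up, "n_mito"),
        frac_up_mito = mean(flags_up),
        background_mito_frac = mean(flags_all))
    }
    prot_trained_res <- sex_contrast(prot, sheet, timepoint = "trained")
    dp_trained <- significant_features(prot_trained_res, config$p_threshold)
    fiber <- NULL
    if (!is.null(dat$annotation$fiber_reference)) {
      calls <- classify_fiber_proteins(dat$annotation$fiber_reference, pool_type2 = TRUE)
      enr <- tryCatch(fiber_enrichment_of_diff(dp, calls), error = function(e) NULL)
      fiber_ids <- intersect(calls$protein_id, dp$feature_id)
      equal <- equalization_analysis(fiber_ids,
                                     intersect(calls$protein_id, dp_trained$feature_id),
                                     male_response = train_m, female_response = train_f,
                                     p = config$p_threshold)
      fiber <- list(calls = calls, enrichment = enr, equalization = equal)
    }
    training <- list(female = train_f, male = train_m, up_both = up_both,
                     mito = mito_stats, dp_trained = dp_trained, fiber = fiber)
  }
  tick("training")

  ## enrichment --------------------------------------------------------
  enrichment <- NULL
  if (!is.null(dat$annotation$gene_sets)) {
    universe <- rownames(dat$transcriptome$values)
    enrichment <- list(
      de_baseline = ora(intersect(de$feature_id, universe),
                        dat$annotation$gene_sets, universe,
                        min_size = config$ora_min_size))
    if (!is.null(acute)) {
      enrichment$acute_male_only <- ora(intersect(acute$up$male_only, universe),
                                        dat$annotation$gene_sets, universe,
                                        min_size = config$ora_min_size)
      enrichment$acute_female_only <- ora(intersect(acute$up$female_only, universe),
                                          dat$annotation$gene_sets, universe,
                                          min_size = config$ora_min_size)
    }
  }
  tick("enrichment")

  report <- list(
    seed = config$seed,
    n_samples = nrow(sheet),
    n_female = length(unique(sheet$subject_id[sheet$sex == "F"])),
    n_male = length(unique(sheet$subject_id[sheet$sex == "M"])),
    proteome_prep = prep$report,
    diff_counts = list(
      dm_cpgs = nrow(dm), de_transcripts = nrow(de), dp_proteins = nrow(dp)),
    ebayes = list(
      d0_methylome = meth_res$params$d0, d0_transcriptome = txn_res$params$d0,
      d0_proteome = prot_res$params$d0),
    integration = integration,
    dmr = c(dmr_summary[c("n_dmrs", "chrX_fraction", "n_gene_proximal",
                          "n_intergenic", "n_genes")],
            list(n_detected_total = nrow(dmrs),
                 n_txn_links = nrow(dmr_txn),
                 n_txn_concordant = sum(dmr_txn$concordant))),
    acute = if (!is.null(acute)) list(
      n_shared_up = length(acute$up$shared),
      n_female_only_up = length(acute$up$female_only),
      n_male_only_up = length(acute$up$male_only),
      female_only_up = acute$up$female_only,
      male_only_up = acute$up$male_only),
    training = if (!is.null(training)) list(
      n_up_both = length(training$up_both),
      mito = training$mito,
      n_equalized = if (!is.null(training$fiber)) sum(training$fiber$equalization$equalized),
      n_baseline_fiber_diff = if (!is.null(training$fiber)) nrow(training$fiber$equalization),
      fiber_or = if (!is.null(training$fiber) && !is.null(training$fiber$enrichment))
        training$fiber$enrichment$odds_ratio,
      fiber_p = if (!is.null(training$fiber) && !is.null(training$fiber$enrichment))
        training$fiber$enrichment$p),
    timings = timings)

  out <- list(report = report, data = dat, proteome_prepped = prot,
              results = list(methylome = meth_res, transcriptome = txn_res,
                             proteome = prot_res),
              sig = list(dm = dm, de = de, dp = dp),
              dmrs = dmrs, dmr_txn_links = dmr_txn, links = links,
              protein_links = plinks, acute = acute, training = training,
              enrichment = enrichment)

  if (!is.null(config$out_dir)) persist_pipeline(out, config$out_dir)
  out
}

persist_pipeline <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wtsv(out$results$methylome$table, "diff_methylome_sex.tsv")
  wtsv(out$results$transcriptome$table, "diff_transcriptome_sex.tsv")
  wtsv(out$results$proteome$table, "diff_proteome_sex.tsv")
  if (nrow(out$dmrs)) write_dmr_bed(out$dmrs, file.path(dir, "dmrs.bed.tsv"))
  wtsv(out$links, "cpg_transcript_links.tsv")
  if (!is.null(out$acute)) {
    wtsv(out$acute$female$table, "acute_response_female.tsv")
    wtsv(out$acute$male$table, "acute_response_male.tsv")
  }
  if (!is.null(out$training) && !is.null(out$training$fiber))
    wtsv(out$training$fiber$equalization, "equalization.tsv")
  if (!is.null(out$enrichment))
    for (nm in names(out$enrichment))
      wtsv(out$enrichment[[nm]][, setdiff(names(out$enrichment[[nm]]), "members")],
           sprintf("ora_%s.tsv", nm))
  write_json_artifact(out$report, file.path(dir, "report.json"))
  writeLines(report_digest(out$report), file.path(dir, "report.md"))
  invisible(dir)
}

#' Human-readable digest of a pipeline report
#' @param report the `report` element of a [run_pipeline()] result.
#' @return character vector of markdown lines.
#' @export
report_digest <- function(report) {
  c("# Sex-difference multi-omics report",
    "",
    sprintf("Cohort: %d female / %d male subjects, %d samples.",
            report$n_female, report$n_male, report$n_samples),
    sprintf("Proteome prep: %d/%d proteins kept; %d cells (%.2f%%) imputed.",
            report$proteome_prep$n_features_kept, report$proteome_prep$n_features_in,
            report$proteome_prep$n_imputed, 100 * report$proteome_prep$frac_imputed),
    "",
    "## Baseline sex differences",
    sprintf("- %d DM CpGs (%.1f%% hypermethylated in females)",
            report$diff_counts$dm_cpgs, report$integration$pct_hyper_F),
    sprintf("- %d DE transcripts, %d (%.1f%%) linked to methylation",
            report$diff_counts$de_transcripts, report$integration$n_linked_transcripts,
            report$integration$pct_linked_transcripts),
    sprintf("- %d DP proteins, %d (%.1f%%) methylation-linked, %d in the full chain",
            report$diff_counts$dp_proteins, report$integration$n_linked_proteins,
            report$integration$pct_linked_proteins, report$integration$n_chain_proteins),
    sprintf("- %d DMRs (chrX fraction %.2f; %d gene-proximal, %d intergenic)",
            report$dmr$n_dmrs, report$dmr$chrX_fraction %||% NA,
            report$dmr$n_gene_proximal, report$dmr$n_intergenic),
    "",
    if (!is.null(report$acute)) c(
      "## Acute response (upregulated transcripts)",
      sprintf("- shared: %d, female-only: %d, male-only: %d",
              report$acute$n_shared_up, report$acute$n_female_only_up,
              report$acute$n_male_only_up), "") else NULL,
    if (!is.null(report$training)) c(
      "## Training response",
      sprintf("- %d proteins up in both sexes", report$training$n_up_both),
      if (!is.null(report$training$n_equalized))
        sprintf("- equalization: %d of %d baseline fiber-type differences resolved",
                report$training$n_equalized, report$training$n_baseline_fiber_diff)
      else NULL) else NULL)
}
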