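# Synthetic cohort generator.
#
# Emulates the statistical structure of a two-sex endurance-training
# multi-omics study: a female-majority cohort sampled at baseline, after
# one acute exercise bout, and after eight weeks of training; a baseline
# CpG methylome with bimodal beta values and predominantly female-
# hypermethylated differential sites concentrated in clustered blocks on
# chrX; a transcriptome whose sex-differential genes are directionally
# coupled to methylation by the promoter/gene-body rule; a proteome
# coupled to the transcriptome with intensity-dependent (MNAR)
# missingness, a male fast-fiber protein excess that training shrinks,
# and a mitochondrial training response shared by both sexes.

#' Configuration of the synthetic cohort
#'
#' Default values are the study conditions the generator emulates:
#' 16 females and 9 males, ages ~28 +/- 9 (F) vs 33 +/- 6 (M) years, three
#' timepoints, 84% of planted differentially methylated CpGs
#' hypermethylated in females, 88% of DMR blocks on chrX, a male-only
#' acute stress-transcript induction, and a training effect that
#' up-regulates mitochondrial proteins in both sexes while removing most
#' of the male fast-fiber protein excess.
#'
#' @param n_female,n_male subjects per sex.
#' @param n_timepoints number of timepoints (3: baseline/acute/trained).
#' @param n_genes number of genes (transcripts).
#' @param cpgs_per_gene_promoter,cpgs_per_gene_body CpGs annotated to each
#'   gene's promoter / gene body.
#' @param n_intergenic_cpgs isolated intergenic CpGs.
#' @param frac_de_transcripts fraction of genes planted sex-differential.
#' @param frac_dm_cpgs fraction of CpGs planted sex-differential
#'   (excluding DMR-block CpGs, which are differential by construction).
#' @param frac_female_hyper probability that a planted differential CpG is
#'   hypermethylated in females.
#' @param frac_coupled fraction of (non-DMR) DE genes whose expression
#'   direction is coupled to planted CpG methylation via the
#'   promoter/gene-body rule.
#' @param delta_beta planted methylation effect, beta units.
#' @param lfc_sex planted sex log2 fold change for DE transcripts.
#' @param protein_coupling slope linking the protein sex effect to the
#'   transcript sex effect for proteins of DE genes.
#' @param mnar_tau,mnar_scale logistic missingness parameters:
#'   P(missing | x) = plogis((mnar_tau - x)/mnar_scale) on log2 abundance.
#' @param n_dmr_blocks,dmr_block_len planted DMR blocks and CpGs per block.
#' @param frac_dmr_on_chrX fraction of DMR blocks placed on chrX.
#' @param acute_stress_genes transcripts induced after acute exercise in
#'   males only.
#' @param acute_lfc log2 magnitude of the male-only acute induction.
#' @param training_mito_lfc log2 up-regulation of mitochondrial proteins
#'   after training, both sexes.
#' @param n_proteins proteins quantified (mapped 1:1 to the first
#'   `n_proteins` genes).
#' @param n_mito_proteins proteins carrying the mitochondrial label and the
#'   training response.
#' @param n_type1_proteins,n_type2_proteins fiber-type-specific proteins
#'   (slow type 1: female-higher; fast type 2: male-higher at baseline).
#' @param fiber_sex_lfc baseline log2 sex effect of fiber-type proteins.
#' @param equalize_frac fraction of type 2 proteins whose male excess is
#'   removed after training (equalization).
#' @param subject_sd SD of the subject-level random intercept (log2 units;
#'   induces within-subject correlation so paired contrasts differ from
#'   unpaired ones).
#' @param resid_sd_txn,resid_sd_prot residual SDs, log2 units.
#' @param meth_noise_sd methylation noise SD on the logit scale
#'   (~0.03 beta units at mid-range).
#' @param age_beta_txn per-year age slope on transcripts (log2 units);
#'   with the sexes' age distributions differing, age acts as a mild
#'   confounder that the age covariate must absorb.
#' @param protein_mean,protein_sd log2 abundance location/spread across
#'   proteins.
#' @param seed RNG seed; identical seed + config gives bit-identical
#'   output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_female = 16, n_male = 9, n_timepoints = 3,
                       n_genes = 2000,
                       cpgs_per_gene_promoter = 2, cpgs_per_gene_body = 2,
                       n_intergenic_cpgs = 2500,
                       frac_de_transcripts = 0.10, frac_dm_cpgs = 0.10,
                       frac_female_hyper = 0.84, frac_coupled = 0.60,
                       delta_beta = 0.20, lfc_sex = 1.0,
                       protein_coupling = 0.85,
                       mnar_tau = 14, mnar_scale = 1.0,
                       n_dmr_blocks = 12, dmr_block_len = 8,
                       frac_dmr_on_chrX = 0.88,
                       acute_stress_genes = 60, acute_lfc = 1.5,
                       training_mito_lfc = 0.75,
                       n_proteins = 600, n_mito_proteins = 120,
                       n_type1_proteins = 15, n_type2_proteins = 15,
                       fiber_sex_lfc = 1.2, equalize_frac = 0.8,
                       subject_sd = 0.3, resid_sd_txn = 0.4,
                       resid_sd_prot = 0.5, meth_noise_sd = 0.12,
                       age_beta_txn = 0.02,
                       protein_mean = 20, protein_sd = 2,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  num <- vapply(cfg, is.numeric, TRUE)
  if (!all(num)) stopf("non-numeric config field(s): %s", paste(names(cfg)[!num], collapse = ", "))
  if (any(!vapply(cfg, function(x) all(is.finite(x)), TRUE)))
    stopf("non-finite config value(s)")
  fracs <- c("frac_de_transcripts", "frac_dm_cpgs", "frac_female_hyper",
             "frac_coupled", "frac_dmr_on_chrX", "equalize_frac")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("%s must be in [0,1], got %g", f, cfg[[f]])
  counts <- c("n_female", "n_male", "n_timepoints", "n_genes",
              "cpgs_per_gene_promoter", "cpgs_per_gene_body")
  for (f in counts)
    if (cfg[[f]] < 1) stopf("%s must be a positive count, got %g", f, cfg[[f]])
  if (cfg$delta_beta <= 0 || cfg$delta_beta >= 1)
    stopf("delta_beta must be in (0,1), got %g", cfg$delta_beta)
  if (cfg$n_female + cfg$n_male < 4)
    stopf("n_female + n_male must be >= 4 for a design with an age covariate")
  if (cfg$n_proteins > cfg$n_genes) stopf("n_proteins cannot exceed n_genes")
  invisible(cfg)
}

# Gene layout: a deterministic block of chrX genes first (enough to host
# the chrX DMR blocks), one or two chrY genes, the rest cycled over the
# autosomes. Genes occupy consecutive 100 kb windows per chromosome.
gene_layout <- function(cfg) {
  n <- cfg$n_genes
  n_x_needed <- ceiling(cfg$n_dmr_blocks * cfg$frac_dmr_on_chrX)
  n_x <- max(ceiling(0.05 * n), n_x_needed + 2)
  n_y <- max(1, round(0.005 * n))
  if (n_x + n_y >= n) stopf("n_genes too small for the chromosome layout")
  chrom <- c(rep("chrX", n_x), rep("chrY", n_y),
             paste0("chr", rep_len(1:22, n - n_x - n_y)))
  gene <- sprintf("gene_%05d", seq_len(n))
  slot <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  data.frame(gene = gene, chrom = chrom, slot = slot,
             start = (slot - 1) * 100000 + 1, stringsAsFactors = FALSE)
}

build_annotation <- function(cfg, genes) {
  npro <- cfg$cpgs_per_gene_promoter
  nbod <- cfg$cpgs_per_gene_body
  per_gene <- npro + nbod
  n <- nrow(genes)
  gidx <- rep(seq_len(n), each = per_gene)
  within <- rep(seq_len(per_gene), times = n)
  ctx <- rep(c(rep("promoter", npro), rep("gene_body", nbod)), times = n)
  # promoter CpGs near the gene start, body CpGs 2 kb in; 150 bp spacing
  offset <- ifelse(ctx == "promoter", (within - 1) * 150,
                   2000 + (within - npro - 1) * 150)
  ann <- data.frame(
    cpg_id = sprintf("cpg_%s_%s%d", genes$gene[gidx], substr(ctx, 1, 1), within),
    chrom = genes$chrom[gidx],
    pos = genes$start[gidx] + offset,
    gene = genes$gene[gidx],
    context = ctx, stringsAsFactors = FALSE)
  # isolated intergenic CpGs: 10 kb apart at the top of chr1 coordinates
  if (cfg$n_intergenic_cpgs > 0) {
    ig <- data.frame(
      cpg_id = sprintf("cpg_ig_%05d", seq_len(cfg$n_intergenic_cpgs)),
      chrom = "chr1",
      pos = 5e8 + (seq_len(cfg$n_intergenic_cpgs) - 1) * 10000,
      gene = "", context = "intergenic", stringsAsFactors = FALSE)
    ann <- rbind(ann, ig)
  }
  ann
}

#' Simulate a complete synthetic cohort
#'
#' Generates the sample sheet, the three omics layers, their annotation
#' tables and the exact ground truth of every planted effect. Beta values
#' are drawn from a bimodal Beta mixture with sex effects added on the
#' logit scale and clipped to `[0.001, 0.999]`; transcript and protein
#' layers are Gaussian on the log2 scale with subject random intercepts;
#' proteome missingness follows `P(missing | x) = plogis((tau - x)/scale)`.
#' The methylome covers baseline samples only (methylation is assayed once,
#' before training); transcriptome and proteome cover all timepoints.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `sheet` (sample sheet), `methylome`,
#'   `transcriptome`, `proteome` (`omics_matrix`; proteome on the raw
#'   abundance scale with `NA` for missing), `annotation` (list:
#'   `cpg` CpG table, `gene` gene table, `protein_gene_map`,
#'   `fiber_reference`, `mito_list`, `gene_sets`), and `truth` (planted
#'   ground truth; see Details).
#' @details `truth` contains `dm_cpg` (cpg_id + direction, +1 = female-
#'   hyper), `de_gene` (gene + signed log2 effect), `coupled_gene`
#'   (gene + coupling context), `dp_protein`, `dmr_intervals`,
#'   `acute_male_gene_ids`, `training_protein_ids`, and the expected
#'   missingness rate of the proteome under the logistic MNAR model.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)

  ## ---- design -------------------------------------------------------
  n_subj <- cfg$n_female + cfg$n_male
  subject_id <- sprintf("subj_%02d", seq_len(n_subj))
  sex <- c(rep("F", cfg$n_female), rep("M", cfg$n_male))
  age <- numeric(n_subj)
  for (i in seq_len(n_subj)) {
    mu <- if (sex[i] == "F") 27.9 else 33.2
    sdv <- if (sex[i] == "F") 8.79 else 5.59
    a <- -1
    while (a < 18) a <- stats::rnorm(1, mu, sdv)
    age[i] <- round(a, 1)
  }
  tps <- VALID_TIMEPOINTS[seq_len(cfg$n_timepoints)]
  sheet <- data.frame(
    sample_id = as.vector(outer(subject_id, tps, paste, sep = "_")),
    subject_id = rep(subject_id, times = length(tps)),
    sex = rep(sex, times = length(tps)),
    age = rep(age, times = length(tps)),
    timepoint = rep(tps, each = n_subj), stringsAsFactors = FALSE)
  sheet <- sheet[order(sheet$subject_id, match(sheet$timepoint, tps)), ]
  rownames(sheet) <- NULL
  validate_sample_sheet(sheet)

  ## ---- gene/CpG layout ---------------------------------------------
  genes <- gene_layout(cfg)
  ann <- build_annotation(cfg, genes)

  ## ---- planted DMR blocks ------------------------------------------
  n_blocks <- cfg$n_dmr_blocks
  dmr_cpgs <- NULL
  block_gene <- character(0)
  block_dir <- integer(0)
  if (n_blocks > 0) {
    n_x_blocks <- round(cfg$frac_dmr_on_chrX * n_blocks)
    x_genes <- genes$gene[genes$chrom == "chrX"]
    a_genes <- genes$gene[!genes$chrom %in% c("chrX", "chrY")]
    block_gene <- c(sample(x_genes, n_x_blocks),
                    sample(a_genes, n_blocks - n_x_blocks))
    block_dir <- ifelse(stats::runif(n_blocks) < cfg$frac_female_hyper, 1L, -1L)
    gi <- match(block_gene, genes$gene)
    # block CpGs sit in the promoter region, 50 bp apart (always < maxgap)
    dmr_cpgs <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      data.frame(
        cpg_id = sprintf("cpg_dmr%02d_%d", b, seq_len(cfg$dmr_block_len)),
        chrom = genes$chrom[gi[b]],
        pos = genes$start[gi[b]] + 500 + (seq_len(cfg$dmr_block_len) - 1) * 50,
        gene = block_gene[b], context = "promoter",
        stringsAsFactors = FALSE)
    }))
    ann <- rbind(ann, dmr_cpgs)
  }
  ann <- ann[order(ann$chrom, ann$pos), ]
  rownames(ann) <- NULL

  ## ---- choose DE genes and couplings -------------------------------
  n_de <- round(cfg$frac_de_transcripts * cfg$n_genes)
  de_gene <- character(0); de_lfc <- numeric(0)
  coupled <- data.frame(gene = character(0), context = character(0),
                        meth_dir = integer(0), stringsAsFactors = FALSE)
  dm_ids <- character(0); dm_dir <- integer(0)

  if (n_blocks > 0) {
    # DMR-block genes are DE with direction implied by the promoter rule
    de_gene <- block_gene
    de_lfc <- -block_dir * cfg$lfc_sex
    coupled <- data.frame(gene = block_gene, context = "promoter",
                          meth_dir = block_dir, stringsAsFactors = FALSE)
    dm_ids <- dmr_cpgs$cpg_id
    dm_dir <- rep(block_dir, each = cfg$dmr_block_len)
  }
  n_de_rest <- max(0, n_de - length(de_gene))
  pool <- setdiff(genes$gene, de_gene)
  de_rest <- if (n_de_rest > 0) sample(pool, n_de_rest) else character(0)
  n_coup <- round(cfg$frac_coupled * n_de_rest)
  if (n_coup > 0) {
    cg <- de_rest[seq_len(n_coup)]
    ctx <- sample(c("promoter", "gene_body"), n_coup, replace = TRUE)
    mdir <- ifelse(stats::runif(n_coup) < cfg$frac_female_hyper, 1L, -1L)
    # promoter methylation silences (opposite direction), gene-body
    # methylation tracks active transcription (same direction)
    lfc_dir <- ifelse(ctx == "promoter", -mdir, mdir)
    de_gene <- c(de_gene, cg)
    de_lfc <- c(de_lfc, lfc_dir * cfg$lfc_sex)
    coupled <- rbind(coupled, data.frame(gene = cg, context = ctx,
                                         meth_dir = mdir, stringsAsFactors = FALSE))
    for (i in seq_len(n_coup)) {
      sel <- ann$gene == cg[i] & ann$context == ctx[i] &
        !startsWith(ann$cpg_id, "cpg_dmr")
      dm_ids <- c(dm_ids, ann$cpg_id[sel])
      dm_dir <- c(dm_dir, rep(mdir[i], sum(sel)))
    }
  }
  if (n_de_rest > n_coup) {
    fg <- de_rest[(n_coup + 1):n_de_rest]
    de_gene <- c(de_gene, fg)
    de_lfc <- c(de_lfc, sample(c(-1, 1), length(fg), replace = TRUE) * cfg$lfc_sex)
  }

  # free (uncoupled) DM CpGs at the configured rate, outside planted ones
  n_dm_free <- round(cfg$frac_dm_cpgs *
                       (nrow(ann) - if (n_blocks > 0) nrow(dmr_cpgs) else 0)) -
    length(dm_ids)
  if (n_dm_free > 0) {
    free_pool <- setdiff(ann$cpg_id, dm_ids)
    free_pool <- free_pool[!startsWith(free_pool, "cpg_dmr")]
    n_dm_free <- min(n_dm_free, length(free_pool))
    fids <- sample(free_pool, n_dm_free)
    dm_ids <- c(dm_ids, fids)
    dm_dir <- c(dm_dir, ifelse(stats::runif(n_dm_free) < cfg$frac_female_hyper, 1L, -1L))
  }

  ## ---- methylome (baseline samples only) ----------------------------
  base_sheet <- sheet[sheet$timepoint == "baseline", ]
  n_cpg <- nrow(ann)
  # bimodal baseline: promoters low, gene bodies high, intergenic mixed
  shape <- ifelse(ann$context == "promoter", 1L, ifelse(ann$context == "gene_body", 2L, 3L))
  base_beta <- numeric(n_cpg)
  base_beta[shape == 1] <- stats::rbeta(sum(shape == 1), 2, 8)
  base_beta[shape == 2] <- stats::rbeta(sum(shape == 2), 8, 2)
  base_beta[shape == 3] <- stats::rbeta(sum(shape == 3),
                                        sample(c(2, 8), sum(shape == 3), TRUE), 5)
  base_beta <- clip01(base_beta, 0.02, 0.98)
  # DMR-block CpGs sit at intermediate methylation (X-inactivation-like
  # regions), so the planted block effect fits either direction unclipped
  blk <- startsWith(ann$cpg_id, "cpg_dmr")
  base_beta[blk] <- stats::runif(sum(blk), 0.35, 0.65)
  eff_logit <- numeric(n_cpg)
  mi <- match(dm_ids, ann$cpg_id)
  # DMR-block CpGs carry the full coherent effect; isolated differential
  # CpGs draw heterogeneous magnitudes (a quarter to the full delta), as
  # array-wide single-site effects are mostly smaller than block effects
  is_block <- startsWith(dm_ids, "cpg_dmr")
  dm_delta <- numeric(length(dm_ids))
  dm_delta[is_block] <- cfg$delta_beta
  dm_delta[!is_block] <- stats::runif(sum(!is_block), 0.25, 0.9) * cfg$delta_beta
  # female-side effect on the logit scale equivalent to the beta shift
  eff_logit[mi] <- logit(clip01(base_beta[mi] + dm_dir * dm_delta)) -
    logit(base_beta[mi])
  sexF_b <- as.numeric(base_sheet$sex == "F")
  mu_logit <- logit(base_beta)
  meth <- matrix(0, n_cpg, nrow(base_sheet),
                 dimnames = list(ann$cpg_id, base_sheet$sample_id))
  for (j in seq_len(ncol(meth))) {
    meth[, j] <- clip01(inv_logit(mu_logit + sexF_b[j] * eff_logit +
                                    stats::rnorm(n_cpg, 0, cfg$meth_noise_sd)))
  }

  ## ---- transcriptome ------------------------------------------------
  n_smp <- nrow(sheet)
  sexF <- as.numeric(sheet$sex == "F")
  acute <- as.numeric(sheet$timepoint == "acute")
  subj_i <- match(sheet$subject_id, subject_id)
  g_mean <- stats::rnorm(cfg$n_genes, 8, 1.5)
  lfc <- numeric(cfg$n_genes); lfc[match(de_gene, genes$gene)] <- de_lfc
  age_slope <- rep(cfg$age_beta_txn, cfg$n_genes)
  n_acute <- min(cfg$acute_stress_genes, cfg$n_genes - n_de)
  acute_genes <- if (n_acute > 0) sample(setdiff(genes$gene, de_gene), n_acute) else character(0)
  acute_eff <- numeric(cfg$n_genes)
  acute_eff[match(acute_genes, genes$gene)] <- cfg$acute_lfc
  subj_int_t <- matrix(stats::rnorm(cfg$n_genes * n_subj, 0, cfg$subject_sd),
                       cfg$n_genes, n_subj)
  isM <- as.numeric(sheet$sex == "M")
  txn <- g_mean + subj_int_t[, subj_i, drop = FALSE]
  txn <- txn + outer(lfc, sexF) + outer(age_slope, sheet$age - mean(age))
  txn <- txn + outer(acute_eff, acute * isM)   # male-only acute induction
  txn <- txn + matrix(stats::rnorm(cfg$n_genes * n_smp, 0, cfg$resid_sd_txn),
                      cfg$n_genes, n_smp)
  dimnames(txn) <- list(genes$gene, sheet$sample_id)

  ## ---- proteome -----------------------------------------------------
  prot_gene <- genes$gene[seq_len(cfg$n_proteins)]
  protein_id <- paste0("prot_", prot_gene)
  # fiber-type and mito labels among proteins of non-DE genes
  non_de_prot <- which(!prot_gene %in% de_gene)
  n_t1 <- min(cfg$n_type1_proteins, length(non_de_prot))
  t1_idx <- non_de_prot[seq_len(n_t1)]
  rest <- setdiff(non_de_prot, t1_idx)
  n_t2 <- min(cfg$n_type2_proteins, length(rest))
  t2_idx <- rest[seq_len(n_t2)]
  rest <- setdiff(rest, t2_idx)
  n_mito <- min(cfg$n_mito_proteins, length(rest))
  mito_idx <- rest[seq_len(n_mito)]

  p_lfc <- numeric(cfg$n_proteins)
  cp <- match(prot_gene, genes$gene)
  p_lfc <- cfg$protein_coupling * lfc[cp]          # coupled to transcript effect
  p_lfc[t1_idx] <- cfg$fiber_sex_lfc               # slow fibers: higher in F
  p_lfc[t2_idx] <- -cfg$fiber_sex_lfc              # fast fibers: higher in M
  trained <- as.numeric(sheet$timepoint == "trained")
  train_eff <- numeric(cfg$n_proteins)
  train_eff[mito_idx] <- cfg$training_mito_lfc
  # equalization: endurance training pulls male fiber-type profiles
  # toward female ones — the male fast-fiber (type 2) excess comes down
  # and the male slow-fiber (type 1) deficit fills up
  eq2_idx <- t2_idx[seq_len(round(cfg$equalize_frac * n_t2))]
  eq1_idx <- t1_idx[seq_len(round(cfg$equalize_frac * n_t1))]
  eq_idx <- c(eq2_idx, eq1_idx)
  equalize_eff <- numeric(cfg$n_proteins)
  equalize_eff[eq2_idx] <- cfg$fiber_sex_lfc       # male trained: down
  equalize_eff[eq1_idx] <- -cfg$fiber_sex_lfc      # male trained: up

  p_mean <- stats::rnorm(cfg$n_proteins, cfg$protein_mean, cfg$protein_sd)
  subj_int_p <- matrix(stats::rnorm(cfg$n_proteins * n_subj, 0, cfg$subject_sd),
                       cfg$n_proteins, n_subj)
  prot <- p_mean + subj_int_p[, subj_i, drop = FALSE]
  prot <- prot + outer(p_lfc, sexF) + outer(train_eff, trained)
  prot <- prot - outer(equalize_eff, trained * isM)
  prot <- prot + matrix(stats::rnorm(cfg$n_proteins * n_smp, 0, cfg$resid_sd_prot),
                        cfg$n_proteins, n_smp)
  dimnames(prot) <- list(protein_id, sheet$sample_id)
  # MNAR missingness on log2 abundance
  p_miss <- stats::plogis((cfg$mnar_tau - prot) / cfg$mnar_scale)
  miss <- matrix(stats::runif(length(prot)), nrow(prot)) < p_miss
  prot_raw <- 2^prot
  prot_raw[miss] <- NA_real_

  ## ---- reference tables --------------------------------------------
  fiber_ref <- NULL
  if (n_t1 + n_t2 > 0) {
    fiber_profile <- function(ids, dominant_is_type1) {
      n <- length(ids)
      major <- stats::runif(n, 60, 80)
      split2a <- stats::runif(n, 0.3, 0.7)
      p1 <- round(if (dominant_is_type1) major else 100 - major, 1)
      p2a <- round((100 - p1) * split2a, 1)
      data.frame(protein_id = ids, pct_type1 = p1, pct_type2a = p2a,
                 pct_type2x = round(100 - p1 - p2a, 1),
                 stringsAsFactors = FALSE)
    }
    fiber_ref <- rbind(fiber_profile(protein_id[t1_idx], TRUE),
                       fiber_profile(protein_id[t2_idx], FALSE))
    validate_fiber_reference(fiber_ref)
  }
  mito_list <- protein_id[mito_idx]

  gene_sets <- list(
    mito_genes = prot_gene[mito_idx],
    fast_fiber = prot_gene[t2_idx],
    slow_fiber = prot_gene[t1_idx],
    acute_stress = acute_genes)
  gene_sets <- gene_sets[vapply(gene_sets, length, 1L) >= 3]
  # random background sets over the gene universe
  for (k in seq_len(5)) {
    gene_sets[[sprintf("random_set_%d", k)]] <-
      sample(genes$gene, min(50, cfg$n_genes))
  }

  ## ---- truth --------------------------------------------------------
  dp_protein <- protein_id[p_lfc != 0]
  chain_prot <- protein_id[prot_gene %in% coupled$gene & p_lfc != 0]
  dmr_intervals <- NULL
  if (n_blocks > 0) {
    gi <- match(block_gene, genes$gene)
    dmr_intervals <- data.frame(
      block = seq_len(n_blocks),
      chrom = genes$chrom[gi],
      start = genes$start[gi] + 500,
      end = genes$start[gi] + 500 + (cfg$dmr_block_len - 1) * 50,
      gene = block_gene, direction = block_dir, stringsAsFactors = FALSE)
  }
  truth <- list(
    dm_cpg = data.frame(cpg_id = dm_ids, direction = dm_dir, stringsAsFactors = FALSE),
    de_gene = data.frame(gene = de_gene, lfc = de_lfc, stringsAsFactors = FALSE),
    coupled_gene = coupled,
    dp_protein = data.frame(protein_id = dp_protein,
                            lfc = p_lfc[match(dp_protein, protein_id)],
                            stringsAsFactors = FALSE),
    chain_protein_ids = chain_prot,
    dmr_intervals = dmr_intervals,
    acute_male_gene_ids = acute_genes,
    training_protein_ids = if (cfg$training_mito_lfc != 0) protein_id[mito_idx] else character(0),
    equalized_protein_ids = protein_id[eq_idx],
    type1_protein_ids = if (cfg$fiber_sex_lfc != 0) protein_id[t1_idx] else character(0),
    type2_protein_ids = if (cfg$fiber_sex_lfc != 0) protein_id[t2_idx] else character(0),
    expected_missing_rate = mean(p_miss))

  list(
    sheet = sheet,
    methylome = omics_matrix(meth, "methylation_beta"),
    transcriptome = omics_matrix(txn, "transcript_log2"),
    proteome = omics_matrix(prot_raw, "protein_raw"),
    annotation = list(
      cpg = ann,
      gene = genes[, c("gene", "chrom")],
      protein_gene_map = data.frame(protein_id = protein_id, gene = prot_gene,
                                    stringsAsFactors = FALSE),
      fiber_reference = fiber_ref,
      mito_list = mito_list,
      gene_sets = gene_sets),
    truth = truth,
    config = cfg)
}

#' Simulate a null cohort (no planted effects)
#'
#' Same machinery as [simulate_cohort()] with every effect fraction and
#' planted magnitude forced to zero: no differential CpGs, transcripts or
#' proteins, no DMR blocks, no acute or training response, no fiber-type
#' sex effects. Used to calibrate type-I error and DMR family-wise rates.
#'
#' @param cfg a [sim_config()]; effect fields are overridden to zero.
#' @return as [simulate_cohort()], with empty truth id lists.
#' @export
simulate_null_cohort <- function(cfg = sim_config()) {
  cfg$frac_de_transcripts <- 0
  cfg$frac_dm_cpgs <- 0
  cfg$frac_coupled <- 0
  cfg$n_dmr_blocks <- 0
  cfg$acute_stress_genes <- 0
  cfg$training_mito_lfc <- 0
  cfg$fiber_sex_lfc <- 0
  cfg$equalize_frac <- 0
  simulate_cohort(cfg)
}

#' Write a simulated cohort to disk
#'
#' Persists every artifact through the package readers' formats: CSV
#' sample sheet, TSV matrices, TSV CpG annotation, GMT gene sets, JSON
#' ground truth.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sample_sheet(sim$sheet, file.path(dir, "sample_sheet.csv"))
  write_omics_matrix(sim$methylome, file.path(dir, "methylome_beta.tsv"))
  write_omics_matrix(sim$transcriptome, file.path(dir, "transcriptome_log2.tsv"))
  write_omics_matrix(sim$proteome, file.path(dir, "proteome_raw.tsv"))
  write_cpg_annotation(sim$annotation$cpg, file.path(dir, "cpg_annotation.tsv"))
  utils::write.table(sim$annotation$protein_gene_map,
                     file.path(dir, "protein_gene_map.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(sim$annotation$fiber_reference))
    write_fiber_reference(sim$annotation$fiber_reference,
                          file.path(dir, "fiber_reference.tsv"))
  writeLines(sim$annotation$mito_list, file.path(dir, "mito_list.txt"))
  write_gmt(sim$annotation$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_json_artifact(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
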