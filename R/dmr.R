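# Bump-hunting detection of differentially methylated regions (DMRs)
# from per-CpG sex effects, with a sex-label permutation null.
#
# Pipeline per dataset (observed or permuted): per-CpG sex coefficient
# from the linear model (intercept + sexF + age) -> running-mean
# smoothing (window 3) within clusters of nearby CpGs -> candidate bumps
# as maximal same-sign runs of smoothed effect exceeding a quantile
# cutoff with at least min_cpgs members -> area statistic (sum of
# absolute smoothed effects). The null statistic is the maximum candidate
# area of each permutation, giving family-wise p-values in [1/(B+1), 1].

#' Cluster CpGs by genomic proximity
#'
#' Consecutive CpGs on the same chromosome separated by at most `maxgap`
#' bp share a cluster; clusters never span chromosomes. Unsorted input is
#' sorted internally.
#'
#' @param ann CpG annotation table (`cpg_id`, `chrom`, `pos`, ...).
#' @param maxgap maximum gap in bp.
#' @return integer cluster ids aligned with the input row order.
#' @export
cluster_cpgs <- function(ann, maxgap = 300) {
  ord <- order(ann$chrom, ann$pos)
  chrom <- ann$chrom[ord]
  pos <- ann$pos[ord]
  n <- length(pos)
  new_cluster <- c(TRUE, chrom[-1] != chrom[-n] | (pos[-1] - pos[-n]) > maxgap)
  cl_sorted <- cumsum(new_cluster)
  cl <- integer(n)
  cl[ord] <- cl_sorted
  cl
}

# Precompute running-mean window bounds (window 3, truncated at cluster
# edges; clusters smaller than 3 CpGs are left unsmoothed) for CpGs
# sorted by (chrom, pos). Returns lo/hi indices into the sorted order.
smoother_layout <- function(cluster_sorted) {
  n <- length(cluster_sorted)
  idx <- seq_len(n)
  start <- stats::ave(idx, cluster_sorted, FUN = min)
  end <- stats::ave(idx, cluster_sorted, FUN = max)
  size <- end - start + 1
  lo <- pmax(idx - 1, start)
  hi <- pmin(idx + 1, end)
  small <- size < 3
  lo[small] <- idx[small]
  hi[small] <- idx[small]
  list(lo = lo, hi = hi)
}

smooth_effects <- function(eff, layout) {
  cs <- cumsum(eff)
  (cs[layout$hi] - c(0, cs)[layout$lo]) / (layout$hi - layout$lo + 1)
}

# Extract candidate bumps from smoothed effects (already sorted by
# chrom, pos). Returns a data.frame of runs with their area.
extract_bumps <- function(sm, cluster_sorted, cutoff, min_cpgs) {
  qual <- abs(sm) >= cutoff & sm != 0
  sgn <- sign(sm)
  run_key <- cumsum(c(TRUE, cluster_sorted[-1] != cluster_sorted[-length(sm)] |
                        sgn[-1] != sgn[-length(sm)] |
                        qual[-1] != qual[-length(sm)]))
  keep <- which(qual)
  if (!length(keep)) return(NULL)
  rk <- run_key[keep]
  len <- tapply(rk, rk, length)
  ok_runs <- names(len)[len >= min_cpgs]
  if (!length(ok_runs)) return(NULL)
  sel <- keep[rk %in% ok_runs]
  rk_sel <- run_key[sel]
  data.frame(
    run = as.integer(names(tapply(sel, rk_sel, min))),
    first = as.integer(tapply(sel, rk_sel, min)),
    last = as.integer(tapply(sel, rk_sel, max)),
    n_cpgs = as.integer(tapply(sel, rk_sel, length)),
    area = as.numeric(tapply(abs(sm[sel]), rk_sel, sum)),
    stringsAsFactors = FALSE)
}

# Per-CpG sex coefficient for matrix M (CpG x samples) under design X:
# beta = M %*% c where c is the extractor row of the least-squares
# solution for the sexF column.
sex_coef_vector <- function(X) {
  cmat <- solve(crossprod(X), t(X))
  cmat["sexF", ]
}

#' Detect differentially methylated regions
#'
#' Bump hunting over the per-CpG sex effects with a permutation null:
#' sex labels are permuted within timepoint strata, the full candidate
#' extraction (coefficients, smoothing, cutoff, runs) is re-run on each
#' of the `B` resamplings, and each observed bump's area is compared to
#' the null distribution of per-permutation maximum areas:
#' `p = (1 + #[null >= area]) / (B + 1)`.
#'
#' @param meth methylome `omics_matrix` (beta values, typically baseline
#'   samples only).
#' @param sheet sample sheet covering the matrix columns.
#' @param ann CpG annotation table aligned with the matrix features.
#' @param maxgap cluster gap, bp.
#' @param cutoff_quantile candidate cutoff: quantile of |smoothed effect|.
#' @param min_cpgs minimum CpGs per DMR.
#' @param B number of resamplings (>= 20 for usable p resolution).
#' @param seed permutation RNG seed.
#' @return `Dmr` data.frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `n_cpgs`, `mean_delta_beta` (female minus male), `area`, `direction`
#'   (`hyper_F`/`hypo_F`), `p_value`, `fwer_rank`, `cpg_ids`
#'   (comma-separated members), sorted by p then area.
#' @export
detect_dmrs <- function(meth, sheet, ann, maxgap = 300, cutoff_quantile = 0.99,
                        min_cpgs = 2, B = 1000, seed = 1) {
  stopifnot(inherits(meth, "omics_matrix"))
  if (B < 20) stopf("B = %d resamplings gives too coarse a p resolution (need >= 20)", B)
  M <- meth$values
  sheet <- sheet[match(colnames(M), sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) stopf("matrix columns missing from sample sheet")
  ann <- ann[match(rownames(M), ann$cpg_id), ]
  if (anyNA(ann$cpg_id)) stopf("matrix features missing from CpG annotation")

  ord <- order(ann$chrom, ann$pos)
  M <- M[ord, , drop = FALSE]
  ann <- ann[ord, ]
  cluster <- cluster_cpgs(ann, maxgap)   # already sorted; ids in order
  if (max(tapply(seq_along(cluster), cluster, length)) < min_cpgs)
    stopf("no CpG cluster with >= %d members; nothing to detect", min_cpgs)
  layout <- smoother_layout(cluster)

  X <- build_design(sheet, c("sexF", "age"))
  run_once <- function(Xd, cutoff = NULL) {
    beta <- drop(M %*% sex_coef_vector(Xd))
    sm <- smooth_effects(beta, layout)
    # the cutoff is chosen once, from the observed smoothed effects, and
    # held fixed for the resamplings so areas are comparable
    if (is.null(cutoff))
      cutoff <- stats::quantile(abs(sm), cutoff_quantile, names = FALSE)
    list(bumps = extract_bumps(sm, cluster, cutoff, min_cpgs),
         beta = beta, sm = sm, cutoff = cutoff)
  }
  obs <- run_once(X)
  if (is.null(obs$bumps)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_cpgs = integer(0), mean_delta_beta = numeric(0),
                      area = numeric(0), direction = character(0),
                      p_value = numeric(0), fwer_rank = integer(0),
                      cpg_ids = character(0), stringsAsFactors = FALSE))
  }

  # permutation null: sex labels shuffled within timepoint strata
  set.seed(seed)
  strata <- split(seq_len(nrow(sheet)), sheet$timepoint)
  null_max <- numeric(B)
  sexF <- X[, "sexF"]
  for (b in seq_len(B)) {
    perm <- sexF
    for (s in strata) perm[s] <- sexF[sample(s)]
    Xp <- X
    Xp[, "sexF"] <- perm
    nb <- run_once(Xp, cutoff = obs$cutoff)$bumps
    null_max[b] <- if (is.null(nb)) 0 else max(nb$area)
  }

  bp <- obs$bumps
  pvals <- vapply(bp$area, function(a) (1 + sum(null_max >= a)) / (B + 1), 0)
  dmrs <- data.frame(
    chrom = ann$chrom[bp$first],
    start = ann$pos[bp$first],
    end = ann$pos[bp$last],
    n_cpgs = bp$n_cpgs,
    mean_delta_beta = vapply(seq_len(nrow(bp)), function(i)
      mean(obs$beta[bp$first[i]:bp$last[i]]), 0),
    area = bp$area,
    direction = ifelse(vapply(seq_len(nrow(bp)), function(i)
      mean(obs$sm[bp$first[i]:bp$last[i]]), 0) > 0, "hyper_F", "hypo_F"),
    p_value = pvals,
    fwer_rank = NA_integer_,
    cpg_ids = vapply(seq_len(nrow(bp)), function(i)
      paste(ann$cpg_id[bp$first[i]:bp$last[i]], collapse = ","), ""),
    stringsAsFactors = FALSE)
  dmrs <- dmrs[order(dmrs$p_value, -dmrs$area), ]
  dmrs$fwer_rank <- seq_len(nrow(dmrs))
  rownames(dmrs) <- NULL
  dmrs
}

#' Summarize a DMR table
#'
#' Per-chromosome counts and fractions, the gene-proximal vs intergenic
#' partition (a DMR is gene-proximal iff at least one member CpG has
#' non-intergenic context), and the number of distinct genes touched.
#' Both a disjoint partition and the overlapping gene-touch count are
#' reported, so either reading of "in close proximity to genes" can be
#' produced.
#'
#' @param dmrs `Dmr` table from [detect_dmrs()] (non-empty).
#' @param ann CpG annotation table.
#' @param alpha optional p-value threshold applied before summarizing
#'   (`NULL` = summarize all rows).
#' @return list: `n_dmrs`, `by_chrom` (counts + fractions), `chrX_fraction`,
#'   `n_gene_proximal`, `n_intergenic`, `n_genes`, `genes`.
#' @export
summarize_dmrs <- function(dmrs, ann, alpha = NULL) {
  if (!is.null(alpha)) dmrs <- dmrs[dmrs$p_value <= alpha, , drop = FALSE]
  if (nrow(dmrs) == 0) {
    return(list(n_dmrs = 0L, by_chrom = data.frame(), chrX_fraction = NA_real_,
                n_gene_proximal = 0L, n_intergenic = 0L, n_genes = 0L,
                genes = character(0)))
  }
  members <- strsplit(dmrs$cpg_ids, ",", fixed = TRUE)
  ctx <- lapply(members, function(ids) ann$context[match(ids, ann$cpg_id)])
  gene_prox <- vapply(ctx, function(cc) any(cc != "intergenic"), TRUE)
  genes <- sort(unique(unlist(lapply(members, function(ids) {
    g <- ann$gene[match(ids, ann$cpg_id)]
    g[g != ""]
  }))))
  counts <- table(dmrs$chrom)
  by_chrom <- data.frame(chrom = names(counts), n = as.integer(counts),
                         fraction = as.numeric(counts) / nrow(dmrs),
                         stringsAsFactors = FALSE)
  list(n_dmrs = nrow(dmrs),
       by_chrom = by_chrom,
       chrX_fraction = sum(dmrs$chrom == "chrX") / nrow(dmrs),
       n_gene_proximal = sum(gene_prox),
       n_intergenic = sum(!gene_prox),
       n_genes = length(genes),
       genes = genes)
}

#' Write a DMR table as BED-flavoured TSV
#'
#' Columns: chrom, 0-based start, end, name, area, direction, p. The
#' in-memory table is 1-based inclusive (array-manifest convention);
#' only this export shifts to BED coordinates.
#'
#' @param dmrs `Dmr` table.
#' @param path file path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1, end = dmrs$end,
                    name = sprintf("dmr_%03d", seq_len(nrow(dmrs))),
                    area = dmrs$area, direction = dmrs$direction,
                    p = dmrs$p_value, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
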