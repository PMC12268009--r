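# Direction-aware multi-omics integration: differential CpGs are linked
# to differential transcripts through the promoter/gene-body rule
# (promoter methylation silences, gene-body methylation accompanies
# active transcription), chained onward to differential proteins, and
# rolled up into cross-stage overlap summaries.

#' Hypermethylation summary
#'
#' Counts differential CpGs with a positive female-minus-male effect
#' (hypermethylated in females) and reports the percentage truncated to
#' one decimal.
#'
#' @param effects signed CpG effects (female minus male), or a
#'   `DiffResult` data.frame with an `effect` column.
#' @return list: `n`, `n_hyper_F`, `pct_hyper_F`.
#' @export
hypermethylation_summary <- function(effects) {
  if (is.data.frame(effects)) effects <- effects$effect
  if (!length(effects)) stopf("no differential CpGs to summarize")
  n_hyper <- sum(effects > 0)
  list(n = length(effects), n_hyper_F = n_hyper,
       pct_hyper_F = pct_1dp(n_hyper, length(effects)))
}

#' Direction-aware CpG-to-transcript linking
#'
#' One record per (differential CpG, differential transcript) pair
#' sharing a gene. A record is consistent iff the CpG sits in the
#' promoter and methylation and expression point in opposite directions,
#' or sits in the gene body and they point in the same direction. A
#' transcript is "linked" iff it has at least one consistent record.
#'
#' @param dm_cpgs differential CpGs: data.frame `feature_id`, `effect`
#'   (already thresholded, e.g. p < 0.05).
#' @param de_transcripts differential transcripts: data.frame
#'   `feature_id`, `effect` (thresholded likewise).
#' @param ann CpG annotation table.
#' @return `LinkRecord` data.frame: `cpg_id`, `gene`, `context`,
#'   `meth_direction`, `expr_direction`, `consistent`; attribute
#'   `n_unannotated` counts skipped CpGs without annotation.
#' @export
directional_link <- function(dm_cpgs, de_transcripts, ann) {
  m <- match(dm_cpgs$feature_id, ann$cpg_id)
  n_unann <- sum(is.na(m))
  keep <- !is.na(m)
  cpg <- data.frame(cpg_id = dm_cpgs$feature_id[keep],
                    meth_effect = dm_cpgs$effect[keep],
                    gene = ann$gene[m[keep]],
                    context = ann$context[m[keep]], stringsAsFactors = FALSE)
  cpg <- cpg[cpg$context %in% c("promoter", "gene_body"), , drop = FALSE]
  de <- data.frame(gene = de_transcripts$feature_id,
                   expr_effect = de_transcripts$effect, stringsAsFactors = FALSE)
  rec <- merge(cpg, de, by = "gene")
  if (nrow(rec) == 0) {
    out <- data.frame(cpg_id = character(0), gene = character(0),
                      context = character(0), meth_direction = character(0),
                      expr_direction = character(0), consistent = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_unannotated") <- n_unann
    return(out)
  }
  meth_dir <- ifelse(rec$meth_effect > 0, "hyper_F", "hypo_F")
  expr_dir <- ifelse(rec$expr_effect > 0, "up_F", "down_F")
  same <- (rec$meth_effect > 0) == (rec$expr_effect > 0)
  consistent <- ifelse(rec$context == "promoter", !same, same)
  out <- data.frame(cpg_id = rec$cpg_id, gene = rec$gene, context = rec$context,
                    meth_direction = meth_dir, expr_direction = expr_dir,
                    consistent = consistent, stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$cpg_id), ]
  rownames(out) <- NULL
  attr(out, "n_unannotated") <- n_unann
  out
}

#' Transcripts linked to methylation
#' @param links `LinkRecord` table from [directional_link()].
#' @return character vector of genes with >= 1 consistent record.
#' @export
linked_transcripts <- function(links) {
  sort(unique(links$gene[links$consistent]))
}

#' Chain differential proteins back to methylation
#'
#' A differential protein is "linked" to methylation if its gene carries
#' at least one differential CpG in its promoter or gene body (no
#' direction requirement at the protein level); it is in the stricter
#' "chain" if its gene is additionally a differential transcript with a
#' consistent CpG link and protein and transcript effects in the same
#' direction, tracing protein abundance over expression back to
#' sex-specific methylation.
#'
#' @param links `LinkRecord` table from [directional_link()].
#' @param dp_proteins differential proteins: data.frame `feature_id`,
#'   `effect` (thresholded).
#' @param gene_map data.frame `protein_id`, `gene`.
#' @param de_transcripts differential transcripts (`feature_id`,
#'   `effect`).
#' @param dm_cpgs differential CpGs (`feature_id`, `effect`).
#' @param ann CpG annotation table.
#' @return list: `linked` (protein ids), `chain` (protein ids),
#'   `n_unmapped` proteins without a gene mapping.
#' @export
link_proteins <- function(links, dp_proteins, gene_map, de_transcripts,
                          dm_cpgs, ann) {
  g <- gene_map$gene[match(dp_proteins$feature_id, gene_map$protein_id)]
  n_unmapped <- sum(is.na(g))
  ok <- !is.na(g)
  dm_genes <- unique(ann$gene[match(dm_cpgs$feature_id, ann$cpg_id)])
  dm_genes <- dm_genes[!is.na(dm_genes) & dm_genes != ""]
  linked <- dp_proteins$feature_id[ok & g %in% dm_genes]
  chain_genes <- unique(links$gene[links$consistent])
  de_eff <- de_transcripts$effect[match(g, de_transcripts$feature_id)]
  in_chain <- ok & g %in% chain_genes & !is.na(de_eff) &
    (sign(de_eff) == sign(dp_proteins$effect))
  list(linked = sort(linked),
       chain = sort(dp_proteins$feature_id[in_chain]),
       n_unmapped = n_unmapped)
}

#' DMR-to-transcript direction concordance
#'
#' Pairs each DMR with the differential transcripts of its member CpGs'
#' genes and checks direction concordance under the same promoter /
#' gene-body rule as [directional_link()] (context taken per gene from
#' the member CpGs; promoter wins if both contexts occur).
#'
#' @param dmrs `Dmr` table.
#' @param de_transcripts differential transcripts (`feature_id`,
#'   `effect`).
#' @param ann CpG annotation table.
#' @return data.frame: `chrom`, `start`, `end`, `direction`, `gene`,
#'   `context`, `expr_direction`, `concordant`.
#' @export
link_dmrs_to_transcripts <- function(dmrs, de_transcripts, ann) {
  rows <- list()
  for (i in seq_len(nrow(dmrs))) {
    ids <- strsplit(dmrs$cpg_ids[i], ",", fixed = TRUE)[[1]]
    sub <- ann[match(ids, ann$cpg_id), ]
    sub <- sub[!is.na(sub$gene) & sub$gene != "", , drop = FALSE]
    if (!nrow(sub)) next
    for (g in unique(sub$gene)) {
      j <- match(g, de_transcripts$feature_id)
      if (is.na(j)) next
      ctxs <- sub$context[sub$gene == g]
      ctx <- if ("promoter" %in% ctxs) "promoter" else "gene_body"
      hyper <- dmrs$direction[i] == "hyper_F"
      up <- de_transcripts$effect[j] > 0
      conc <- if (ctx == "promoter") hyper != up else hyper == up
      rows[[length(rows) + 1]] <- data.frame(
        chrom = dmrs$chrom[i], start = dmrs$start[i], end = dmrs$end[i],
        direction = dmrs$direction[i], gene = g, context = ctx,
        expr_direction = if (up) "up_F" else "down_F",
        concordant = conc, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      direction = character(0), gene = character(0),
                      context = character(0), expr_direction = character(0),
                      concordant = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Cross-stage integration summary
#'
#' Rolls the differential sets and link tables up into the study-shaped
#' counts: differential features per layer, methylation-linked
#' transcripts and proteins with percentages (truncated to one decimal),
#' the chain count, the female-hypermethylation summary, and gene-level
#' Venn counts across the three layers.
#'
#' @param dm_cpgs differential CpGs (`feature_id`, `effect`).
#' @param de_transcripts differential transcripts (`feature_id`,
#'   `effect`).
#' @param dp_proteins differential proteins (`feature_id`, `effect`).
#' @param links `LinkRecord` table from [directional_link()].
#' @param protein_links result of [link_proteins()].
#' @param ann CpG annotation table.
#' @param gene_map protein-to-gene map.
#' @return `IntegrationSummary` list; `n_linking_cpgs` counts CpGs in
#'   consistent records, `n_colocated_cpgs` those merely sharing a gene
#'   with a differential transcript.
#' @export
summarize_overlap <- function(dm_cpgs, de_transcripts, dp_proteins,
                              links, protein_links, ann, gene_map) {
  n_de <- nrow(de_transcripts)
  n_dp <- nrow(dp_proteins)
  lt <- linked_transcripts(links)
  hyp <- if (nrow(dm_cpgs)) hypermethylation_summary(dm_cpgs) else
    list(n = 0L, n_hyper_F = 0L, pct_hyper_F = 0)
  # gene-level sets for the Venn
  g_meth <- unique(ann$gene[match(dm_cpgs$feature_id, ann$cpg_id)])
  g_meth <- g_meth[!is.na(g_meth) & g_meth != ""]
  g_txn <- unique(de_transcripts$feature_id)
  g_prot <- unique(gene_map$gene[match(dp_proteins$feature_id, gene_map$protein_id)])
  g_prot <- g_prot[!is.na(g_prot)]
  venn <- list(
    meth_only = length(setdiff(setdiff(g_meth, g_txn), g_prot)),
    txn_only = length(setdiff(setdiff(g_txn, g_meth), g_prot)),
    prot_only = length(setdiff(setdiff(g_prot, g_meth), g_txn)),
    meth_txn = length(setdiff(intersect(g_meth, g_txn), g_prot)),
    meth_prot = length(setdiff(intersect(g_meth, g_prot), g_txn)),
    txn_prot = length(setdiff(intersect(g_txn, g_prot), g_meth)),
    meth_txn_prot = length(intersect(intersect(g_meth, g_txn), g_prot)))
  list(
    n_dm_cpgs = nrow(dm_cpgs),
    n_de_transcripts = n_de,
    n_linked_transcripts = length(lt),
    n_linking_cpgs = length(unique(links$cpg_id[links$consistent])),
    n_colocated_cpgs = length(unique(links$cpg_id)),
    pct_linked_transcripts = pct_1dp(length(lt), n_de),
    n_dp_proteins = n_dp,
    n_linked_proteins = length(protein_links$linked),
    pct_linked_proteins = pct_1dp(length(protein_links$linked), n_dp),
    n_chain_proteins = length(protein_links$chain),
    n_hyper_F_cpgs = hyp$n_hyper_F,
    pct_hyper_F = hyp$pct_hyper_F,
    venn = venn)
}

#' Extract the significant feature set from a moderated result
#'
#' @param res result list from [ebayes_moderate()] (or its `table`).
#' @param p threshold on raw p (the headline sex-difference sets use
#'   raw p < 0.05); set `adjusted = TRUE` to threshold on BH-adjusted p.
#' @param adjusted threshold on `p_adj` instead of `p`.
#' @return data.frame `feature_id`, `effect` of significant features.
#' @export
significant_features <- function(res, p = 0.05, adjusted = FALSE) {
  tab <- if (is.data.frame(res)) res else res$table
  col <- if (adjusted) tab$p_adj else tab$p
  keep <- !is.na(col) & col < p
  data.frame(feature_id = tab$feature_id[keep], effect = tab$effect[keep],
             stringsAsFactors = FALSE)
}
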