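# Fiber-type and mitochondrial annotation of differential proteins, and
# the baseline-vs-trained equalization analysis.

#' Classify proteins by dominant fiber type
#'
#' The dominant type is the argmax of the reference percentage profile
#' (slow type 1 vs fast type 2a/2x); a protein is unclassified when the
#' top two percentages lie within `tie_margin` points. With
#' `pool_type2 = TRUE` the 2a and 2x percentages are pooled before the
#' comparison and the call is type1 vs type2.
#'
#' @param ref fiber-type reference table, see [read_fiber_reference()].
#' @param tie_margin tie margin in percentage points.
#' @param pool_type2 pool the fast subtypes.
#' @return `FiberCall` data.frame: `protein_id`, `dominant_type`,
#'   `max_pct`.
#' @export
classify_fiber_proteins <- function(ref, tie_margin = 5, pool_type2 = FALSE) {
  validate_fiber_reference(ref)
  if (pool_type2) {
    p <- cbind(type1 = ref$pct_type1, type2 = ref$pct_type2a + ref$pct_type2x)
  } else {
    p <- cbind(type1 = ref$pct_type1, type2a = ref$pct_type2a, type2x = ref$pct_type2x)
  }
  calls <- apply(p, 1, function(x) {
    o <- order(x, decreasing = TRUE)
    if (x[o[1]] - x[o[2]] < tie_margin) "unclassified" else colnames(p)[o[1]]
  })
  data.frame(protein_id = ref$protein_id, dominant_type = unname(calls),
             max_pct = apply(p, 1, max), stringsAsFactors = FALSE)
}

#' Fiber-type enrichment of sex-differential proteins
#'
#' 2x2 association of protein sex direction (male-higher vs
#' female-higher) with fiber-type class (fast type 2 vs slow type 1)
#' among classified differential proteins. The p-value is the exact
#' Fisher test (hypergeometric enumeration); the odds ratio is the
#' sample odds ratio with a Haldane 0.5 correction when any cell is 0.
#'
#' @param dp_proteins differential proteins (`feature_id`, `effect`;
#'   positive = higher in females).
#' @param calls `FiberCall` table from [classify_fiber_proteins()].
#' @return list: `table` (2x2), `odds_ratio`, `p`.
#' @export
fiber_enrichment_of_diff <- function(dp_proteins, calls) {
  type <- calls$dominant_type[match(dp_proteins$feature_id, calls$protein_id)]
  type[type %in% c("type2a", "type2x")] <- "type2"
  keep <- !is.na(type) & type %in% c("type1", "type2")
  if (!any(keep)) stopf("no classified fiber-type proteins among the differential set")
  male_higher <- dp_proteins$effect[keep] < 0
  type <- type[keep]
  tab <- matrix(c(sum(male_higher & type == "type2"),
                  sum(male_higher & type == "type1"),
                  sum(!male_higher & type == "type2"),
                  sum(!male_higher & type == "type1")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("male_higher", "female_higher"),
                                c("type2", "type1")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("need at least one protein per margin of the 2x2 table")
  p <- stats::fisher.test(tab)$p.value
  h <- if (any(tab == 0)) 0.5 else 0
  or <- ((tab[1, 1] + h) * (tab[2, 2] + h)) / ((tab[1, 2] + h) * (tab[2, 1] + h))
  list(table = tab, odds_ratio = or, p = p)
}

#' Training equalization of baseline sex differences
#'
#' Re-evaluates the features that differed between the sexes at baseline:
#' a feature is equalized iff it is no longer differential after
#' training. Per-sex change directions come from the paired
#' trained-vs-baseline contrasts.
#'
#' @param baseline_diff_ids features differential at baseline.
#' @param trained_diff_ids features differential after training
#'   (same feature universe).
#' @param male_response,female_response paired contrast tables
#'   (`DiffResult`, trained vs baseline per sex) or `NULL`.
#' @param p significance threshold for calling a change direction.
#' @return `EqualizationRecord` data.frame: `protein_id`,
#'   `diff_at_baseline`, `diff_after_training`,
#'   `male_change_direction`, `female_change_direction`, `equalized`.
#' @export
equalization_analysis <- function(baseline_diff_ids, trained_diff_ids,
                                  male_response = NULL, female_response = NULL,
                                  p = 0.05) {
  ids <- sort(unique(baseline_diff_ids))
  if (!length(ids)) {
    return(data.frame(protein_id = character(0), diff_at_baseline = logical(0),
                      diff_after_training = logical(0),
                      male_change_direction = character(0),
                      female_change_direction = character(0),
                      equalized = logical(0), stringsAsFactors = FALSE))
  }
  dir_of <- function(res, id) {
    if (is.null(res)) return(NA_character_)
    tab <- if (is.data.frame(res)) res else res$table
    j <- match(id, tab$feature_id)
    if (is.na(j) || is.na(tab$p[j]) || tab$p[j] >= p) return("none")
    if (tab$effect[j] > 0) "up" else "down"
  }
  after <- ids %in% trained_diff_ids
  data.frame(
    protein_id = ids,
    diff_at_baseline = TRUE,
    diff_after_training = after,
    male_change_direction = vapply(ids, function(i) dir_of(male_response, i), ""),
    female_change_direction = vapply(ids, function(i) dir_of(female_response, i), ""),
    equalized = !after,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Mitochondrial annotation
#'
#' Flags proteins by exact, case-sensitive membership in a mitochondrial
#' catalogue. Identifiers matching only after case folding are reported
#' as near misses (attribute `near_miss`) but never counted.
#'
#' @param ids protein identifiers.
#' @param mito_list mitochondrial identifiers.
#' @return logical vector named by `ids`; attributes `n_mito` and
#'   `near_miss`.
#' @export
annotate_mito <- function(ids, mito_list) {
  flag <- ids %in% mito_list
  near <- ids[!flag & tolower(ids) %in% tolower(mito_list)]
  if (length(near))
    warnf("%d identifier(s) match the mitochondrial list only after case folding (e.g. '%s'); counted as non-mitochondrial",
          length(near), near[1])
  structure(stats::setNames(flag, ids), n_mito = sum(flag), near_miss = near)
}
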