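# Over-representation analysis: hypergeometric upper-tail test of a
# query feature set against gene-set collections, BH-corrected across
# terms. (The graph-aware g:SCS correction used by online services is
# proprietary; BH is the correction applied here and reported as such.)

#' Over-representation analysis of a feature set
#'
#' For each gene set (intersected with the universe, size limits
#' applied), tests whether the overlap `k` with the query of size `n`
#' exceeds chance in a universe of size `N`:
#' `p = sum_{i>=k} C(K,i) C(N-K, n-i) / C(N,n)`.
#'
#' @param query query feature set (must be a subset of the universe).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe feature universe; conventionally all features
#'   quantified in the relevant layer.
#' @param min_size,max_size set-size limits after universe intersection.
#' @param p_adj_threshold flag threshold for the `significant` column.
#' @return `EnrichmentResult` data.frame sorted by `p_adj` then `p`:
#'   `term_id`, `k`, `K`, `n`, `N`, `p`, `p_adj`, `significant`,
#'   `members` (overlapping features, comma-separated).
#' @export
ora <- function(query, gene_sets, universe, min_size = 3, max_size = Inf,
                p_adj_threshold = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  query <- unique(query)
  bad <- setdiff(query, universe)
  if (length(bad))
    stopf("query feature(s) outside the universe: %s%s",
          paste(utils::head(bad, 5), collapse = ", "),
          if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else "")
  empty <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      members = character(0), stringsAsFactors = FALSE)
  if (!length(query)) return(empty)
  sets <- lapply(gene_sets, intersect, universe)
  K <- vapply(sets, length, 1L)
  sets <- sets[K >= min_size & K <= max_size]
  if (!length(sets)) return(empty)
  N <- length(universe)
  n <- length(query)
  k <- vapply(sets, function(s) length(intersect(s, query)), 1L)
  K <- vapply(sets, length, 1L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(sets), k = k, K = K, n = n, N = N,
                    p = p, p_adj = bh_adjust(p), significant = NA,
                    members = vapply(sets, function(s)
                      paste(sort(intersect(s, query)), collapse = ","), ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$p_adj < p_adj_threshold
  out[order(out$p_adj, out$p, out$term_id), ]
}
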