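# Label-free proteome preprocessing: total-amount normalization,
# group-completeness filtering, log2 transform and downshifted-normal
# imputation of missing-not-at-random values.

#' Total-amount normalization
#'
#' Scales each sample so its observed total abundance equals the mean of
#' all sample totals, correcting sample-loading differences. Operates on
#' raw-scale (non-log) abundances; the missingness pattern is unchanged.
#'
#' @param mat `omics_matrix`, layer `protein_raw`, non-negative values.
#' @return normalized `omics_matrix`; attribute `scale_factors` records
#'   the per-sample factors.
#' @export
total_amount_normalize <- function(mat) {
  stopifnot(inherits(mat, "omics_matrix"))
  M <- mat$values
  if (any(M < 0, na.rm = TRUE)) stopf("total-amount normalization expects non-negative raw abundances")
  totals <- colSums(M, na.rm = TRUE)
  if (any(totals == 0))
    stopf("sample '%s' has zero observed total abundance", colnames(M)[which(totals == 0)[1]])
  f <- mean(totals) / totals
  out <- omics_matrix(sweep(M, 2, f, `*`), mat$layer)
  attr(out, "scale_factors") <- f
  out
}

#' Group-completeness filter
#'
#' Keeps a protein if it is quantified in at least `threshold` of the
#' samples of at least one experimental group (default groups:
#' sex x timepoint). The boundary is inclusive: 9 of 10 passes at 0.90.
#'
#' @param mat `omics_matrix` with missing values.
#' @param sheet sample sheet covering the matrix columns.
#' @param groups factor/character of group labels per matrix column, or
#'   `NULL` for sex x timepoint.
#' @param threshold required observed fraction within a group.
#' @return filtered `omics_matrix`; attribute `decisions` is a per-feature
#'   table of the best group completeness and the keep/drop call.
#' @export
filter_by_completeness <- function(mat, sheet, groups = NULL, threshold = 0.90) {
  stopifnot(inherits(mat, "omics_matrix"))
  M <- mat$values
  sheet <- sheet[match(colnames(M), sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) stopf("matrix columns missing from sample sheet")
  if (is.null(groups)) groups <- paste(sheet$sex, sheet$timepoint, sep = ".")
  if (length(groups) != ncol(M)) stopf("groups must label every sample")
  tab <- table(groups)
  if (any(tab == 0)) stopf("empty experimental group: %s", names(tab)[tab == 0][1])
  obs <- !is.na(M)
  frac_by_group <- sapply(unique(groups), function(g)
    rowMeans(obs[, groups == g, drop = FALSE]))
  best <- apply(frac_by_group, 1, max)
  keep <- best >= threshold
  decisions <- data.frame(feature_id = rownames(M),
                          best_group_completeness = unname(best),
                          kept = unname(keep), stringsAsFactors = FALSE)
  out <- omics_matrix(M[keep, , drop = FALSE], mat$layer)
  attr(out, "decisions") <- decisions
  out
}

#' Downshift imputation specification
#'
#' @param shift downshift from the observed mean, in SD multiples.
#' @param width SD of the imputation distribution, in SD multiples.
#' @param scope `"per_sample"` (column-wise moments, the usual convention
#'   for sample-wise missingness) or `"global"`.
#' @param seed RNG seed for the imputation draws.
#' @return `impute_spec` list.
#' @export
impute_spec <- function(shift = 1.5, width = 0.5, scope = c("per_sample", "global"),
                        seed = 1) {
  scope <- match.arg(scope)
  if (shift < 0) stopf("shift must be >= 0")
  if (width <= 0) stopf("width must be > 0")
  structure(list(shift = shift, width = width, scope = scope, seed = seed),
            class = "impute_spec")
}

#' Downshifted-normal imputation of missing values
#'
#' Replaces each missing cell of a log-scale matrix by a draw from
#' `Normal(mu - shift*sigma, (width*sigma)^2)` where `mu`, `sigma` are the
#' observed mean and SD of the scope (sample column or whole matrix),
#' emulating the detection-limit origin of label-free missingness.
#' Observed cells are untouched; results are deterministic under the
#' seed carried by `spec`.
#'
#' @param mat `omics_matrix`, log scale (`protein_log`).
#' @param spec an [impute_spec()].
#' @return complete `omics_matrix`; attributes `imputed_mask` (logical
#'   matrix), `n_imputed` and `frac_imputed` report what was filled.
#' @export
impute_downshift <- function(mat, spec = impute_spec()) {
  stopifnot(inherits(mat, "omics_matrix"), inherits(spec, "impute_spec"))
  M <- mat$values
  miss <- is.na(M)
  if (!any(miss)) {
    out <- mat
    attr(out, "imputed_mask") <- miss
    attr(out, "n_imputed") <- 0L
    attr(out, "frac_imputed") <- 0
    return(out)
  }
  set.seed(spec$seed)
  scope <- spec$scope
  if (scope == "per_sample") {
    n_obs <- colSums(!miss)
    if (any(n_obs < 3)) {
      warnf("%d sample(s) with < 3 observed values; falling back to global scope",
            sum(n_obs < 3))
      scope <- "global"
    }
  }
  if (scope == "per_sample") {
    for (j in seq_len(ncol(M))) {
      mj <- miss[, j]
      if (!any(mj)) next
      mu <- mean(M[!mj, j])
      sg <- stats::sd(M[!mj, j])
      M[mj, j] <- stats::rnorm(sum(mj), mu - spec$shift * sg, spec$width * sg)
    }
  } else {
    mu <- mean(M[!miss])
    sg <- stats::sd(M[!miss])
    M[miss] <- stats::rnorm(sum(miss), mu - spec$shift * sg, spec$width * sg)
  }
  out <- omics_matrix(M, "protein_log")
  attr(out, "imputed_mask") <- miss
  attr(out, "n_imputed") <- sum(miss)
  attr(out, "frac_imputed") <- mean(miss)
  out
}

#' Log2-transform a raw protein matrix
#'
#' @param mat `omics_matrix`, layer `protein_raw`, strictly positive
#'   observed values.
#' @return `omics_matrix` with layer `protein_log`.
#' @export
log2_protein <- function(mat) {
  stopifnot(inherits(mat, "omics_matrix"))
  if (any(mat$values <= 0, na.rm = TRUE)) stopf("log2 transform requires positive abundances")
  omics_matrix(log2(mat$values), "protein_log")
}

#' Run the full proteome preprocessing chain
#'
#' filter (group completeness) -> total-amount normalize -> log2 ->
#' downshift impute, with an imputation report.
#'
#' @param mat raw-scale `omics_matrix` with missing values.
#' @param sheet sample sheet.
#' @param threshold completeness threshold, see [filter_by_completeness()].
#' @param spec imputation spec, see [impute_spec()].
#' @param groups optional explicit group labels.
#' @return list: `matrix` (complete log2 `omics_matrix`), `decisions`
#'   (filter table), `report` (features before/after, imputed-cell count
#'   and fraction).
#' @export
prep_proteome <- function(mat, sheet, threshold = 0.90, spec = impute_spec(),
                          groups = NULL) {
  n0 <- nrow(mat$values)
  filt <- filter_by_completeness(mat, sheet, groups = groups, threshold = threshold)
  norm <- total_amount_normalize(filt)
  lg <- log2_protein(norm)
  imp <- impute_downshift(lg, spec)
  list(matrix = imp,
       decisions = attr(filt, "decisions"),
       report = list(
         n_features_in = n0,
         n_features_kept = nrow(imp$values),
         n_imputed = attr(imp, "n_imputed"),
         frac_imputed = attr(imp, "frac_imputed")))
}
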