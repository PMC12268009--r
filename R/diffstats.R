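# Per-feature linear models with covariates, empirical-Bayes variance
# moderation, paired timepoint contrasts with fold changes, BH adjustment
# and the Shapiro-Wilk log-transform gate.
#
# The moderation follows the standard moment-matching scheme: the
# log residual variances are matched to a scaled F / log-chi-square
# distribution, the prior degrees of freedom d0 obtained by trigamma
# inversion and the prior variance s0^2 from the corrected mean. The
# posterior variance s~^2 = (d0 s0^2 + d s^2) / (d0 + d) shrinks each
# feature's variance toward the prior, and the moderated t carries
# d0 + d degrees of freedom.

#' Build a design matrix from a sample sheet
#'
#' Columns: intercept, `sexF` (1 = female, so the sex coefficient is the
#' female minus male difference), and optionally `age` (centered). Age is
#' included by default: the cohort's sexes differ in mean age, so all
#' linear models carry age as a covariate.
#'
#' @param sheet sample sheet rows matching the matrix columns, in order.
#' @param covariates subset of `c("sexF", "age")`.
#' @return numeric design matrix with rownames = sample ids.
#' @export
build_design <- function(sheet, covariates = c("sexF", "age")) {
  X <- cbind(intercept = rep(1, nrow(sheet)))
  if ("sexF" %in% covariates) X <- cbind(X, sexF = as.numeric(sheet$sex == "F"))
  if ("age" %in% covariates) X <- cbind(X, age = sheet$age - mean(sheet$age))
  rownames(X) <- sheet$sample_id
  X
}

#' Shapiro-Wilk gate for log transformation
#'
#' Group-comparison variables that fail a Shapiro-Wilk normality test at
#' `alpha` are log-transformed, provided all values are strictly
#' positive. Applied to clinical-style variables, not to omics features
#' (which are modeled on their stated scale).
#'
#' @param x numeric vector, at least 3 finite values.
#' @param alpha significance threshold of the normality test.
#' @return `"log"` or `"identity"`, with attributes `p` (Shapiro-Wilk p)
#'   and, when a non-normal variable contains non-positive values,
#'   `warning` describing why the log branch was refused.
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stopf("shapiro_gate needs >= 3 finite values, got %d", length(x))
  if (stats::sd(x) == 0) stopf("shapiro_gate undefined for constant input (zero variance)")
  p <- stats::shapiro.test(x)$p.value
  if (p < alpha) {
    if (all(x > 0)) return(structure("log", p = p))
    return(structure("identity", p = p,
                     warning = "non-normal but contains non-positive values; log transform refused"))
  }
  structure("identity", p = p)
}

#' Fit per-feature linear models
#'
#' Ordinary least squares of every matrix row on a shared design.
#'
#' @param mat `omics_matrix` or numeric matrix (features x samples),
#'   complete (impute the proteome first).
#' @param design design matrix from [build_design()], rows aligned with
#'   the matrix columns.
#' @return `feature_fit` list: `coefficients` (features x p),
#'   `s2` residual variances, `df` residual degrees of freedom,
#'   `stdev_unscaled` per-coefficient unscaled standard errors
#'   (sqrt of the diagonal of (X'X)^-1), `feature_id`.
#' @export
fit_linear_model <- function(mat, design) {
  M <- if (inherits(mat, "omics_matrix")) mat$values else mat
  if (anyNA(M)) stopf("matrix contains missing values; impute before model fitting")
  if (ncol(M) != nrow(design))
    stopf("dimension mismatch: %d samples in matrix, %d rows in design", ncol(M), nrow(design))
  if (!is.null(rownames(design)) && !is.null(colnames(M)) &&
      !identical(colnames(M), rownames(design)))
    stopf("sample order of matrix and design disagree")
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design))
    stopf("design matrix is rank deficient (rank %d < %d columns)", qr_x$rank, ncol(design))
  coefs <- t(qr.coef(qr_x, t(M)))
  resid <- t(qr.resid(qr_x, t(M)))
  df <- ncol(M) - ncol(design)
  s2 <- if (df > 0) rowSums(resid^2) / df else rep(NA_real_, nrow(M))
  xtx_inv <- chol2inv(qr.R(qr_x))
  structure(list(
    feature_id = rownames(M),
    coefficients = coefs,
    s2 = unname(s2),
    df = rep(df, nrow(M)),
    stdev_unscaled = stats::setNames(sqrt(diag(xtx_inv)), colnames(design)),
    mean_abundance = rowMeans(M)), class = "feature_fit")
}

# Invert the trigamma function by Newton iteration (monotone decreasing,
# convex on (0, Inf)); used to solve trigamma(d0/2) = excess variance.
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Estimate moderation hyper-parameters from residual variances
#'
#' Method-of-moments fit of the scaled-F model for the sample variances:
#' `e = log(s2) - digamma(d/2) + log(d/2)` has mean
#' `log(s0^2) - digamma(d0/2) + log(d0/2)` and excess variance
#' `trigamma(d0/2)` beyond `trigamma(d/2)`; d0 follows by trigamma
#' inversion. When the variances are (near) identical the excess is
#' non-positive and the prior is degenerate: `d0 = Inf`,
#' `s0^2 = mean(s2)`.
#'
#' @param s2 residual variances (only finite, positive entries are used
#'   for estimation).
#' @param df residual degrees of freedom (scalar or vector).
#' @return list `d0`, `s02`.
#' @export
squeeze_variances <- function(s2, df) {
  if (length(df) == 1) df <- rep(df, length(s2))
  usable <- is.finite(s2) & df > 0
  if (!any(usable)) stopf("no features with positive residual df")
  # identical sample variances (including all-zero): degenerate prior
  if (diff(range(s2[usable])) <= 1e-12 * max(1, max(abs(s2[usable]))))
    return(list(d0 = Inf, s02 = s2[usable][1]))
  ok <- usable & s2 > 0
  if (sum(ok) < 10) stopf("need >= 10 features with positive residual df and variance")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated t-statistics for one coefficient
#'
#' Shrinks each feature's residual variance toward the estimated prior
#' and tests the named design coefficient with a t distribution on
#' `d0 + d` degrees of freedom.
#'
#' @param fit a `feature_fit` from [fit_linear_model()].
#' @param coef name of the design coefficient to test (e.g. `"sexF"`).
#' @param contrast label recorded in the result table.
#' @param d0 optional prior degrees of freedom override (`0` gives the
#'   classical unmoderated t; `Inf` pools to a common variance).
#' @return list: `params` (`d0`, `s02`), `table` (a `DiffResult`
#'   data.frame: `feature_id`, `contrast`, `effect`, `fc`, `t`, `p`,
#'   `p_adj`, `mean`, `degenerate`).
#' @export
ebayes_moderate <- function(fit, coef = "sexF", contrast = coef, d0 = NULL) {
  stopifnot(inherits(fit, "feature_fit"))
  if (!coef %in% colnames(fit$coefficients))
    stopf("coefficient '%s' not in design (have: %s)", coef,
          paste(colnames(fit$coefficients), collapse = ", "))
  params <- squeeze_variances(fit$s2, fit$df)
  if (!is.null(d0)) {
    params$d0 <- d0
    if (is.infinite(d0)) params$s02 <- mean(fit$s2[is.finite(fit$s2)])
  }
  s2 <- fit$s2
  d <- fit$df
  if (params$d0 == 0) {
    s2_post <- s2
    df_total <- d
  } else if (is.infinite(params$d0)) {
    s2_post <- rep(params$s02, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (params$d0 * params$s02 + d * s2) / (params$d0 + d)
    df_total <- params$d0 + d
  }
  su <- fit$stdev_unscaled[coef]
  effect <- fit$coefficients[, coef]
  se <- su * sqrt(s2_post)
  tstat <- effect / se
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[!is.finite(tstat)] <- NA_real_  # degenerate variance: flagged, not tested
  tab <- data.frame(
    feature_id = fit$feature_id,
    contrast = contrast,
    effect = unname(effect),
    fc = 2^unname(effect),
    t = unname(tstat),
    p = unname(p),
    p_adj = NA_real_,
    mean = unname(fit$mean_abundance),
    degenerate = s2_post == 0 | !is.finite(tstat),
    stringsAsFactors = FALSE)
  tab$p_adj <- bh_adjust(tab$p)
  list(params = params, table = tab)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p p-values in `[0,1]`; `NaN` is an error.
#' @return adjusted p-values (monotone step-up, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) stopf("NaN p-value at position %d", which(is.nan(p))[1])
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Sex contrast at one timepoint
#'
#' Unpaired female-minus-male comparison with the age covariate, variance
#' moderation and BH adjustment. Positive effects mean higher in females.
#'
#' @param mat `omics_matrix` (complete).
#' @param sheet sample sheet covering the matrix columns.
#' @param timepoint timepoint to subset to (`NULL` = all columns).
#' @param covariates design covariates, see [build_design()].
#' @return a moderated result list, see [ebayes_moderate()].
#' @export
sex_contrast <- function(mat, sheet, timepoint = "baseline",
                         covariates = c("sexF", "age")) {
  M <- if (inherits(mat, "omics_matrix")) mat$values else mat
  sheet <- sheet[match(colnames(M), sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) stopf("matrix columns missing from sample sheet")
  if (!is.null(timepoint)) {
    keep <- sheet$timepoint == timepoint
    M <- M[, keep, drop = FALSE]
    sheet <- sheet[keep, ]
  }
  X <- build_design(sheet, covariates)
  fit <- fit_linear_model(M, X)
  ebayes_moderate(fit, coef = "sexF",
                  contrast = sprintf("F_vs_M_%s", timepoint %||% "all"))
}

#' Paired timepoint contrast
#'
#' Within-subject difference between two timepoints: subjects missing
#' either timepoint are dropped (with a logged count); the per-subject
#' difference vector is regressed on an intercept (optionally plus sex),
#' moderated across features, and fold changes reported as `2^effect`.
#'
#' @param mat `omics_matrix` (complete) containing both timepoints.
#' @param sheet sample sheet.
#' @param t_from,t_to timepoints compared as `t_to - t_from`.
#' @param sex restrict to one sex (`"F"`/`"M"`) or `NULL` for all.
#' @param covariates extra covariates for the difference model
#'   (subset of `"sexF"`; age cancels within subject).
#' @return moderated result list; the table's `effect` is the mean
#'   within-subject log2 difference, `fc = 2^effect`; attribute
#'   `n_dropped` counts subjects without both timepoints.
#' @export
paired_contrast <- function(mat, sheet, t_from = "baseline", t_to = "acute",
                            sex = NULL, covariates = NULL) {
  M <- if (inherits(mat, "omics_matrix")) mat$values else mat
  sheet <- sheet[sheet$sample_id %in% colnames(M), ]
  if (!is.null(sex)) sheet <- sheet[sheet$sex == sex, ]
  from <- sheet[sheet$timepoint == t_from, ]
  to <- sheet[sheet$timepoint == t_to, ]
  subj <- intersect(from$subject_id, to$subject_id)
  n_dropped <- length(setdiff(union(from$subject_id, to$subject_id), subj))
  if (length(subj) < 3)
    stopf("paired contrast needs >= 3 complete pairs, got %d", length(subj))
  cols_from <- from$sample_id[match(subj, from$subject_id)]
  cols_to <- to$sample_id[match(subj, to$subject_id)]
  D <- M[, cols_to, drop = FALSE] - M[, cols_from, drop = FALSE]
  colnames(D) <- subj
  dsheet <- from[match(subj, from$subject_id), ]
  dsheet$sample_id <- subj
  X <- build_design(dsheet, covariates = intersect(covariates, "sexF"))
  fit <- fit_linear_model(D, X)
  res <- ebayes_moderate(fit, coef = "intercept",
                         contrast = sprintf("%s_vs_%s%s", t_to, t_from,
                                            if (is.null(sex)) "" else paste0("_", sex)))
  attr(res, "n_dropped") <- n_dropped
  attr(res, "n_pairs") <- length(subj)
  res
}
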