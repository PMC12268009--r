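# Frozen normality fixture: 25 values drawn once from N(10, 1).
# shapiro.test gives p = 0.688 on the fixture and p = 0.0083 on its
# exponential, so the gate must return identity / log respectively.
normal_fixture <- c(
  8.2062, 10.1999, 10.5625, 9.5812, 9.3522, 9.4293, 8.5349, 9.7351,
  11.1577, 10.313, 10.0011, 10.326, 9.857, 10.08, 10.3301, 10.8994,
  11.2373, 10.6947, 10.6726, 10.4864, 9.3451, 11.259, 9.6054, 8.9949,
  9.3623)

test_that("shapiro gate keeps normal data and logs positive non-normal data", {
  expect_equal(as.character(shapiro_gate(normal_fixture)), "identity")
  expect_equal(as.character(shapiro_gate(exp(normal_fixture))), "log")
  expect_error(shapiro_gate(rep(3, 5)), "constant|zero variance")
  expect_error(shapiro_gate(c(1, 2)), ">= 3")
  # non-normal but with non-positive values: identity with a warning record
  x <- -exp(normal_fixture)
  g <- shapiro_gate(x)
  expect_equal(as.character(g), "identity")
  expect_match(attr(g, "warning"), "non-positive")
})

test_that("least-squares fits are exact on noiseless data and match the normal equations", {
  sheet <- toy_sheet(3, 3)
  X <- build_design(sheet, "age")   # intercept + centered age
  y <- 2 * sheet$age + 5
  fit <- fit_linear_model(matrix(y, 1, dimnames = list("f1", sheet$sample_id)), X)
  expect_equal(unname(fit$coefficients[1, "age"]), 2, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients[1, "intercept"]), 5 + 2 * mean(sheet$age),
               tolerance = 1e-12)
  expect_equal(fit$s2[1], 0, tolerance = 1e-20)

  # 6-sample toy vs brute-force normal equations solve(X'X) X'y
  set.seed(11)
  X2 <- build_design(sheet)
  Y <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(paste0("f", 1:4), sheet$sample_id))
  fit2 <- fit_linear_model(Y, X2)
  oracle <- t(solve(crossprod(X2), t(X2) %*% t(Y)))
  expect_lt(max(abs(fit2$coefficients - oracle)), 1e-10)
  # residual variance against the direct definition
  res <- Y - fit2$coefficients %*% t(X2)
  expect_equal(fit2$s2, unname(rowSums(res^2) / (6 - 3)), tolerance = 1e-12)

  X_bad <- cbind(X2, dup = X2[, "sexF"])
  expect_error(fit_linear_model(Y, X_bad), "rank deficient")
  expect_error(fit_linear_model(Y[, 1:5], X2), "dimension mismatch|sample order")
})

test_that("moderated t collapses to the classical t when variances are shared or d0 = 0", {
  sheet <- toy_sheet(4, 4)
  X <- build_design(sheet, "sexF")
  set.seed(21)
  Y <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(sprintf("f%02d", 1:30), sheet$sample_id))
  fit <- fit_linear_model(Y, X)

  # d0 forced to 0: exactly the classical two-sample pooled-variance t
  res0 <- ebayes_moderate(fit, "sexF", d0 = 0)
  classical_t <- vapply(seq_len(30), function(i) {
    unname(stats::t.test(Y[i, sheet$sex == "F"], Y[i, sheet$sex == "M"],
                         var.equal = TRUE)$statistic)
  }, 0)
  expect_equal(res0$table$t, classical_t, tolerance = 1e-10)

  # identical variances: shrinkage to a point; moderated t = ordinary t
  # computed with the common variance
  fit_eq <- fit
  fit_eq$s2 <- rep(0.7, 30)
  res_eq <- ebayes_moderate(fit_eq, "sexF")
  expect_true(is.infinite(res_eq$params$d0))
  expect_equal(res_eq$params$s02, 0.7)
  manual_t <- fit$coefficients[, "sexF"] / (fit$stdev_unscaled["sexF"] * sqrt(0.7))
  expect_equal(res_eq$table$t, unname(manual_t), tolerance = 1e-12)
})

test_that("moment-matching recovers planted moderation hyper-parameters", {
  set.seed(9)
  d0 <- 4; s02 <- 1; d <- 10; n <- 5000
  sigma2 <- s02 * d0 / rchisq(n, d0)         # inverse-chi-square prior
  s2 <- sigma2 * rchisq(n, d) / d            # sampling variances
  est <- squeeze_variances(s2, d)
  expect_gt(est$d0, 3); expect_lt(est$d0, 5)
  expect_gt(est$s02, 0.9); expect_lt(est$s02, 1.1)
})

test_that("moderated statistics agree with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  sheet <- toy_sheet(5, 5)
  X <- build_design(sheet)
  set.seed(31)
  sigma2 <- 1 * 4 / rchisq(400, 4)
  Y <- matrix(rnorm(400 * 10, sd = rep(sqrt(sigma2), 10)), 400, 10,
              dimnames = list(sprintf("f%03d", 1:400), sheet$sample_id))
  mine <- ebayes_moderate(fit_linear_model(Y, X), "sexF")
  ref <- limma::eBayes(limma::lmFit(Y, X))
  expect_equal(mine$params$d0, ref$df.prior, tolerance = 1e-9)
  expect_equal(mine$params$s02, ref$s2.prior, tolerance = 1e-9)
  expect_equal(mine$table$t, unname(ref$t[, "sexF"]), tolerance = 1e-9)
  expect_equal(mine$table$p, unname(ref$p.value[, "sexF"]), tolerance = 1e-9)
})

test_that("BH adjustment matches the hand-enumerated step-up rule and its contract", {
  # m = 3: p(3)*3/3 = 0.03; p(2)*3/2 = 0.03; p(1)*3/1 = 0.03; cummin -> all 0.03
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    a <- bh_adjust(p)
    expect_true(all(a >= p) && all(a <= 1))
    expect_true(all(diff(a[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
  expect_error(bh_adjust(c(0.1, 1.7)), "\\[0,1\\]")
})

test_that("paired contrasts equal the brute-force mean difference and beat unpaired variance", {
  sheet <- toy_sheet(3, 2, c("baseline", "acute"))
  ids_b <- sheet$sample_id[sheet$timepoint == "baseline"]
  ids_a <- sheet$sample_id[sheet$timepoint == "acute"]
  set.seed(51)
  subj_eff <- rnorm(5, 0, 3)                 # strong subject intercepts
  base <- outer(rep(1, 10), subj_eff) + matrix(rnorm(50, sd = 0.3), 10)
  acute <- base + 1 + matrix(rnorm(50, sd = 0.3), 10)
  M <- cbind(base, acute)
  dimnames(M) <- list(sprintf("f%02d", 1:10), c(ids_b, ids_a))
  om <- omics_matrix(M, "transcript_log2")

  res <- paired_contrast(om, sheet, "baseline", "acute")
  brute <- rowMeans(M[, ids_a] - M[, ids_b])
  expect_equal(res$table$effect, unname(brute), tolerance = 1e-12)
  expect_equal(res$table$fc, unname(2^brute), tolerance = 1e-12)

  # within-subject correlation: the paired residual variance is smaller
  # than treating the timepoints as independent groups
  X_unp <- cbind(intercept = rep(1, 10), acute = rep(c(0, 1), each = 5))
  rownames(X_unp) <- colnames(M)
  fit_unp <- fit_linear_model(M, X_unp)
  s2_paired <- apply(M[, ids_a] - M[, ids_b], 1, var)
  expect_true(all(s2_paired < fit_unp$s2))
})

test_that("degenerate paired differences are flagged rather than tested", {
  sheet <- toy_sheet(2, 2, c("baseline", "trained"))
  ids_b <- sheet$sample_id[sheet$timepoint == "baseline"]
  ids_t <- sheet$sample_id[sheet$timepoint == "trained"]
  M <- matrix(5, 3, 8, dimnames = list(paste0("f", 1:3), c(ids_b, ids_t)))
  M[, ids_t] <- M[, ids_b] + 1               # identical +1 shift per subject
  om <- omics_matrix(M, "protein_log")
  res <- paired_contrast(om, sheet, "baseline", "trained")
  expect_equal(res$table$effect, rep(1, 3))
  expect_equal(res$table$fc, rep(2, 3))
  expect_true(all(res$table$degenerate))
  expect_true(all(is.na(res$table$p)))

  # identical timepoints: zero effect, unit fold change
  M2 <- M; M2[, ids_t] <- M2[, ids_b]
  set.seed(3); M2 <- M2 + matrix(0, 3, 8)
  M2[1:3, ids_b] <- matrix(rnorm(12), 3)
  M2[, ids_t] <- M2[, ids_b]
  res2 <- paired_contrast(omics_matrix(M2, "protein_log"), sheet, "baseline", "trained")
  expect_equal(res2$table$effect, rep(0, 3))
  expect_equal(res2$table$fc, rep(1, 3))

  expect_error(paired_contrast(om, sheet[sheet$subject_id %in% c("s01", "s02"), ],
                               "baseline", "trained"), ">= 3")
})

test_that("sex effects stay unbiased under the age confounder when age is modeled", {
  # age is planted on every transcript and the sexes differ in age;
  # with the covariate the sex-effect estimates center on the truth
  sim <- simulate_cohort(small_config(seed = 13, age_beta_txn = 0.05))
  res <- sex_contrast(sim$transcriptome, sim$sheet, "baseline")
  tr <- sim$truth$de_gene
  est <- res$table$effect[match(tr$gene, res$table$feature_id)]
  expect_lt(abs(mean(est - tr$lfc)), 0.1)
  # null genes centered on zero
  null_est <- res$table$effect[!res$table$feature_id %in% tr$gene]
  expect_lt(abs(mean(null_est)), 0.05)
})
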