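test_that("total-amount normalization equalizes observed column totals", {
  m <- matrix(c(4, 6, 8, 12), nrow = 2,
              dimnames = list(c("p1", "p2"), c("sA", "sB")))
  om <- omics_matrix(m, "protein_raw")
  norm <- total_amount_normalize(om)
  expect_equal(unname(attr(norm, "scale_factors")), c(1.5, 0.75))
  expect_equal(unname(colSums(norm$values)), c(15, 15))

  # already equal totals: identity
  m2 <- matrix(c(1, 9, 4, 6), nrow = 2, dimnames = dimnames(m))
  norm2 <- total_amount_normalize(omics_matrix(m2, "protein_raw"))
  expect_equal(norm2$values, m2)

  # random matrix with missing cells: totals equal to 1e-9 relative
  set.seed(61)
  m3 <- matrix(runif(20, 1, 100), 5, 4,
               dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  m3[cbind(c(1, 3), c(2, 4))] <- NA
  norm3 <- total_amount_normalize(omics_matrix(m3, "protein_raw"))
  tot <- colSums(norm3$values, na.rm = TRUE)
  expect_lt(diff(range(tot)) / mean(tot), 1e-9)
  expect_identical(is.na(norm3$values), is.na(m3))

  m4 <- m2; m4[, 1] <- 0
  expect_error(total_amount_normalize(omics_matrix(m4, "protein_raw")), "zero observed total")
})

test_that("completeness filter keeps a feature on an inclusive per-group boundary", {
  sheet <- toy_sheet(5, 5, c("baseline", "trained"))   # groups of 5 per sex x tp
  ids <- sheet$sample_id
  m <- matrix(1, 3, 20, dimnames = list(c("kept_boundary", "dropped", "kept_all"), ids))
  grp <- paste(sheet$sex, sheet$timepoint, sep = ".")
  # boundary feature: observed in 9 of 10 female samples (>= 0.9 in
  # neither single group of 5... use explicit groups of 10 by sex)
  m["kept_boundary", sheet$sex == "M"] <- NA
  m["kept_boundary", which(sheet$sex == "F")[1]] <- NA       # 9/10 in F
  m["dropped", ] <- NA
  m["dropped", c(which(sheet$sex == "F")[1:8], which(sheet$sex == "M")[1:8])] <- 1  # 8/10 each
  om <- omics_matrix(m, "protein_raw")
  filt <- filter_by_completeness(om, sheet, groups = sheet$sex, threshold = 0.90)
  expect_setequal(rownames(filt$values), c("kept_boundary", "kept_all"))
  dec <- attr(filt, "decisions")
  expect_equal(dec$best_group_completeness[dec$feature_id == "kept_boundary"], 0.9)
  expect_false(dec$kept[dec$feature_id == "dropped"])

  # threshold 0 is vacuous
  all_kept <- filter_by_completeness(om, sheet, threshold = 0)
  expect_equal(nrow(all_kept$values), 3)
})

test_that("downshift imputation draws from the stated shifted normal", {
  # one column with known observed moments, 10^4 missing cells
  set.seed(71)
  n_obs <- 2000; n_miss <- 10000
  obs <- rnorm(n_obs, 20, 2)
  col <- c(obs, rep(NA, n_miss))
  m <- matrix(col, ncol = 1, dimnames = list(sprintf("p%05d", seq_along(col)), "sA"))
  om <- omics_matrix(m, "protein_log")
  imp <- impute_downshift(om, impute_spec(seed = 99))
  filled <- imp$values[is.na(m)]
  mu <- mean(obs); sg <- sd(obs)
  expect_lt(abs(mean(filled) - (mu - 1.5 * sg)), 0.05)
  expect_lt(abs(sd(filled) - 0.5 * sg), 0.05)
  # observed cells untouched
  expect_identical(imp$values[!is.na(m)], m[!is.na(m)])
  expect_equal(attr(imp, "n_imputed"), n_miss)

  # determinism and identity contracts
  imp2 <- impute_downshift(om, impute_spec(seed = 99))
  expect_identical(imp$values, imp2$values)
  complete <- omics_matrix(matrix(1:6 + 0.5, 2, 3,
                                  dimnames = list(c("a", "b"), c("x", "y", "z"))),
                           "protein_log")
  expect_identical(impute_downshift(complete, impute_spec(seed = 1))$values,
                   complete$values)
})

test_that("imputed values sit below the observed mean and preserve observed ranks", {
  sim <- simulate_cohort(small_config(seed = 17))
  prep <- prep_proteome(sim$proteome, sim$sheet)
  imp <- prep$matrix
  mask <- attr(imp, "imputed_mask")
  expect_false(anyNA(imp$values))
  # property of N(mu - 1.5 sigma, (0.5 sigma)^2): < mu in >= 97% of draws
  below <- vapply(seq_len(ncol(imp$values)), function(j) {
    mj <- mask[, j]
    if (!any(mj)) return(NA_real_)
    mu <- mean(imp$values[!mj, j])
    mean(imp$values[mj, j] < mu)
  }, 0)
  expect_gte(mean(below, na.rm = TRUE), 0.97)
  # imputation leaves observed cells (hence their within-column ranks)
  # bitwise unchanged: rebuild the chain up to the log step and compare
  lg <- log2_protein(total_amount_normalize(
    filter_by_completeness(sim$proteome, sim$sheet)))
  expect_identical(imp$values[!mask], lg$values[!mask])
  expect_gt(prep$report$n_imputed, 0)
  expect_lt(prep$report$frac_imputed, 0.2)
})

test_that("per-sample scope falls back to global when columns are too sparse", {
  m <- matrix(c(1, 2, NA, NA, NA, 21, 20, 22, 19, 23), ncol = 2,
              dimnames = list(paste0("p", 1:5), c("sparse", "dense")))
  om <- omics_matrix(m, "protein_log")
  expect_warning(imp <- impute_downshift(om, impute_spec(seed = 5)), "global scope")
  expect_false(anyNA(imp$values))
})
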