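test_that("fit index formulas reproduce a reference three-level fit table", {
  # chi-square and df as reported for a dyscalculia screening cohort
  # (N = 4527); the RMSEA column must come back to 2 decimals
  printed <- data.frame(chisq = c(731.95, 2821.77, 738.45),
                        df = c(71, 79, 79),
                        rmsea = c(0.045, 0.088, 0.043))
  for (i in 1:3) {
    fi <- fit_indices(printed$chisq[i], printed$df[i],
                      chisq_baseline = 2e4, df_baseline = 84, N = 4527)
    expect_lt(abs(fi$rmsea - printed$rmsea[i]), 5e-4)
  }
  # perfect fit: chisq = df
  fi0 <- fit_indices(50, 50, 500, 84, 1000)
  expect_equal(fi0$rmsea, 0)
  expect_equal(fi0$cfi, 1)
  # CFI stays in [0, 1] over random admissible inputs
  set.seed(4)
  for (r in 1:50) {
    chisq <- runif(1, 0, 300); df <- sample(1:50, 1)
    cb <- runif(1, 0, 400); db <- sample(1:50, 1)
    cfi <- fit_indices(chisq, df, cb, db, 500)$cfi
    expect_gte(cfi, 0); expect_lte(cfi, 1)
  }
  expect_error(fit_indices(10, 5, 20, 0, 100), "baseline df")
})

test_that("factor ICCs decompose the common-factor variance", {
  icc <- factor_icc(1, 0.56, 0.003)
  expect_equal(round(icc$icc_level2, 3), 0.358)
  expect_equal(round(icc$icc_level3, 3), 0.002)
  expect_equal(factor_icc(1, 0, 0), list(icc_level2 = 0, icc_level3 = 0))
  icc3 <- factor_icc(1, 1, 1)
  expect_equal(icc3$icc_level2, 1 / 3)
  expect_equal(icc3$icc_level3, 1 / 3)
  # shares plus the implicit Level-1 share sum to one
  set.seed(8)
  for (r in 1:20) {
    v <- runif(3, 0.01, 2)
    icc <- factor_icc(v[1], v[2], v[3])
    expect_equal(icc$icc_level2 + icc$icc_level3 + v[1] / sum(v), 1)
  }
  expect_error(factor_icc(0, 0, 0), "zero")
  expect_error(factor_icc(1, -0.1), ">= 0")
})

test_that("bias proportions divide residual by implied level and total variance", {
  # worked decomposition: implied Level-2 variance 0.28 of which residual
  # 0.02 -> proportion 0.071 at 3 decimals
  spec <- model_spec(list(
    fixed_level(1, lambda = rep(1, 3), phi_var = 1, theta = rep(0.5, 3)),
    fixed_level(2, lambda = rep(1, 3), phi_var = 0.26,
                theta = rep(0.02, 3)),
    fixed_level(3, lambda = rep(1, 3), phi_var = 0.1, theta = rep(0, 3))),
    intercepts = clusterbias:::fixed_pattern(matrix(0, 3, 1)))
  bp <- bias_proportions(fixed_fit(spec), level = 2)
  expect_equal(round(bp$prop_within_level, 3), rep(0.071, 3))
  expect_equal(bp$prop_total,
               rep(0.02 / (1.5 + 0.28 + 0.1), 3), tolerance = 1e-12)

  # zero residual -> zero proportions; simple closed form otherwise
  spec2 <- model_spec(list(
    fixed_level(1, rep(0.5, 3), 1, rep(0.3, 3)),
    fixed_level(2, rep(0.5, 3), 0.4, rep(0.05, 3))),
    intercepts = clusterbias:::fixed_pattern(matrix(0, 3, 1)))
  bp2 <- bias_proportions(fixed_fit(spec2), level = 2)
  expect_equal(bp2$prop_within_level, rep(0.05 / 0.15, 3),
               tolerance = 1e-12)
  spec3 <- model_spec(list(
    fixed_level(1, rep(0.5, 3), 1, rep(0.3, 3)),
    fixed_level(2, rep(0.5, 3), 0.4, rep(0, 3))),
    intercepts = clusterbias:::fixed_pattern(matrix(0, 3, 1)))
  bp3 <- bias_proportions(fixed_fit(spec3), level = 2)
  expect_equal(bp3$prop_within_level, rep(0, 3))
  expect_equal(bp3$prop_total, rep(0, 3))
})

test_that("observed ICCs are variance shares per indicator", {
  spec <- model_spec(list(
    fixed_level(1, rep(0, 2), 1, rep(3, 2)),
    fixed_level(2, rep(0, 2), 1, rep(1, 2)),
    fixed_level(3, rep(0, 2), 1, rep(1, 2))),
    intercepts = clusterbias:::fixed_pattern(matrix(0, 2, 1)))
  icc <- observed_icc(fixed_fit(spec))
  expect_equal(icc$icc_level2, rep(0.2, 2))
  expect_equal(icc$icc_level3, rep(0.2, 2))
  spec0 <- model_spec(list(
    fixed_level(1, rep(0, 2), 1, rep(3, 2)),
    fixed_level(2, rep(0, 2), 1, rep(0, 2)),
    fixed_level(3, rep(0, 2), 1, rep(0, 2))),
    intercepts = clusterbias:::fixed_pattern(matrix(0, 2, 1)))
  icc0 <- observed_icc(fixed_fit(spec0))
  expect_equal(unlist(icc0[, 2:3], use.names = FALSE), rep(0, 4))
})

test_that("chi-square statistics and difference tests are coherent", {
  d <- simulation_design(n_schools = 40, classes_per_school = 3,
                         students_per_class = 10,
                         loadings = rep(0.7, 4), phi = c(1, 0.3, 0.1),
                         resid1 = 0.5, resid2 = 0.15, resid3 = 0)
  st <- compute_sufficient_stats(simulate_dataset(d, seed = 51))
  mods <- build_cluster_bias_models(4)
  f_base <- fit_ml(mods$baseline, st)
  f_l2 <- fit_ml(mods$level2_constrained, st)
  f_sat <- fit_saturated(st)

  mc_sat <- model_chisq(f_sat, f_sat)
  expect_equal(mc_sat$chisq, 0)
  expect_equal(mc_sat$df, 0)

  mc <- model_chisq(f_base, f_sat)
  expect_gte(mc$chisq, 0)
  expect_equal(mc$df, 12)

  same <- chisq_difference(f_base, f_base)
  expect_equal(same$delta_chisq, 0)
  expect_equal(same$delta_df, 0)
  expect_equal(same$p_value, 1)

  dd <- chisq_difference(f_l2, f_base)
  expect_equal(dd$delta_df, 4)
  expect_match(dd$note, "conservative")
  expect_error(chisq_difference(f_base, f_l2), "not nested")

  # mismatched data are refused
  st2 <- compute_sufficient_stats(simulate_dataset(d, seed = 52))
  f_other <- fit_ml(mods$baseline, st2)
  expect_error(model_chisq(f_other, f_sat), "same data")
})

test_that("mean model chi-square is near its df under a correct model", {
  d <- simulation_design(n_schools = 30, classes_per_school = 3,
                         students_per_class = 10,
                         loadings = rep(0.7, 3), phi = c(1, 0.3, 0.1),
                         resid1 = 0.5, resid2 = 0.08, resid3 = 0.05)
  spec <- build_cluster_bias_models(3)$baseline
  chis <- vapply(1:12, function(r) {
    st <- compute_sufficient_stats(simulate_dataset(d, seed = 600 + r))
    model_chisq(fit_ml(spec, st), fit_saturated(st))$chisq
  }, numeric(1))
  df <- degrees_of_freedom(spec)
  # mean of chi-square(df) has SD sqrt(2*df/M); allow 3 of those
  expect_lt(abs(mean(chis) - df), 3 * sqrt(2 * df / length(chis)) + 1)
})

test_that("the cluster-bias sequence detects injected class-level bias only", {
  d <- simulation_design(n_schools = 60, classes_per_school = 3,
                         students_per_class = 15,
                         loadings = rep(0.7, 4), phi = c(1, 0.3, 0.1),
                         resid1 = 0.5, resid2 = 0.25, resid3 = 0)
  dat <- simulate_dataset(d, seed = 5)
  rep <- cluster_bias_test(dat)
  expect_true(all(rep$fit_table$converged))
  expect_equal(rep$tests$level2$verdict, "bias detected")
  expect_equal(rep$tests$level3$verdict, "no bias detected")
  expect_equal(rep$tests$level2$delta_df, 4)
  expect_equal(rep$fit_table$df, c(12, 16, 16))

  # Wald tests at Level 2 see the (large, every-indicator) injected bias
  w2 <- rep$wald$level2
  expect_gte(sum(w2$significant, na.rm = TRUE), 3)

  # with alpha close to 1 any positive difference is flagged
  rep_a <- cluster_bias_test(dat, alpha = 0.999)
  expect_equal(rep_a$tests$level2$verdict, "bias detected")
  expect_equal(rep_a$tests$level3$verdict,
               if (rep_a$tests$level3$delta_chisq > 0) "bias detected"
               else "no bias detected")

  # factor ICC comes from the estimated level-wise factor variances
  expect_gt(rep$factor_icc$icc_level2, 0.05)
  expect_lt(rep$factor_icc$icc_level3, 0.3)
  # printing renders the full report
  expect_output(print(rep), "delta chi-square")
})

test_that("two-level data yield a Level-2-only report", {
  d <- simulation_design(n_schools = 80, classes_per_school = 1,
                         students_per_class = 12,
                         loadings = rep(0.7, 3), phi = c(1, 0.3),
                         resid1 = 0.5, resid2 = 0)
  dat <- simulate_dataset(d, seed = 9)
  expect_equal(dat$n_levels, 2L)
  rep <- cluster_bias_test(dat)
  expect_null(rep$tests$level3)
  expect_equal(nrow(rep$fit_table), 2)
  expect_true(is.character(rep$tests$level2$verdict))
})

test_that("Wald tests flag a single strongly biased indicator", {
  d <- simulation_design(n_schools = 80, classes_per_school = 3,
                         students_per_class = 15,
                         loadings = rep(0.7, 4), phi = c(1, 0.3, 0.05),
                         resid1 = 0.5, resid2 = c(0.5, 0, 0, 0),
                         resid3 = 0)
  spec <- build_cluster_bias_models(4)$baseline
  f <- standard_errors(fit_ml(spec, simulate_dataset(d, seed = 71)))
  w <- residual_variance_wald(f, level = 2)
  expect_true(w$significant[1])
  # boundary-pinned estimates are flagged, not tested
  expect_true(all(is.na(w$p_value[w$boundary])))
  # z is estimate / se where defined
  i <- which(!is.na(w$z))[1]
  expect_equal(w$z[i], w$estimate[i] / w$se[i])
})
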