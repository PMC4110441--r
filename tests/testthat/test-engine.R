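test_that("implied moments follow the level-wise factor structure", {
  # lambda = (1, 1)', phi = 1, theta = I  =>  Sigma = [[2, 1], [1, 2]]
  lv <- lapply(1:2, function(m) clusterbias:::level_model(m,
    lambda = clusterbias:::fixed_pattern(matrix(c(1, 1), ncol = 1)),
    phi = clusterbias:::fixed_pattern(matrix(1, 1, 1)),
    theta = clusterbias:::fixed_pattern(matrix(1, 2, 1))))
  spec <- model_spec(lv, intercepts = clusterbias:::fixed_pattern(
    matrix(0, 2, 1)))
  mom <- implied_moments(spec, numeric(0))
  expect_equal(mom$sigma[[1]], matrix(c(2, 1, 1, 2), 2))

  # zero loadings, identity residuals => identity
  lv0 <- lapply(1:2, function(m) clusterbias:::level_model(m,
    lambda = clusterbias:::fixed_pattern(matrix(0, 3, 1)),
    phi = clusterbias:::fixed_pattern(matrix(1, 1, 1)),
    theta = clusterbias:::fixed_pattern(matrix(1, 3, 1))))
  spec0 <- model_spec(lv0, intercepts = clusterbias:::fixed_pattern(
    matrix(0, 3, 1)))
  expect_equal(implied_moments(spec0, numeric(0))$sigma[[2]], diag(3))

  # with Level-3 residuals fixed at zero, Sigma_3 = Lambda Phi_3 Lambda'
  # has rank at most the number of factors
  spec <- build_cluster_bias_models(6, list(c(1, 2)))$level3_constrained
  th <- clusterbias:::moment_starts(
    spec, compute_sufficient_stats(tiny_data(2, p = 6)),
    clusterbias:::spec_index(spec))
  S3 <- implied_moments(spec, th)$sigma[[3]]
  expect_lte(qr(S3)$rank, 2)
})

test_that("structured loglik equals the stacked-normal oracle on random instances", {
  n_bad <- 0
  for (r in 1:30) {
    set.seed(r)
    dat <- tiny_data(seed = r)
    st <- compute_sufficient_stats(dat)
    mom <- random_moments(4)
    a <- multilevel_loglik(st, mom)
    b <- naive_stacked_loglik(dat, mom$mu, mom$sigma)
    if (abs(a - b) > 1e-8 * max(1, abs(b))) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("loglik collapses, permutes and rescales as the model demands", {
  # single school, class and student: plain p-variate normal at the total
  # covariance
  one <- preprocess(data.frame(s = "a", c = "b", y1 = 0.3, y2 = -1.2),
                    "s", "c", c("y1", "y2"))
  st1 <- compute_sufficient_stats(one)
  set.seed(5)
  mom <- random_moments(2)
  tot <- Reduce(`+`, mom$sigma)
  r <- c(0.3, -1.2) - mom$mu
  U <- chol(tot)
  direct <- -0.5 * (2 * log(2 * pi) + 2 * sum(log(diag(U))) +
                      sum(backsolve(U, r, transpose = TRUE)^2))
  expect_equal(multilevel_loglik(st1, mom), direct, tolerance = 1e-12)

  # permuting rows within classes leaves the likelihood unchanged
  dat <- tiny_data(seed = 9)
  set.seed(1)
  perm <- sample(nrow(dat$Y))
  datp <- dat
  datp$Y <- dat$Y[perm, , drop = FALSE]
  datp$school <- dat$school[perm]
  datp$class <- dat$class[perm]
  mom <- random_moments(4)
  expect_equal(multilevel_loglik(compute_sufficient_stats(datp), mom),
               multilevel_loglik(compute_sufficient_stats(dat), mom),
               tolerance = 1e-10)

  # scale equivariance: y -> c*y shifts loglik by -N*p*log(c) and scales
  # the matching covariance matrices by c^2
  cc <- 2.5
  datc <- dat
  datc$Y <- dat$Y * cc
  momc <- list(mu = mom$mu * cc, sigma = lapply(mom$sigma, `*`, cc^2))
  expect_equal(multilevel_loglik(compute_sufficient_stats(datc), momc),
               multilevel_loglik(compute_sufficient_stats(dat), mom) -
                 nrow(dat$Y) * 4 * log(cc),
               tolerance = 1e-8)
})

test_that("a three-level model with Sigma3 = 0 matches the two-level likelihood", {
  dat3 <- tiny_data(seed = 13)
  dat2 <- dat3
  dat2$school <- dat3$class  # classes become the only clustering
  dat2$n_levels <- 2L
  set.seed(2)
  mom <- random_moments(4)
  mom3 <- list(mu = mom$mu,
               sigma = list(mom$sigma[[1]], mom$sigma[[2]],
                            matrix(0, 4, 4)))
  mom2 <- list(mu = mom$mu, sigma = mom$sigma[1:2])
  expect_equal(multilevel_loglik(compute_sufficient_stats(dat3), mom3),
               multilevel_loglik(compute_sufficient_stats(dat2), mom2),
               tolerance = 1e-10)
})

test_that("ML fits recover generating parameters and respect nesting", {
  d <- simulation_design(n_schools = 60, classes_per_school = 3,
                         students_per_class = 12,
                         loadings = c(0.8, 0.6, 0.7, 0.9),
                         phi = c(1, 0.3, 0.1),
                         resid1 = 0.5, resid2 = 0.1, resid3 = 0.05)
  dat <- simulate_dataset(d, seed = 21)
  st <- compute_sufficient_stats(dat)
  mods <- build_cluster_bias_models(4)
  f_base <- fit_ml(mods$baseline, st)
  f_l2 <- fit_ml(mods$level2_constrained, st)
  f_sat <- fit_saturated(st)
  f_ind <- fit_independence(st)
  expect_true(f_base$converged)
  expect_true(f_sat$converged)

  lam <- coef(f_base)[paste0("lambda_", 1:4)]
  expect_lt(max(abs(lam - d$loadings)), 0.15)  # single replicate, 60 schools

  # monotonicity under nesting
  expect_gte(f_sat$loglik, f_base$loglik - 1e-6)
  expect_gte(f_base$loglik, f_l2$loglik - 1e-6)
  expect_gte(f_sat$loglik, f_ind$loglik - 1e-6)

  # saturated Sigma1 estimate close to the generating Sigma1
  S1_hat <- implied_moments(f_sat$spec, coef(f_sat))$sigma[[1]]
  expect_lt(max(abs(S1_hat - design_implied_sigma(d)[[1]])), 0.12)
})

test_that("analytic gradients match numerical differentiation", {
  spec <- build_cluster_bias_models(4, list(c(1, 2)))$baseline
  st <- compute_sufficient_stats(tiny_data(seed = 3))
  ix <- clusterbias:::spec_index(spec)
  th <- clusterbias:::moment_starts(spec, st, ix)
  mom <- implied_moments(spec, th)
  core <- clusterbias:::loglik_core(st, mom$mu, mom$sigma, want_grad = TRUE)
  core$mats <- lapply(1:3, function(m) {
    L <- ix$levels[[m]]
    list(Lam = clusterbias:::fill_pattern(L$lambda_tmpl, L$lambda_idx, th),
         Phi = clusterbias:::fill_pattern(L$phi_tmpl, L$phi_idx, th))
  })
  g_an <- clusterbias:::param_gradient(core, ix, 3)
  f <- function(t) multilevel_loglik(st, implied_moments(spec, t))
  g_num <- vapply(seq_along(th), function(j) {
    h <- 1e-6 * max(1, abs(th[j]))
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g_an - g_num)), 1e-5)
})

test_that("balanced one-way variance components match the closed-form ML", {
  # p = 1, two-level balanced design: the ML residual variance is
  # SSW / (N - C) and the between variance is B/C - sigma2_e/n
  set.seed(77)
  Cn <- 40; n <- 8
  b <- rnorm(Cn, 0, sqrt(0.7))
  y <- rnorm(Cn * n, 5 + rep(b, each = n), sqrt(1.3))
  tab <- data.frame(cls = rep(seq_len(Cn), each = n), y = y)
  dat <- preprocess(tab, school_col = NULL, class_col = "cls",
                    indicator_cols = "y")
  f <- fit_saturated(dat)
  expect_true(f$converged)
  ybar_c <- tapply(y, tab$cls, mean)
  ssw <- sum((y - rep(ybar_c, each = n))^2)
  sigma_e <- ssw / (Cn * n - Cn)
  tau <- mean((ybar_c - mean(y))^2) - sigma_e / n
  est <- coef(f)
  expect_equal(unname(est["s_l1_1_1"]), sigma_e, tolerance = 1e-4)
  expect_equal(unname(est["s_l2_1_1"]), tau, tolerance = 1e-4)
  expect_equal(unname(est["nu_1"]), mean(y), tolerance = 1e-6)
})

test_that("higher-level residuals pile at the zero boundary under the null", {
  d <- simulation_design(n_schools = 40, classes_per_school = 3,
                         students_per_class = 8,
                         loadings = rep(0.7, 3), phi = c(1, 0.3, 0.1),
                         resid1 = 0.5, resid2 = 0.1, resid3 = 0)
  spec <- build_cluster_bias_models(3)$baseline
  med <- vapply(1:10, function(r) {
    f <- fit_ml(spec, simulate_dataset(d, seed = 400 + r))
    stats::median(coef(f)[paste0("theta_l3_", 1:3)])
  }, numeric(1))
  expect_equal(stats::median(med), 0, tolerance = 1e-4)
})

test_that("standard errors behave like observed-information estimates", {
  d <- simulation_design(n_schools = 50, classes_per_school = 3,
                         students_per_class = 10,
                         loadings = rep(0.7, 3), phi = c(1, 0.3, 0.15),
                         resid1 = 0.5, resid2 = 0.1, resid3 = 0.1)
  spec <- build_cluster_bias_models(3)$baseline
  f1 <- standard_errors(fit_ml(spec, simulate_dataset(d, seed = 31)))
  pt <- f1$partable
  expect_true(all(is.finite(pt$se[!pt$boundary])))
  expect_true(all(pt$se[!pt$boundary] > 0))

  # quadrupling the number of schools roughly halves the SE of the
  # school-level factor variance
  d4 <- d; d4$n_schools <- 200
  d4$classes_per_school <- rep_len(d$classes_per_school, 200)
  f4 <- standard_errors(fit_ml(spec, simulate_dataset(d4, seed = 31)))
  se1 <- f1$partable$se[f1$partable$label == "phi_g_l3"]
  se4 <- f4$partable$se[f4$partable$label == "phi_g_l3"]
  expect_lt(se4, se1 * 0.8)
  expect_gt(se4, se1 * 0.25)
})

test_that("nonconvergence is reported, never silent", {
  # 2 schools cannot identify a saturated school-level covariance: expect a
  # fit object with converged = FALSE or boundary flags, not a crash
  d <- simulation_design(n_schools = 2, classes_per_school = 2,
                         students_per_class = 3,
                         loadings = rep(0.7, 4), phi = c(1, 0.3, 0.1),
                         resid1 = 0.5)
  f <- fit_saturated(simulate_dataset(d, seed = 8),
                     options = fit_options(restarts = 1))
  expect_s3_class(f, "cb_fit")
  expect_true(is.logical(f$converged))
  expect_error(standard_errors(
    structure(modifyList(f, list(converged = FALSE)), class = "cb_fit")),
    "converged")
})
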