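# Brute-force oracle: the log-density of each school's stacked observation
# vector under the full block covariance matrix, built row by row.  Kept
# deliberately independent of the package's sufficient-statistic reduction.
naive_stacked_loglik <- function(dat, mu, sigma) {
  p <- ncol(dat$Y)
  S3 <- if (length(sigma) >= 3) sigma[[3]] else matrix(0, p, p)
  ll <- 0
  for (s in unique(dat$school)) {
    rows <- which(dat$school == s)
    n <- length(rows)
    cls <- dat$class[rows]
    V <- matrix(0, n * p, n * p)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      blk_i <- (i - 1) * p + seq_len(p)
      blk_j <- (j - 1) * p + seq_len(p)
      B <- S3
      if (cls[i] == cls[j]) B <- B + sigma[[2]]
      if (i == j) B <- B + sigma[[1]]
      V[blk_i, blk_j] <- B
    }
    r <- as.vector(t(dat$Y[rows, , drop = FALSE])) - rep(mu, n)
    U <- chol(V)
    z <- backsolve(U, r, transpose = TRUE)
    ll <- ll - 0.5 * (n * p * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2))
  }
  ll
}

# random admissible level-wise covariance matrices
random_moments <- function(p) {
  rand_psd <- function(scale) {
    A <- matrix(rnorm(p * p), p)
    crossprod(A) * scale / p
  }
  list(mu = rnorm(p),
       sigma = list(rand_psd(1) + diag(p) * 0.3, rand_psd(0.4),
                    rand_psd(0.2)))
}

# small unbalanced three-level dataset
tiny_data <- function(seed, p = 4) {
  d <- simulation_design(n_schools = 3, classes_per_school = c(2, 1, 3),
                         students_per_class = c(2, 3, 1, 4, 2, 3),
                         loadings = runif(p, 0.4, 0.9),
                         phi = c(1, 0.3, 0.2),
                         resid1 = runif(p, 0.3, 0.8),
                         resid2 = runif(p, 0, 0.3),
                         resid3 = runif(p, 0, 0.2))
  simulate_dataset(d, seed = seed)
}

# a cb_fit-like object from a fully fixed specification, for closed-form
# checks of the moment-based summaries
fixed_fit <- function(spec) {
  pt <- parameter_table(spec)
  pt$estimate <- rep(NA_real_, nrow(pt))
  pt$se <- rep(NA_real_, nrow(pt))
  pt$boundary <- rep(FALSE, nrow(pt))
  structure(list(spec = spec,
                 estimates = setNames(numeric(0), character(0)),
                 partable = pt,
                 stats = list(indicator_names = spec$indicator_names),
                 converged = TRUE,
                 loglik = NA_real_),
            class = "cb_fit")
}

# one-common-factor level model with everything fixed, used by fixed_fit()
fixed_level <- function(m, lambda, phi_var, theta) {
  p <- length(lambda)
  clusterbias:::level_model(m,
    lambda = clusterbias:::fixed_pattern(matrix(lambda, ncol = 1)),
    phi = clusterbias:::fixed_pattern(matrix(phi_var, 1, 1)),
    theta = clusterbias:::fixed_pattern(matrix(theta, ncol = 1)))
}
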