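# ---------------------------------------------------------------------------
# Full-information ML engine for two-/three-level factor models.
#
# Model: y_ijk = mu + u_k + v_jk + e_ijk with cov(u) = Sigma3 (school),
# cov(v) = Sigma2 (class), cov(e) = Sigma1 (student), all independent normal.
# The exact joint log-density of all N*p observations is computed from
# sufficient statistics: the orthogonal split of each class into its mean and
# within-class contrasts makes the contrasts i.i.d. N(0, Sigma1) — their
# contribution involves only the pooled within-class scatter — while the
# class means of one school are jointly normal with covariance
# blockdiag(Sigma2 + Sigma1/n_j) + ones %x% Sigma3.  A Jacobian term
# -(p/2) * sum(log n_j) converts the density of scaled means back to raw-data
# scale, so the value matches the naive stacked multivariate normal exactly.
# ---------------------------------------------------------------------------

LOG2PI <- log(2 * pi)

# --- parameter injection ----------------------------------------------------

spec_index <- function(spec) {
  ptab <- parameter_table(spec)
  lab2i <- seq_len(nrow(ptab))
  names(lab2i) <- ptab$label
  idx_of <- function(pat) {
    out <- matrix(0L, nrow(pat$label), ncol(pat$label))
    sel <- !is.na(pat$label)
    out[sel] <- lab2i[pat$label[sel]]
    out
  }
  tmpl_of <- function(pat) {
    v <- pat$value
    v[!is.na(pat$label)] <- 0
    v[is.na(v)] <- 0
    v
  }
  levels <- lapply(spec$levels, function(lm) list(
    lambda_idx = idx_of(lm$lambda), lambda_tmpl = tmpl_of(lm$lambda),
    phi_idx = idx_of(lm$phi), phi_tmpl = tmpl_of(lm$phi),
    theta_idx = idx_of(lm$theta), theta_tmpl = tmpl_of(lm$theta)))
  list(ptab = ptab, levels = levels,
       nu_idx = idx_of(spec$nu), nu_tmpl = tmpl_of(spec$nu),
       q = nrow(ptab))
}

fill_pattern <- function(tmpl, idx, theta) {
  sel <- idx > 0L
  if (any(sel)) tmpl[sel] <- theta[idx[sel]]
  tmpl
}

#' Model-implied moments of a specification at a parameter value
#'
#' Computes the mean vector and the per-level covariance matrices
#' \code{Sigma_m = Lambda_m Phi_m Lambda_m' + diag(theta_m)} implied by a
#' free-parameter vector, with fixed values and equality constraints taken
#' from the specification.
#'
#' @param spec A \code{cb_spec}.
#' @param theta Numeric vector of free-parameter values, in
#'   [parameter_table()] order (names, if present, are checked).
#' @return A list with \code{mu} (length p) and \code{sigma} (list of p x p
#'   matrices, Level 1 first), of class \code{cb_moments}.
#' @export
implied_moments <- function(spec, theta) {
  ix <- spec_index(spec)
  if (length(theta) != ix$q)
    stop("theta has length ", length(theta), ", expected ", ix$q)
  if (!is.null(names(theta)) && !identical(names(theta), ix$ptab$label))
    theta <- theta[ix$ptab$label]
  if (any(!is.finite(theta))) stop("non-finite parameter values")
  sigma <- vector("list", spec$n_levels)
  for (m in seq_len(spec$n_levels)) {
    L <- ix$levels[[m]]
    Lam <- fill_pattern(L$lambda_tmpl, L$lambda_idx, theta)
    Phi <- fill_pattern(L$phi_tmpl, L$phi_idx, theta)
    Th <- fill_pattern(L$theta_tmpl, L$theta_idx, theta)
    S <- Lam %*% Phi %*% t(Lam)
    diag(S) <- diag(S) + as.vector(Th)
    sigma[[m]] <- (S + t(S)) / 2
  }
  mu <- as.vector(fill_pattern(ix$nu_tmpl, ix$nu_idx, theta))
  structure(list(mu = mu, sigma = sigma), class = "cb_moments")
}

# --- structured log-likelihood ---------------------------------------------

# Returns list(ll, ok, dmu, dsigma).  dsigma[[m]] is the derivative of the
# log-likelihood with respect to Sigma_m treating all entries as independent
# (symmetric accumulation is handled by the slot machinery downstream).
loglik_core <- function(stats, mu, sigma, want_grad = FALSE) {
  p <- stats$p
  N <- stats$N
  C <- stats$C
  S1 <- sigma[[1L]]
  S2 <- sigma[[2L]]
  S3 <- if (length(sigma) >= 3L) sigma[[3L]] else matrix(0, p, p)

  fail <- function(mat) {
    ev <- tryCatch(min(eigen(mat, symmetric = TRUE,
                             only.values = TRUE)$values),
                   error = function(e) -1)
    list(ll = -Inf, ok = FALSE, violation = abs(min(ev, 0)) + 1e-8)
  }

  ch1 <- tryCatch(chol(S1), error = function(e) NULL)
  if (is.null(ch1)) return(fail(S1))
  logdet1 <- 2 * sum(log(diag(ch1)))
  S1inv <- chol2inv(ch1)

  ll <- -0.5 * ((N - C) * p * LOG2PI + (N - C) * logdet1 +
                  sum(S1inv * stats$S_W)) -
    0.5 * p * stats$log_n_sum
  dS1 <- dS2 <- dS3 <- NULL
  dmu <- NULL
  if (want_grad) {
    dS1 <- -0.5 * ((N - C) * S1inv - S1inv %*% stats$S_W %*% S1inv)
    dS2 <- matrix(0, p, p)
    dS3 <- matrix(0, p, p)
    dmu <- numeric(p)
  }

  for (g in stats$groups) {
    J <- g$J
    sizes <- g$sizes
    V <- kronecker(matrix(1, J, J), S3)
    for (j in seq_len(J)) {
      blk <- (j - 1L) * p + seq_len(p)
      V[blk, blk] <- V[blk, blk] + S2 + S1 / sizes[j]
    }
    chV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(chV)) return(fail(V))
    logdetV <- 2 * sum(log(diag(chV)))
    Rc <- g$R - rep(mu, J)
    Z <- backsolve(chV, Rc, transpose = TRUE)
    ll <- ll - 0.5 * (g$n_members * (J * p * LOG2PI + logdetV) +
                        sum(Z * Z))
    if (want_grad) {
      Vi <- chol2inv(chV)
      P <- Vi %*% Rc
      dmu <- dmu + rowSums(matrix(rowSums(P), p, J))
      Gv <- -0.5 * (g$n_members * Vi - tcrossprod(P))
      for (j in seq_len(J)) {
        blk <- (j - 1L) * p + seq_len(p)
        Gjj <- Gv[blk, blk]
        dS2 <- dS2 + Gjj
        dS1 <- dS1 + Gjj / sizes[j]
        for (jp in seq_len(J)) {
          dS3 <- dS3 + Gv[blk, (jp - 1L) * p + seq_len(p)]
        }
      }
    }
  }
  list(ll = ll, ok = TRUE, dmu = dmu,
       dsigma = list(dS1, dS2, dS3))
}

#' Exact multilevel-normal log-likelihood from sufficient statistics
#'
#' Evaluates the joint multivariate-normal log-density (including the
#' \code{-(N p / 2) log 2 pi} constant) of all observations under the
#' random-effects decomposition, using the lossless sufficient-statistic
#' reduction.  Equals the log-density of each school's stacked observation
#' vector under the full block covariance matrix.
#'
#' @param stats A \code{cb_stats} from [compute_sufficient_stats()].
#' @param moments A \code{cb_moments} from [implied_moments()], or any list
#'   with \code{mu} and \code{sigma}.
#' @return The log-likelihood; \code{-Inf} (with attribute
#'   \code{"singular"}) when a required covariance matrix is not positive
#'   definite.
#' @export
multilevel_loglik <- function(stats, moments) {
  stopifnot(inherits(stats, "cb_stats"))
  if (length(moments$mu) != stats$p)
    stop("dimension mismatch: moments have p = ", length(moments$mu),
         ", data have p = ", stats$p)
  res <- loglik_core(stats, moments$mu, moments$sigma, want_grad = FALSE)
  if (!res$ok) return(structure(-Inf, singular = TRUE))
  res$ll
}

# --- start values -----------------------------------------------------------

psd_clip <- function(M, floor = 0) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, floor)
  e$vectors %*% (v * t(e$vectors))
}

moment_decomposition <- function(stats) {
  p <- stats$p
  S1h <- if (stats$N > stats$C) stats$S_W / (stats$N - stats$C) else diag(p)
  S1h <- psd_clip(S1h, floor = 1e-4 * max(1, mean(diag(S1h))))
  Vb <- if (stats$C >= 3L) {
    stats::cov(stats$ybar) - S1h * mean(1 / stats$n_c)
  } else matrix(0, p, p)
  Vb <- psd_clip(Vb)
  V3 <- matrix(0, p, p)
  if (stats$n_levels == 3L && stats$n_schools >= 3L) {
    sbar <- rowsum(stats$ybar, stats$class_school, reorder = TRUE)
    Jper <- as.vector(table(stats$class_school))
    sbar <- sbar / Jper
    V3 <- psd_clip(stats::cov(sbar) - Vb * mean(1 / Jper))
  }
  list(S1 = S1h, S2 = Vb, S3 = V3)
}

moment_starts <- function(spec, stats, ix) {
  dec <- moment_decomposition(stats)
  Ms <- list(dec$S1, dec$S2, dec$S3)
  ptab <- ix$ptab
  slots <- attr(ptab, "slots")
  first <- slots[!duplicated(slots$label), , drop = FALSE]
  first <- first[match(ptab$label, first$label), , drop = FALSE]
  start <- ptab$start
  p <- stats$p
  for (i in seq_len(nrow(ptab))) {
    if (!is.na(start[i])) next
    sl <- first[i, ]
    m <- sl$level
    start[i] <- switch(sl$matrix,
      nu = stats$grand_mean[sl$row],
      lambda = sqrt(max(Ms[[1L]][sl$row, sl$row], 0.2) / 2),
      theta = {
        M <- Ms[[min(m, length(Ms))]]
        max(0.5 * M[sl$row, sl$row], 1e-2)
      },
      phi = {
        lm <- spec$levels[[m]]
        M <- Ms[[min(m, length(Ms))]]
        saturated_style <- lm$k == p && !any(is_free(lm$lambda)) &&
          isTRUE(all.equal(lm$lambda$value, diag(p),
                           check.attributes = FALSE))
        if (saturated_style) {
          if (sl$row == sl$col) max(M[sl$row, sl$col], 1e-3) else
            M[sl$row, sl$col]
        } else if (sl$row == sl$col) {
          max(0.5 * mean(diag(M)), 1e-2)
        } else 0
      })
  }
  # keep variance starts strictly inside the bound
  start <- ifelse(ptab$lower == 0, pmax(start, 1e-4), start)
  start
}

# --- fitting ----------------------------------------------------------------

#' Optimizer options for model fitting
#'
#' @param maxit Maximum L-BFGS-B iterations (default 500).
#' @param factr L-BFGS-B relative-reduction tolerance factor (default 1e7,
#'   i.e. about 2e-9 relative change in the log-likelihood).
#' @param pgtol Projected-gradient tolerance (default 1e-5).
#' @param restarts Number of jittered restarts tried after a failed
#'   convergence (default 3).
#' @param jitter Relative jitter applied to start values on restart.
#' @param seed Seed driving the restart jitter (default 0); fitting is
#'   otherwise deterministic.
#' @return A list of class \code{cb_options}.
#' @export
fit_options <- function(maxit = 500L, factr = 1e7, pgtol = 1e-5,
                        restarts = 3L, jitter = 0.2, seed = 0L) {
  structure(list(maxit = as.integer(maxit), factr = factr, pgtol = pgtol,
                 restarts = as.integer(restarts), jitter = jitter,
                 seed = as.integer(seed)),
            class = "cb_options")
}

as_stats <- function(data) {
  if (inherits(data, "cb_stats")) data
  else if (inherits(data, "cb_data")) compute_sufficient_stats(data)
  else stop("expected a cb_data or cb_stats object")
}

# evaluate with a local RNG state so fitting never disturbs the caller's
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

fit_core <- function(spec, stats, options = fit_options()) {
  findings <- validate_spec(spec)
  if (length(findings))
    stop("specification not admissible: ", paste(findings, collapse = "; "))
  if (spec$p != stats$p)
    stop("spec has p = ", spec$p, " but data have p = ", stats$p)
  ix <- spec_index(spec)
  q <- ix$q
  lower <- ix$ptab$lower
  n_eval <- 0L

  eval_at <- function(theta, want_grad) {
    sigma <- vector("list", spec$n_levels)
    mats <- vector("list", spec$n_levels)
    for (m in seq_len(spec$n_levels)) {
      L <- ix$levels[[m]]
      Lam <- fill_pattern(L$lambda_tmpl, L$lambda_idx, theta)
      Phi <- fill_pattern(L$phi_tmpl, L$phi_idx, theta)
      Th <- fill_pattern(L$theta_tmpl, L$theta_idx, theta)
      S <- Lam %*% Phi %*% t(Lam)
      diag(S) <- diag(S) + as.vector(Th)
      sigma[[m]] <- (S + t(S)) / 2
      mats[[m]] <- list(Lam = Lam, Phi = Phi)
    }
    mu <- as.vector(fill_pattern(ix$nu_tmpl, ix$nu_idx, theta))
    core <- loglik_core(stats, mu, sigma, want_grad = want_grad)
    core$mats <- mats
    core
  }

  objective <- function(theta) {
    n_eval <<- n_eval + 1L
    core <- eval_at(theta, want_grad = FALSE)
    if (!core$ok) return(1e10 * (1 + core$violation))
    -core$ll
  }
  gradient <- function(theta) {
    core <- eval_at(theta, want_grad = TRUE)
    if (!core$ok) return(numeric(q))
    -param_gradient(core, ix, spec$n_levels)
  }

  start0 <- moment_starts(spec, stats, ix)
  best <- NULL
  attempt_starts <- function(a) {
    if (a == 0L) return(start0)
    with_local_seed(options$seed + a, {
      s <- start0 * (1 + options$jitter * stats::runif(q, -1, 1))
      s <- s + ifelse(start0 == 0, 0.05 * stats::runif(q, -1, 1), 0)
      pmax(s, ifelse(lower == 0, 1e-4, -Inf))
    })
  }
  for (a in 0:options$restarts) {
    st <- attempt_starts(a)
    opt <- tryCatch(
      stats::optim(st, objective, gradient, method = "L-BFGS-B",
                   lower = lower,
                   control = list(maxit = options$maxit,
                                  factr = options$factr,
                                  pgtol = options$pgtol)),
      error = function(e) list(par = st, value = Inf, convergence = 99L,
                               counts = c(0L, 0L), message = conditionMessage(e)))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0L) { best <- opt; break }
  }
  opt <- best

  theta_hat <- opt$par
  names(theta_hat) <- ix$ptab$label
  core <- eval_at(theta_hat, want_grad = TRUE)
  grad <- if (core$ok) param_gradient(core, ix, spec$n_levels) else
    rep(NA_real_, q)
  # projected gradient: at an active lower bound a negative ll-gradient
  # (pushing the parameter below the bound) does not count
  at_bound <- lower == 0 & theta_hat <= 1e-8
  pgrad <- grad
  pgrad[at_bound & !is.na(grad) & grad < 0] <- 0
  gradient_norm <- if (all(is.finite(pgrad))) max(abs(pgrad)) else Inf
  converged <- opt$convergence == 0L && core$ok && is.finite(gradient_norm)

  ptab <- ix$ptab
  ptab$estimate <- theta_hat
  ptab$se <- NA_real_
  ptab$boundary <- lower == 0 & theta_hat <= 1e-6
  attr(ptab, "slots") <- attr(ix$ptab, "slots")

  structure(list(spec = spec,
                 partable = ptab,
                 estimates = theta_hat,
                 loglik = if (core$ok) core$ll else -Inf,
                 converged = converged,
                 n_iterations = unname(opt$counts[1L]),
                 n_evaluations = n_eval,
                 gradient_norm = gradient_norm,
                 optim_status = opt$convergence,
                 optim_message = opt$message,
                 data_summary = list(N = stats$N, n_classes = stats$C,
                                     n_schools = stats$n_schools,
                                     p = stats$p,
                                     n_levels = stats$n_levels,
                                     fingerprint = unname(c(
                                       stats$N, stats$C, stats$n_schools,
                                       stats$grand_mean, sum(stats$S_W)))),
                 stats = stats,
                 options = options,
                 vcov = NULL),
            class = "cb_fit")
}

param_gradient <- function(core, ix, n_levels) {
  g <- numeric(ix$q)
  acc <- function(g, idx, d) {
    sel <- idx > 0L
    if (!any(sel)) return(g)
    s <- rowsum(d[sel], idx[sel])
    ii <- as.integer(rownames(s))
    g[ii] <- g[ii] + s[, 1L]
    g
  }
  for (m in seq_len(n_levels)) {
    L <- ix$levels[[m]]
    Gm <- core$dsigma[[m]]
    Lam <- core$mats[[m]]$Lam
    Phi <- core$mats[[m]]$Phi
    g <- acc(g, L$lambda_idx, 2 * Gm %*% Lam %*% Phi)
    g <- acc(g, L$phi_idx, t(Lam) %*% Gm %*% Lam)
    g <- acc(g, L$theta_idx, matrix(diag(Gm), ncol = 1L))
  }
  acc(g, ix$nu_idx, matrix(core$dmu, ncol = 1L))
}

#' Fit a multilevel factor model by full-information maximum likelihood
#'
#' Maximizes the exact multilevel-normal log-likelihood over the free
#' parameters of the specification, subject to nonnegativity of variances,
#' with L-BFGS-B and analytic gradients.  Start values come from a
#' moment-based variance decomposition (pooled within-class covariance for
#' Level 1, between-class and between-school mean covariances above, floored
#' at zero).  Nonconvergence triggers up to \code{options$restarts} jittered
#' restarts and is reported, never silent.
#'
#' @param spec A \code{cb_spec}.
#' @param data A \code{cb_data} or \code{cb_stats}.
#' @param options A [fit_options()] list.
#' @return A \code{cb_fit}: parameter table with estimates, log-likelihood,
#'   convergence diagnostics.
#' @export
fit_ml <- function(spec, data, options = fit_options()) {
  fit_core(spec, as_stats(data), options)
}

#' Fit the saturated multilevel model
#'
#' Unstructured mean and one unstructured covariance matrix per level; the
#' log-likelihood reference for the model chi-square.  With few higher-level
#' clusters the saturated top-level covariance may be weakly identified and
#' the fit can fail to converge; this is reported via the convergence flag.
#'
#' @inheritParams fit_ml
#' @param n_levels Number of levels (defaults to the data's).
#' @return A \code{cb_fit}.
#' @export
fit_saturated <- function(data, n_levels = NULL, options = fit_options()) {
  stats <- as_stats(data)
  if (is.null(n_levels)) n_levels <- stats$n_levels
  fit_core(saturated_spec(stats$p, n_levels), stats, options)
}

#' Fit the independence multilevel model
#'
#' Diagonal covariance at every level with free means; the CFI baseline.
#'
#' @inheritParams fit_saturated
#' @return A \code{cb_fit}.
#' @export
fit_independence <- function(data, n_levels = NULL, options = fit_options()) {
  stats <- as_stats(data)
  if (is.null(n_levels)) n_levels <- stats$n_levels
  fit_core(independence_spec(stats$p, n_levels), stats, options)
}

#' @export
print.cb_fit <- function(x, ...) {
  cat(sprintf("Multilevel factor model fit (%d levels, p = %d)\n",
              x$spec$n_levels, x$spec$p))
  cat(sprintf("  N = %d units, %d classes, %d schools\n",
              x$data_summary$N, x$data_summary$n_classes,
              x$data_summary$n_schools))
  cat(sprintf("  log-likelihood: %.4f  (converged: %s, max |grad|: %.2e)\n",
              x$loglik, x$converged, x$gradient_norm))
  cat(sprintf("  free parameters: %d, df: %d\n", length(x$estimates),
              degrees_of_freedom(x$spec)))
  invisible(x)
}

#' @export
logLik.cb_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates),
            nobs = object$data_summary$N, class = "logLik")
}

#' @export
coef.cb_fit <- function(object, ...) object$estimates

# --- standard errors --------------------------------------------------------

#' Standard errors from the inverse observed information
#'
#' Computes the observed information matrix by central numerical
#' differentiation of the analytic gradient at the optimum and inverts it.
#' Parameters pinned at the zero boundary are flagged \code{boundary} and
#' excluded: their sampling distribution is not normal and a Wald standard
#' error would be meaningless there.
#'
#' @param fit A converged \code{cb_fit}.
#' @return The fit with \code{se} filled in its parameter table and a
#'   \code{vcov} matrix attached; non-invertible information yields NA
#'   standard errors and a diagnostic note, never an error.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "cb_fit"))
  if (!fit$converged)
    stop("standard errors require a converged fit")
  if (!is.null(fit$vcov)) return(fit)
  spec <- fit$spec
  stats <- fit$stats
  ix <- spec_index(spec)
  q <- ix$q
  theta <- fit$estimates

  grad_at <- function(th) {
    sigma <- vector("list", spec$n_levels)
    mats <- vector("list", spec$n_levels)
    for (m in seq_len(spec$n_levels)) {
      L <- ix$levels[[m]]
      Lam <- fill_pattern(L$lambda_tmpl, L$lambda_idx, th)
      Phi <- fill_pattern(L$phi_tmpl, L$phi_idx, th)
      Th <- fill_pattern(L$theta_tmpl, L$theta_idx, th)
      S <- Lam %*% Phi %*% t(Lam)
      diag(S) <- diag(S) + as.vector(Th)
      sigma[[m]] <- (S + t(S)) / 2
      mats[[m]] <- list(Lam = Lam, Phi = Phi)
    }
    mu <- as.vector(fill_pattern(ix$nu_tmpl, ix$nu_idx, th))
    core <- loglik_core(stats, mu, sigma, want_grad = TRUE)
    if (!core$ok) return(rep(NA_real_, q))
    core$mats <- mats
    param_gradient(core, ix, spec$n_levels)
  }

  pinned <- fit$partable$boundary
  free <- which(!pinned)
  H <- matrix(NA_real_, q, q)
  for (j in free) {
    h <- 1e-4 * max(1, abs(theta[j]))
    lo <- theta; lo[j] <- lo[j] - h
    hi <- theta; hi[j] <- hi[j] + h
    if (ix$ptab$lower[j] == 0 && lo[j] < 0) {  # one-sided near the bound
      lo <- theta
      H[, j] <- -(grad_at(hi) - grad_at(lo)) / h
    } else {
      H[, j] <- -(grad_at(hi) - grad_at(lo)) / (2 * h)
    }
  }
  Hs <- H[free, free, drop = FALSE]
  Hs <- (Hs + t(Hs)) / 2
  vc <- tryCatch(solve(Hs), error = function(e) NULL)
  se <- rep(NA_real_, q)
  note <- NULL
  if (is.null(vc) || any(!is.finite(vc))) {
    note <- "observed information not invertible; standard errors unavailable"
    vcov <- NULL
  } else {
    d <- diag(vc)
    se[free] <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
    if (any(d <= 0))
      note <- "observed information not positive definite for some parameters"
    vcov <- matrix(NA_real_, q, q,
                   dimnames = list(ix$ptab$label, ix$ptab$label))
    vcov[free, free] <- vc
  }
  fit$partable$se <- se
  fit$vcov <- vcov
  fit$se_note <- note
  fit
}
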