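# ---------------------------------------------------------------------------
# From fitted models to the cluster-bias testing sequence: chi-square fit
# statistics, RMSEA/CFI, chi-square difference tests (with the boundary
# caveat), latent and observed ICCs, bias proportions, Wald tests.
# ---------------------------------------------------------------------------

same_data <- function(a, b) {
  isTRUE(all.equal(a$data_summary$fingerprint, b$data_summary$fingerprint,
                   tolerance = 1e-12))
}

#' Model chi-square against the saturated model
#'
#' \code{chisq = 2 * (loglik_saturated - loglik_model)}, clipped at zero,
#' with degrees of freedom from the specification.
#'
#' @param fit A converged \code{cb_fit} of a structured model.
#' @param saturated A converged saturated \code{cb_fit} on the same data.
#' @return A list with \code{chisq}, \code{df} and \code{p_value}.
#' @export
model_chisq <- function(fit, saturated) {
  stopifnot(inherits(fit, "cb_fit"), inherits(saturated, "cb_fit"))
  if (!same_data(fit, saturated))
    stop("fits are not on the same data (fingerprints differ)")
  if (!fit$converged || !saturated$converged)
    stop("both fits must have converged")
  chisq <- max(0, 2 * (saturated$loglik - fit$loglik))
  df <- degrees_of_freedom(fit$spec)
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else
    as.numeric(chisq <= 0)
  list(chisq = chisq, df = df, p_value = p)
}

#' RMSEA and CFI from chi-square statistics
#'
#' \code{rmsea = sqrt(max(chisq - df, 0) / (df * N))} with N the total number
#' of Level-1 units, and
#' \code{cfi = 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)}
#' against the independence baseline.  RMSEA below 0.08 is conventionally
#' satisfactory (below 0.05, close fit); CFI above 0.95, reasonably good fit.
#'
#' @param chisq,df Model chi-square and degrees of freedom (df > 0).
#' @param chisq_baseline,df_baseline Independence-baseline chi-square and df.
#' @param N Number of Level-1 units.
#' @return A list with \code{rmsea} and \code{cfi}.
#' @export
fit_indices <- function(chisq, df, chisq_baseline, df_baseline, N) {
  if (df <= 0) stop("df must be positive for the RMSEA")
  if (df_baseline <= 0) stop("baseline df must be positive")
  if (N <= 0) stop("N must be positive")
  excess <- max(chisq - df, 0)
  rmsea <- sqrt(excess / (df * N))
  denom <- max(chisq_baseline - df_baseline, chisq - df, 0)
  cfi <- if (denom == 0) 1 else 1 - excess / denom
  list(rmsea = rmsea, cfi = min(max(cfi, 0), 1))
}

spec_free_labels <- function(spec) parameter_table(spec)$label

restriction_pins_variance <- function(restricted, full) {
  # TRUE when the restriction fixes at zero a variance that is free in the
  # full model (the chi-bar-square boundary situation)
  for (m in seq_len(restricted$n_levels)) {
    rth <- restricted$levels[[m]]$theta
    fth <- full$levels[[m]]$theta
    if (any(is.na(rth$label) & rth$value == 0 & !is.na(fth$label)))
      return(TRUE)
    rph <- restricted$levels[[m]]$phi
    fph <- full$levels[[m]]$phi
    dsel <- diag(is.na(rph$label)) & diag(rph$value) == 0 &
      diag(!is.na(fph$label))
    if (any(dsel)) return(TRUE)
  }
  FALSE
}

#' Chi-square difference test between nested fits
#'
#' \code{delta_chisq = 2 * (loglik_full - loglik_restricted)} (clipped at 0)
#' referred to a central chi-square with df equal to the difference in free
#' parameters.  When the restriction pins variances at their zero boundary,
#' the true null distribution is a mixture of chi-squares and the central
#' chi-square p-value is conservative; the result carries a note saying so.
#'
#' @param restricted A converged \code{cb_fit} whose free parameters are a
#'   subset of \code{full}'s.
#' @param full A converged \code{cb_fit} on the same data.
#' @return A list with \code{delta_chisq}, \code{delta_df}, \code{p_value}
#'   and possibly \code{note}.
#' @export
chisq_difference <- function(restricted, full) {
  stopifnot(inherits(restricted, "cb_fit"), inherits(full, "cb_fit"))
  if (!same_data(restricted, full))
    stop("fits are not on the same data (fingerprints differ)")
  if (!restricted$converged || !full$converged)
    stop("both fits must have converged")
  lr <- spec_free_labels(restricted$spec)
  lf <- spec_free_labels(full$spec)
  if (!all(lr %in% lf))
    stop("models are not nested: restricted model frees parameter(s) ",
         paste(utils::head(setdiff(lr, lf), 5L), collapse = ", "),
         " absent from the full model")
  delta_chisq <- max(0, 2 * (full$loglik - restricted$loglik))
  delta_df <- length(lf) - length(lr)
  p <- if (delta_df > 0)
    stats::pchisq(delta_chisq, delta_df, lower.tail = FALSE)
  else as.numeric(delta_chisq <= 0)
  out <- list(delta_chisq = delta_chisq, delta_df = delta_df, p_value = p)
  if (restriction_pins_variance(restricted$spec, full$spec))
    out$note <- paste("restriction places variances on the zero boundary;",
                      "the central chi-square p-value is conservative")
  out
}

#' Intraclass correlations of a common factor
#'
#' With loadings equal across levels the factor is on the same scale at every
#' level, so its variance decomposes and
#' \code{icc_level2 = phi2 / (phi1 + phi2 + phi3)} (and analogously for
#' Level 3) is the share of factor variance at each clustering level.
#'
#' @param phi1,phi2,phi3 Factor variances at Levels 1-3 (\code{phi3 = 0} for
#'   two-level models); all nonnegative, positive total.
#' @return A list with \code{icc_level2} and \code{icc_level3}.
#' @examples
#' factor_icc(1, 0.56, 0.003)  # 0.358 and 0.002
#' @export
factor_icc <- function(phi1, phi2, phi3 = 0) {
  if (any(c(phi1, phi2, phi3) < 0)) stop("factor variances must be >= 0")
  total <- phi1 + phi2 + phi3
  if (total <= 0) stop("total factor variance is zero")
  list(icc_level2 = phi2 / total, icc_level3 = phi3 / total)
}

#' Per-indicator observed intraclass correlations
#'
#' For each indicator, the share of its model-implied total variance located
#' at Level 2 and (for three-level fits) Level 3.  Typically applied to the
#' saturated fit, where the implied matrices are the unstructured ML
#' level-wise covariance estimates.
#'
#' @param fit A converged \code{cb_fit}.
#' @return A data frame with columns indicator, icc_level2, icc_level3.
#' @export
observed_icc <- function(fit) {
  stopifnot(inherits(fit, "cb_fit"))
  mom <- implied_moments(fit$spec, fit$estimates)
  p <- fit$spec$p
  tot <- Reduce(`+`, lapply(mom$sigma, diag))
  icc2 <- diag(mom$sigma[[2L]]) / tot
  icc3 <- if (fit$spec$n_levels == 3L) diag(mom$sigma[[3L]]) / tot else
    rep(0, p)
  data.frame(indicator = fit$stats$indicator_names,
             icc_level2 = icc2, icc_level3 = icc3,
             row.names = NULL)
}

theta_estimates <- function(fit, level) {
  # per-indicator residual variance at a level: estimate (or fixed value),
  # SE and boundary flag
  spec <- fit$spec
  stopifnot(level %in% seq_len(spec$n_levels))
  pat <- spec$levels[[level]]$theta
  p <- spec$p
  est <- se <- rep(NA_real_, p)
  fixed <- boundary <- rep(FALSE, p)
  ptab <- fit$partable
  for (v in seq_len(p)) {
    lab <- pat$label[v, 1L]
    if (is.na(lab)) {
      est[v] <- pat$value[v, 1L]
      fixed[v] <- TRUE
    } else {
      i <- match(lab, ptab$label)
      est[v] <- ptab$estimate[i]
      se[v] <- ptab$se[i]
      boundary[v] <- isTRUE(ptab$boundary[i])
    }
  }
  data.frame(indicator = fit$stats$indicator_names, estimate = est, se = se,
             fixed = fixed, boundary = boundary, row.names = NULL)
}

#' Bias proportions of higher-level residual variance
#'
#' For each indicator v at level m, the residual variance as a share of the
#' model-implied variance at that level, \code{theta_m[v] / Sigma_m[v, v]},
#' and as a share of the implied total variance over all levels.  The
#' level-m implied variance includes the common-factor and any doublet
#' (method) factor contributions.
#'
#' @param fit A converged \code{cb_fit} with loadings equal across levels.
#' @param level Level at which to decompose (2 or 3).
#' @return A data frame with columns indicator, residual, prop_within_level,
#'   prop_total.
#' @export
bias_proportions <- function(fit, level = 2) {
  stopifnot(inherits(fit, "cb_fit"))
  mom <- implied_moments(fit$spec, fit$estimates)
  th <- theta_estimates(fit, level)
  denom_level <- diag(mom$sigma[[level]])
  denom_total <- Reduce(`+`, lapply(mom$sigma, diag))
  if (any(denom_total <= 0))
    stop("zero implied total variance for some indicator")
  prop_within <- ifelse(th$estimate == 0, 0,
                        th$estimate / denom_level)
  if (any(denom_level <= 0 & th$estimate > 0))
    stop("zero implied level variance with nonzero residual")
  data.frame(indicator = th$indicator,
             residual = th$estimate,
             prop_within_level = prop_within,
             prop_total = ifelse(th$estimate == 0, 0,
                                 th$estimate / denom_total),
             row.names = NULL)
}

#' Wald tests of per-indicator residual variances at a level
#'
#' \code{z = estimate / se} with a two-sided normal p-value, flagged at the
#' given alpha.  Boundary-pinned estimates are flagged and not tested (their
#' Wald statistic has no standard null distribution at the boundary); fixed
#' entries get no test either.
#'
#' @param fit A converged \code{cb_fit}; standard errors are computed on
#'   demand.
#' @param level Level of the residual variances (2 or 3).
#' @param alpha Significance level (default 0.05).
#' @return A data frame with columns indicator, estimate, se, z, p_value,
#'   significant, boundary.
#' @export
residual_variance_wald <- function(fit, level = 2, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(fit$vcov)) fit <- standard_errors(fit)
  th <- theta_estimates(fit, level)
  z <- ifelse(th$boundary | th$fixed | is.na(th$se), NA_real_,
              th$estimate / th$se)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(indicator = th$indicator,
             estimate = th$estimate, se = th$se, z = z, p_value = p,
             significant = !is.na(p) & p < alpha,
             boundary = th$boundary,
             row.names = NULL)
}

common_factor_variances <- function(fit) {
  # Phi[1,1] per level (fixed or estimated) of the common factor
  mom_phi <- numeric(fit$spec$n_levels)
  ix <- spec_index(fit$spec)
  for (m in seq_len(fit$spec$n_levels)) {
    L <- ix$levels[[m]]
    Phi <- fill_pattern(L$phi_tmpl, L$phi_idx, fit$estimates)
    mom_phi[m] <- Phi[1L, 1L]
  }
  mom_phi
}

#' Run the full cluster-bias testing sequence
#'
#' Fits the baseline model (one common factor, loadings tied across levels,
#' plus any doublet factors), the model with all Level-2 residual variances
#' fixed at zero, and -- for three-level data -- the model with all Level-3
#' residual variances fixed at zero, together with the saturated and
#' independence reference models.  A significant chi-square difference when
#' zeroing a level's residual variances indicates measurement bias with
#' respect to that clustering variable (strong factorial invariance is
#' rejected).  Both constrained models are compared against the baseline, so
#' each difference test has df = p.
#'
#' @param data A \code{cb_data} (or \code{cb_stats}).
#' @param doublets List of indicator-index sets sharing method factors.
#' @param alpha Significance level for the verdicts (default 0.05).
#' @param options [fit_options()] passed to every fit.
#' @return A \code{cb_report} with the fit table, difference tests with
#'   verdicts, per-indicator Wald tests, bias proportions, factor and
#'   observed ICCs.  Nonconvergence marks affected entries unavailable.
#' @export
cluster_bias_test <- function(data, doublets = list(), alpha = 0.05,
                              options = fit_options()) {
  stopifnot(alpha > 0, alpha < 1)
  stats <- as_stats(data)
  p <- stats$p
  n_levels <- stats$n_levels
  models <- build_cluster_bias_models(p, doublets, n_levels = n_levels)

  safe_fit <- function(spec) {
    tryCatch(fit_core(spec, stats, options), error = function(e) NULL)
  }
  fits <- list(saturated = tryCatch(fit_core(saturated_spec(p, n_levels),
                                             stats, options),
                                    error = function(e) NULL),
               independence = safe_fit(independence_spec(p, n_levels)),
               baseline = safe_fit(models$baseline),
               level2 = safe_fit(models$level2_constrained),
               level3 = if (n_levels == 3L)
                 safe_fit(models$level3_constrained) else NULL)
  usable <- function(f) !is.null(f) && f$converged

  ind_ref <- if (usable(fits$saturated) && usable(fits$independence))
    model_chisq(fits$independence, fits$saturated) else NULL

  fit_row <- function(fit, label) {
    row <- data.frame(model = label, df = NA_integer_, chisq = NA_real_,
                      rmsea = NA_real_, cfi = NA_real_,
                      converged = usable(fit), stringsAsFactors = FALSE)
    if (!is.null(fit)) row$df <- degrees_of_freedom(fit$spec)
    if (usable(fit) && usable(fits$saturated)) {
      mc <- model_chisq(fit, fits$saturated)
      row$chisq <- mc$chisq
      if (mc$df > 0 && !is.null(ind_ref)) {
        fi <- fit_indices(mc$chisq, mc$df, ind_ref$chisq, ind_ref$df,
                          stats$N)
        row$rmsea <- fi$rmsea
        row$cfi <- fi$cfi
      }
    }
    row
  }
  fit_table <- rbind(
    fit_row(fits$baseline, "Baseline model (equal factor loadings across levels)"),
    fit_row(fits$level2, "Strong factorial invariance at Level 2"),
    if (n_levels == 3L)
      fit_row(fits$level3, "Strong factorial invariance at Level 3"))

  diff_test <- function(constrained) {
    if (!usable(constrained) || !usable(fits$baseline))
      return(list(available = FALSE))
    d <- chisq_difference(constrained, fits$baseline)
    c(list(available = TRUE,
           verdict = if (d$p_value < alpha) "bias detected" else
             "no bias detected"), d)
  }
  tests <- list(level2 = diff_test(fits$level2))
  if (n_levels == 3L) tests$level3 <- diff_test(fits$level3)

  wald <- proportions <- list()
  ficc <- NULL
  if (usable(fits$baseline)) {
    bfit <- tryCatch(standard_errors(fits$baseline),
                     error = function(e) fits$baseline)
    fits$baseline <- bfit
    for (m in 2:n_levels) {
      lev <- paste0("level", m)
      wald[[lev]] <- tryCatch(residual_variance_wald(bfit, m, alpha),
                              error = function(e) NULL)
      proportions[[lev]] <- tryCatch(bias_proportions(bfit, m),
                                     error = function(e) NULL)
    }
    phis <- common_factor_variances(bfit)
    ficc <- factor_icc(phis[1L], phis[2L],
                       if (n_levels == 3L) phis[3L] else 0)
    ficc$phi <- phis
  }
  oicc <- if (usable(fits$saturated)) observed_icc(fits$saturated) else NULL

  structure(list(fit_table = fit_table,
                 tests = tests,
                 wald = wald,
                 bias_proportions = proportions,
                 factor_icc = ficc,
                 observed_icc = oicc,
                 alpha = alpha,
                 n_levels = n_levels,
                 doublets = doublets,
                 data_summary = list(N = stats$N, n_classes = stats$C,
                                     n_schools = stats$n_schools, p = p),
                 fits = fits),
            class = "cb_report")
}

#' @export
print.cb_report <- function(x, digits_fit = 2, digits_prop = 3, ...) {
  ds <- x$data_summary
  cat(sprintf("Test for cluster bias (%d levels): N = %d, %d classes, %d schools, p = %d\n\n",
              x$n_levels, ds$N, ds$n_classes, ds$n_schools, ds$p))
  ft <- x$fit_table
  ft$chisq <- round(ft$chisq, digits_fit)
  ft$rmsea <- round(ft$rmsea, digits_fit + 1)
  ft$cfi <- round(ft$cfi, digits_fit)
  cat("Fit of the three-level models:\n")
  print(ft, row.names = FALSE)
  cat("\n")
  for (lev in names(x$tests)) {
    t <- x$tests[[lev]]
    m <- sub("level", "Level ", lev)
    if (!isTRUE(t$available)) {
      cat(sprintf("%s test: unavailable (nonconvergence)\n", m))
    } else {
      cat(sprintf("%s: delta chi-square(%d) = %.2f, p = %.4g -> %s\n",
                  m, t$delta_df, t$delta_chisq, t$p_value, t$verdict))
      if (!is.null(t$note)) cat("  note: ", t$note, "\n", sep = "")
    }
  }
  if (!is.null(x$factor_icc)) {
    cat(sprintf("\nFactor ICC: Level 2 = %.3f, Level 3 = %.3f\n",
                x$factor_icc$icc_level2, x$factor_icc$icc_level3))
  }
  for (lev in names(x$bias_proportions)) {
    bp <- x$bias_proportions[[lev]]
    if (is.null(bp)) next
    bp$prop_within_level <- round(bp$prop_within_level, digits_prop)
    bp$prop_total <- round(bp$prop_total, digits_prop)
    bp$residual <- round(bp$residual, digits_prop)
    cat(sprintf("\nResidual-variance proportions at %s:\n",
                sub("level", "Level ", lev)))
    print(bp, row.names = FALSE)
  }
  invisible(x)
}
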