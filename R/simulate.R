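# ---------------------------------------------------------------------------
# Generative model for two-/three-level factor data, plus Monte-Carlo
# type-I-error and power studies for the cluster-bias tests.
# ---------------------------------------------------------------------------

#' Describe a simulation design for multilevel factor data
#'
#' The generative model is \code{y = tau + lambda * (eta1 + eta2 + eta3) +
#' doublet terms + e1 [+ e2 + e3]}, with the common-factor components
#' \code{eta_m ~ N(0, phi_m)} drawn per student / class / school, residuals
#' \code{e_m ~ N(0, diag(resid_m))} at each level, and all components
#' independent.  Nonzero \code{resid2}/\code{resid3} inject cluster bias
#' (violations of strong factorial invariance) at the class / school level.
#' A per-cluster loading perturbation (\code{loading_sd2}) injects a
#' weak-invariance violation instead, which the cluster-bias test flags the
#' same way.
#'
#' @param n_schools Number of Level-3 clusters.
#' @param classes_per_school Constant or per-school vector of class counts.
#' @param students_per_class Constant, per-class vector (recycled), or a
#'   list \code{list(sizes =, probs =)} to draw unbalanced sizes from a
#'   discrete distribution.
#' @param loadings Length-p true loadings (equal across levels).
#' @param phi True common-factor variances \code{c(phi1, phi2, phi3)}
#'   (length 2 for two-level designs).
#' @param resid1,resid2,resid3 Per-indicator residual variances at each
#'   level (scalars recycled); \code{resid2 = resid3 = 0} is the
#'   no-cluster-bias null.
#' @param intercepts Length-p true intercepts (scalar recycled).
#' @param doublets List of indicator-index sets with unit-loading method
#'   factors; \code{doublet_phi} gives each set's per-level variances as a
#'   vector of length \code{n_levels} (list parallel to \code{doublets}).
#' @param doublet_phi See \code{doublets}.
#' @param loading_sd2 SD of a per-class multiplicative loading perturbation
#'   (0 = none; weak-invariance violation switch).
#' @param seed Default seed for [simulate_dataset()].
#' @return A \code{cb_design}.
#' @export
simulation_design <- function(n_schools = 50,
                              classes_per_school = 3,
                              students_per_class = 10,
                              loadings = rep(0.7, 4),
                              phi = c(1, 0.3, 0.1),
                              resid1 = 0.5,
                              resid2 = 0,
                              resid3 = 0,
                              intercepts = 0,
                              doublets = list(),
                              doublet_phi = list(),
                              loading_sd2 = 0,
                              seed = 0L) {
  p <- length(loadings)
  n_levels <- length(phi)
  stopifnot(p >= 1, n_schools >= 1, n_levels %in% 2:3,
            all(phi >= 0), loading_sd2 >= 0)
  rec <- function(x) {
    x <- rep_len(x, p)
    stopifnot(all(x >= 0))
    x
  }
  classes_per_school <- rep_len(classes_per_school, n_schools)
  stopifnot(all(classes_per_school >= 1))
  if (!is.list(students_per_class))
    stopifnot(all(students_per_class >= 1))
  if (length(doublets) != length(doublet_phi))
    stop("doublets and doublet_phi must be parallel lists")
  for (dv in doublet_phi) stopifnot(length(dv) == n_levels, all(dv >= 0))
  structure(list(n_schools = n_schools,
                 classes_per_school = classes_per_school,
                 students_per_class = students_per_class,
                 p = p, n_levels = n_levels,
                 loadings = loadings, phi = phi,
                 resid1 = rec(resid1), resid2 = rec(resid2),
                 resid3 = if (n_levels == 3L) rec(resid3) else rep(0, p),
                 intercepts = rep_len(intercepts, p),
                 doublets = lapply(doublets, as.integer),
                 doublet_phi = doublet_phi,
                 loading_sd2 = loading_sd2,
                 seed = as.integer(seed)),
            class = "cb_design")
}

#' Simulate a nested dataset from a design
#'
#' Deterministic given the seed.  Returns a ready-to-fit \code{cb_data};
#' use [as.data.frame()] on the result for a long-format table (e.g. to
#' write CSV).
#'
#' @param design A [simulation_design()].
#' @param seed Seed (defaults to the design's).
#' @return A \code{cb_data}.
#' @export
simulate_dataset <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "cb_design"))
  with_local_seed(seed, {
    p <- design$p
    three <- design$n_levels == 3L
    n_classes_total <- sum(design$classes_per_school)
    class_sizes <- if (is.list(design$students_per_class)) {
      sp <- design$students_per_class
      probs <- if (is.null(sp$probs)) rep(1, length(sp$sizes)) else sp$probs
      sample(sp$sizes, n_classes_total, replace = TRUE, prob = probs)
    } else rep_len(design$students_per_class, n_classes_total)

    N <- sum(class_sizes)
    lam <- design$loadings
    sd2 <- sqrt(design$phi[2L])
    sd3 <- if (three) sqrt(design$phi[3L]) else 0

    school_of_class <- rep.int(seq_len(design$n_schools),
                               design$classes_per_school)
    class_of_row <- rep.int(seq_len(n_classes_total), class_sizes)
    school_of_row <- school_of_class[class_of_row]

    eta3 <- if (three) stats::rnorm(design$n_schools, 0, sd3) else
      numeric(design$n_schools)
    eta2 <- stats::rnorm(n_classes_total, 0, sd2)
    eta1 <- stats::rnorm(N, 0, sqrt(design$phi[1L]))
    eta <- eta1 + eta2[class_of_row] + eta3[school_of_row]

    lam_row <- matrix(lam, N, p, byrow = TRUE)
    if (design$loading_sd2 > 0) {
      pert <- matrix(stats::rnorm(n_classes_total * p, 1,
                                  design$loading_sd2),
                     n_classes_total, p)
      lam_row <- lam_row * pert[class_of_row, , drop = FALSE]
    }
    Y <- matrix(design$intercepts, N, p, byrow = TRUE) + lam_row * eta

    # doublet (method) factors, orthogonal, unit loadings on members
    for (d in seq_along(design$doublets)) {
      members <- design$doublets[[d]]
      dv <- design$doublet_phi[[d]]
      comp <- stats::rnorm(N, 0, sqrt(dv[1L])) +
        stats::rnorm(n_classes_total, 0, sqrt(dv[2L]))[class_of_row] +
        (if (three) stats::rnorm(design$n_schools, 0,
                                 sqrt(dv[3L]))[school_of_row] else 0)
      Y[, members] <- Y[, members] + comp
    }

    # residuals per level
    add_resid <- function(Y, var_vec, index, n_units) {
      nz <- which(var_vec > 0)
      for (v in nz) {
        Y[, v] <- Y[, v] + stats::rnorm(n_units, 0, sqrt(var_vec[v]))[index]
      }
      Y
    }
    Y <- add_resid(Y, design$resid1, seq_len(N), N)
    Y <- add_resid(Y, design$resid2, class_of_row, n_classes_total)
    if (three) Y <- add_resid(Y, design$resid3, school_of_row,
                              design$n_schools)

    colnames(Y) <- paste0("y", seq_len(p))
    school_lab <- paste0("school", school_of_row)
    class_lab <- paste0("class", class_of_row)
    structure(list(Y = Y,
                   school = if (three) school_lab else class_lab,
                   class = paste(if (three) school_lab else class_lab,
                                 class_lab, sep = "\r"),
                   indicator_names = colnames(Y),
                   n_levels = design$n_levels,
                   n_dropped = 0L),
              class = "cb_data")
  })
}

#' @export
as.data.frame.cb_data <- function(x, ...) {
  raw_class <- sub("^.*\r", "", x$class)
  data.frame(school = sub("\r.*$", "", x$school),
             class = raw_class,
             as.data.frame(x$Y),
             row.names = NULL)
}

#' Population moments implied by a simulation design
#'
#' The per-level covariance matrices the generator targets; useful for
#' convergence checks of empirical level-wise decompositions.
#'
#' @param design A \code{cb_design}.
#' @return A list of p x p matrices, Level 1 first.
#' @export
design_implied_sigma <- function(design) {
  p <- design$p
  lam <- design$loadings
  out <- vector("list", design$n_levels)
  resid <- list(design$resid1, design$resid2, design$resid3)
  for (m in seq_len(design$n_levels)) {
    S <- design$phi[m] * tcrossprod(lam)
    for (d in seq_along(design$doublets)) {
      members <- design$doublets[[d]]
      S[members, members] <- S[members, members] + design$doublet_phi[[d]][m]
    }
    diag(S) <- diag(S) + resid[[m]]
    out[[m]] <- S
  }
  out
}

# --- Monte-Carlo studies ----------------------------------------------------

run_study <- function(design, M, alpha, level, seed, expect_null) {
  stopifnot(M >= 2, level %in% 2:design$n_levels,
            all(alpha >= 0 & alpha <= 1))
  resid_tested <- if (level == 2L) design$resid2 else design$resid3
  if (expect_null && any(resid_tested != 0))
    stop("type-I-error study requires zero residual variance at the tested level")
  if (!expect_null && all(resid_tested == 0) && design$loading_sd2 == 0)
    warning("power study without injected bias estimates the type-I error")

  models <- build_cluster_bias_models(design$p, design$doublets,
                                      n_levels = design$n_levels)
  constrained <- if (level == 2L) models$level2_constrained else
    models$level3_constrained

  rep_seeds <- with_local_seed(seed,
                               sample.int(.Machine$integer.max - 1L, M))
  delta <- pvals <- rep(NA_real_, M)
  ok <- logical(M)
  for (r in seq_len(M)) {
    dat <- simulate_dataset(design, seed = rep_seeds[r])
    stats <- compute_sufficient_stats(dat)
    f_full <- tryCatch(fit_core(models$baseline, stats),
                       error = function(e) NULL)
    f_res <- tryCatch(fit_core(constrained, stats),
                      error = function(e) NULL)
    if (!is.null(f_full) && !is.null(f_res) && f_full$converged &&
        f_res$converged) {
      d <- chisq_difference(f_res, f_full)
      delta[r] <- d$delta_chisq
      pvals[r] <- d$p_value
      ok[r] <- TRUE
    }
  }
  n_ok <- sum(ok)
  nonconv_rate <- 1 - n_ok / M
  rejection <- vapply(alpha, function(a) mean(pvals[ok] < a), numeric(1))
  mc_se <- sqrt(rejection * (1 - rejection) / max(n_ok, 1L))
  structure(list(n_replicates = M,
                 n_converged = n_ok,
                 nonconvergence_rate = nonconv_rate,
                 unreliable = nonconv_rate > 0.2,
                 level = level,
                 alpha = alpha,
                 rejection_rate = stats::setNames(rejection,
                                                  paste0("alpha_", alpha)),
                 mc_se = stats::setNames(mc_se, paste0("alpha_", alpha)),
                 delta_chisq = delta,
                 p_values = pvals,
                 converged = ok,
                 seed = seed,
                 design = design),
            class = "cb_study")
}

#' Type-I-error study of a cluster-bias difference test
#'
#' Simulates datasets satisfying the null (zero residual variance at the
#' tested level), runs the baseline-vs-constrained chi-square difference
#' test per replicate, and reports the empirical rejection rate with its
#' Monte-Carlo standard error.  Because the restriction lies on the zero
#' boundary of the parameter space, the central chi-square reference is
#' conservative: the rate is expected at or below the nominal alpha.
#'
#' @param design A [simulation_design()] with zero residual variance at the
#'   tested level.
#' @param M Number of replicates (>= 50 recommended).
#' @param alpha Nominal level(s); may be a vector.
#' @param level Tested level (2 or 3).
#' @param seed Master seed; per-replicate seeds are spawned from it, so the
#'   study is reproducible bit-for-bit.
#' @return A \code{cb_study}; flagged unreliable when more than 20% of
#'   replicates fail to converge.
#' @export
type1_error_study <- function(design, M = 200, alpha = 0.05,
                              level = design$n_levels, seed = design$seed) {
  stopifnot(M >= 50)
  run_study(design, M, alpha, level, seed, expect_null = TRUE)
}

#' Power study of a cluster-bias difference test
#'
#' As [type1_error_study()], but for designs with injected bias (nonzero
#' residual variance at the tested level, or a per-cluster loading
#' perturbation); the rejection rate estimates power.
#'
#' @inheritParams type1_error_study
#' @return A \code{cb_study}.
#' @export
power_study <- function(design, M = 200, alpha = 0.05,
                        level = design$n_levels, seed = design$seed) {
  run_study(design, M, alpha, level, seed, expect_null = FALSE)
}

#' @export
print.cb_study <- function(x, ...) {
  cat(sprintf("Monte-Carlo study: Level-%d difference test, %d replicates (%d converged)\n",
              x$level, x$n_replicates, x$n_converged))
  for (i in seq_along(x$alpha)) {
    cat(sprintf("  alpha = %.3g: rejection rate %.3f (MC-SE %.3f)\n",
                x$alpha[i], x$rejection_rate[i], x$mc_se[i]))
  }
  if (x$unreliable)
    cat("  WARNING: > 20% nonconvergence; study flagged unreliable\n")
  invisible(x)
}
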