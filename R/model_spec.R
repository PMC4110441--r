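# ---------------------------------------------------------------------------
# Parameter patterns
#
# A pattern is a numeric matrix of values plus a character matrix of labels.
# An entry with a non-NA label is a free parameter (the value, if not NA, is
# its start value); an entry with label NA is fixed at its value.  Labels
# shared between entries -- within a matrix, across matrices, or across
# levels -- impose an equality constraint: all such slots receive the same
# estimate and count as one free parameter.
# ---------------------------------------------------------------------------

new_pattern <- function(value, label) {
  value <- as.matrix(value)
  label <- as.matrix(label)
  stopifnot(identical(dim(value), dim(label)))
  storage.mode(value) <- "double"
  storage.mode(label) <- "character"
  structure(list(value = value, label = label), class = "cb_pattern")
}

fixed_pattern <- function(value) {
  value <- as.matrix(value)
  new_pattern(value, matrix(NA_character_, nrow(value), ncol(value)))
}

free_pattern <- function(label, start = NA_real_) {
  label <- as.matrix(label)
  start <- if (length(start) == 1L) {
    matrix(start, nrow(label), ncol(label))
  } else {
    as.matrix(start)
  }
  new_pattern(start, label)
}

is_free <- function(pat) !is.na(pat$label)

#' Construct a level-specific factor model
#'
#' Bundles the loading matrix, factor covariance matrix and (diagonal)
#' residual variances for one level of a multilevel factor model.  Each
#' component is a pattern: a matrix of values paired with a matrix of labels,
#' where labelled entries are free parameters and unlabelled entries are
#' fixed.  The implied covariance matrix at the level is
#' \code{Sigma_m = Lambda Phi Lambda' + diag(theta)}.
#'
#' @param level Integer level index (1 = within, 2 = class, 3 = school).
#' @param lambda A p x k loading pattern (see [new_pattern()] internals);
#'   built by the spec constructors.
#' @param phi A k x k symmetric factor covariance pattern.
#' @param theta A length-p residual variance pattern (diagonal only).
#' @return An object of class \code{cb_level}.
#' @keywords internal
level_model <- function(level, lambda, phi, theta) {
  p <- nrow(lambda$value)
  k <- ncol(lambda$value)
  stopifnot(level %in% 1:3,
            nrow(phi$value) == k, ncol(phi$value) == k,
            length(theta$value) == p)
  theta$value <- matrix(theta$value, ncol = 1L)
  theta$label <- matrix(theta$label, ncol = 1L)
  structure(list(level = level, lambda = lambda, phi = phi, theta = theta,
                 p = p, k = k),
            class = "cb_level")
}

#' Construct a multilevel factor-model specification
#'
#' A specification holds one [level_model()] per level (Level 1 first) plus a
#' pattern of p intercepts.  All levels must share the indicator count and
#' order; cross-level equality (e.g. loadings equal across levels) is imposed
#' by giving the tied entries the same label.
#'
#' @param levels List of 2 or 3 \code{cb_level} objects, Level 1 first.
#' @param intercepts Length-p intercept pattern; defaults to all free.
#' @param indicator_names Character vector of indicator names.
#' @param factor_names Character vector of factor names.
#' @return An object of class \code{cb_spec}.
#' @export
model_spec <- function(levels, intercepts = NULL, indicator_names = NULL,
                       factor_names = NULL) {
  stopifnot(length(levels) %in% 2:3)
  p <- levels[[1L]]$p
  for (lm in levels) {
    if (lm$p != p) stop("all levels must share the indicator count p")
  }
  if (is.null(intercepts)) {
    intercepts <- free_pattern(matrix(paste0("nu_", seq_len(p)), ncol = 1L))
  }
  stopifnot(length(intercepts$value) == p)
  intercepts$value <- matrix(intercepts$value, ncol = 1L)
  intercepts$label <- matrix(intercepts$label, ncol = 1L)
  if (is.null(indicator_names)) indicator_names <- paste0("y", seq_len(p))
  if (is.null(factor_names)) factor_names <- paste0("f", seq_len(levels[[1L]]$k))
  spec <- structure(list(levels = levels, nu = intercepts, p = p,
                         n_levels = length(levels),
                         indicator_names = indicator_names,
                         factor_names = factor_names),
                    class = "cb_spec")
  # fail early on malformed symmetric patterns
  for (lm in levels) {
    if (!identical(lm$phi$label, t(lm$phi$label)) ||
        !isTRUE(all.equal(lm$phi$value, t(lm$phi$value), tolerance = 1e-12,
                          check.attributes = FALSE)))
      stop("factor covariance pattern must be symmetric (values and labels)")
  }
  spec
}

# ---------------------------------------------------------------------------
# Parameter table: one row per distinct free label, with the slots it fills.
# ---------------------------------------------------------------------------

enumerate_slots <- function(spec) {
  out <- list()
  add <- function(pat, level, matrix_name) {
    sel <- which(is_free(pat), arr.ind = TRUE)
    if (nrow(sel) == 0L) return()
    out[[length(out) + 1L]] <<- data.frame(
      label = pat$label[sel],
      level = level, matrix = matrix_name,
      row = sel[, 1L], col = sel[, 2L],
      start = pat$value[sel],
      stringsAsFactors = FALSE)
  }
  for (m in seq_along(spec$levels)) {
    lm <- spec$levels[[m]]
    add(lm$lambda, m, "lambda")
    add(lm$phi, m, "phi")
    add(lm$theta, m, "theta")
  }
  add(spec$nu, 0L, "nu")
  if (length(out) == 0L) {
    return(data.frame(label = character(), level = integer(),
                      matrix = character(), row = integer(), col = integer(),
                      start = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Parameter table of a specification
#'
#' One row per distinct free parameter (equality-tied slots collapse to a
#' single row), with lower bound and start value.  Variance-type parameters
#' (residual variances, factor variances) get lower bound 0.
#'
#' @param spec A \code{cb_spec}.
#' @return A data frame with columns label, lower, start, n_slots; the full
#'   slot list is attached as attribute \code{"slots"}.
#' @export
parameter_table <- function(spec) {
  slots <- enumerate_slots(spec)
  labels <- unique(slots$label)
  is_var_slot <- slots$matrix == "theta" |
    (slots$matrix == "phi" & slots$row == slots$col)
  lower <- vapply(labels, function(l) {
    if (any(is_var_slot[slots$label == l])) 0 else -Inf
  }, numeric(1))
  start <- vapply(labels, function(l) {
    s <- slots$start[slots$label == l]
    s <- s[!is.na(s)]
    if (length(s)) s[[1L]] else NA_real_
  }, numeric(1))
  n_slots <- vapply(labels, function(l) sum(slots$label == l), integer(1))
  tab <- data.frame(label = labels, lower = unname(lower),
                    start = unname(start), n_slots = unname(n_slots),
                    stringsAsFactors = FALSE)
  attr(tab, "slots") <- slots
  tab
}

#' Number of distinct free parameters in a specification
#'
#' Equality-tied entries (shared labels) count once.
#'
#' @param spec A \code{cb_spec}.
#' @return Integer count of free parameters.
#' @export
count_free_parameters <- function(spec) {
  nrow(parameter_table(spec))
}

#' Degrees of freedom of a specification
#'
#' The number of sample moments (p means plus one p x p covariance matrix per
#' level, i.e. \code{p + L * p * (p + 1) / 2}) minus the number of free
#' parameters.
#'
#' @param spec A \code{cb_spec}.
#' @return Integer degrees of freedom.
#' @export
degrees_of_freedom <- function(spec) {
  p <- spec$p
  moments <- p + spec$n_levels * p * (p + 1) / 2
  df <- moments - count_free_parameters(spec)
  if (df < 0) stop("over-parameterized specification: df = ", df)
  as.integer(df)
}

# ---------------------------------------------------------------------------
# Cluster-bias model constructors
# ---------------------------------------------------------------------------

#' Build the three model specifications of the cluster-bias testing sequence
#'
#' Constructs (i) a baseline model with one common factor whose loadings are
#' constrained equal across all levels, the common-factor variance fixed at 1
#' at Level 1 and free at the higher levels, free residual variances at every
#' level, and free intercepts; (ii) the same model with all Level-2 residual
#' variances fixed at zero (strong factorial invariance across Level-2
#' clusters); and (iii) the same with all Level-3 residual variances fixed at
#' zero.  Each doublet set adds an orthogonal method factor with loadings
#' fixed at 1 on its member indicators and a free variance at every level;
#' this is the standard reparameterization of a residual covariance, needed
#' because the residual matrices are diagonal.  Doublet-factor variances stay
#' free in the constrained models.
#'
#' @param p Number of indicators (at least 3).
#' @param doublets List of integer vectors; each names the (>= 2) indicators
#'   sharing a method factor.  Sets must not overlap.
#' @param n_levels 2 or 3 (default 3).
#' @param identification "factor_variance" (default; common-factor variance
#'   fixed at 1 at Level 1) or "first_loading" (first loading fixed at 1,
#'   all factor variances free).
#' @return A named list with elements \code{baseline},
#'   \code{level2_constrained} and (for three-level models)
#'   \code{level3_constrained}, each a \code{cb_spec}.
#' @examples
#' mods <- build_cluster_bias_models(p = 8, doublets = list(c(1, 2)))
#' degrees_of_freedom(mods$baseline)            # 71
#' degrees_of_freedom(mods$level2_constrained)  # 79
#' @export
build_cluster_bias_models <- function(p, doublets = list(), n_levels = 3,
                                      identification = c("factor_variance",
                                                         "first_loading")) {
  identification <- match.arg(identification)
  if (p < 3) stop("p < 3: a one-factor model needs at least 3 indicators")
  stopifnot(n_levels %in% 2:3)
  doublets <- lapply(doublets, function(d) sort(unique(as.integer(d))))
  all_idx <- unlist(doublets)
  if (length(doublets)) {
    if (any(vapply(doublets, length, integer(1)) < 2))
      stop("each doublet set needs at least 2 distinct indicators")
    if (any(all_idx < 1 | all_idx > p))
      stop("doublet indices must lie in 1..", p)
    if (anyDuplicated(all_idx))
      stop("doublet sets must not share indicators")
  }
  nd <- length(doublets)
  k <- 1L + nd
  factor_names <- c("g", if (nd) paste0("doublet", seq_len(nd)))

  lam_label <- matrix(NA_character_, p, k)
  lam_value <- matrix(0, p, k)
  lam_label[, 1L] <- paste0("lambda_", seq_len(p))   # tied across levels
  lam_value[, 1L] <- NA_real_
  if (identification == "first_loading") {
    lam_label[1L, 1L] <- NA_character_
    lam_value[1L, 1L] <- 1
  }
  for (d in seq_len(nd)) lam_value[doublets[[d]], 1L + d] <- 1

  make_level <- function(m, theta_free) {
    phi_label <- matrix(NA_character_, k, k)
    phi_value <- matrix(0, k, k)
    if (identification == "factor_variance" && m == 1L) {
      phi_value[1L, 1L] <- 1
    } else {
      phi_label[1L, 1L] <- paste0("phi_g_l", m)
      phi_value[1L, 1L] <- NA_real_
    }
    for (d in seq_len(nd)) {
      phi_label[1L + d, 1L + d] <- paste0("phi_doublet", d, "_l", m)
      phi_value[1L + d, 1L + d] <- NA_real_
    }
    if (theta_free) {
      theta <- free_pattern(matrix(paste0("theta_l", m, "_", seq_len(p)),
                                   ncol = 1L))
    } else {
      theta <- fixed_pattern(matrix(0, p, 1L))
    }
    level_model(m,
                lambda = new_pattern(lam_value, lam_label),
                phi = new_pattern(phi_value, phi_label),
                theta = theta)
  }

  build <- function(theta_free_by_level) {
    model_spec(lapply(seq_len(n_levels),
                      function(m) make_level(m, theta_free_by_level[m])),
               factor_names = factor_names)
  }
  out <- list(baseline = build(rep(TRUE, n_levels)),
              level2_constrained = build(replace(rep(TRUE, n_levels), 2L,
                                                 FALSE)))
  if (n_levels == 3)
    out$level3_constrained <- build(replace(rep(TRUE, 3L), 3L, FALSE))
  out
}

#' Saturated multilevel specification
#'
#' One unstructured mean vector plus one unstructured covariance matrix per
#' level, expressed in the common engine as identity loadings with a full
#' free symmetric factor covariance and zero residuals.  Its log-likelihood
#' is the reference point for the model chi-square; its df is 0.
#'
#' @param p Number of indicators.
#' @param n_levels 2 or 3.
#' @return A \code{cb_spec}.
#' @export
saturated_spec <- function(p, n_levels = 3) {
  stopifnot(p >= 1, n_levels %in% 2:3)
  make_level <- function(m) {
    phi_label <- outer(seq_len(p), seq_len(p), function(a, b)
      paste0("s_l", m, "_", pmin(a, b), "_", pmax(a, b)))
    level_model(m,
                lambda = fixed_pattern(diag(p)),
                phi = new_pattern(matrix(NA_real_, p, p), phi_label),
                theta = fixed_pattern(matrix(0, p, 1L)))
  }
  model_spec(lapply(seq_len(n_levels), make_level))
}

#' Independence multilevel specification
#'
#' Diagonal covariance matrix at every level with free means; the baseline
#' model for the CFI.
#'
#' @inheritParams saturated_spec
#' @return A \code{cb_spec}.
#' @export
independence_spec <- function(p, n_levels = 3) {
  stopifnot(p >= 1, n_levels %in% 2:3)
  make_level <- function(m) {
    level_model(m,
                lambda = fixed_pattern(matrix(0, p, 1L)),
                phi = fixed_pattern(matrix(0, 1L, 1L)),
                theta = free_pattern(matrix(paste0("theta_l", m, "_",
                                                   seq_len(p)), ncol = 1L)))
  }
  model_spec(lapply(seq_len(n_levels), make_level))
}

# ---------------------------------------------------------------------------
# Validation
# ---------------------------------------------------------------------------

#' Check a specification for structural problems
#'
#' Applies identification heuristics and sanity checks; returns character
#' findings rather than raising conditions, so callers can decide severity.
#' An empty result means the specification is structurally admissible.
#'
#' @param spec A \code{cb_spec}.
#' @return Character vector of findings (empty if none).
#' @export
validate_spec <- function(spec) {
  findings <- character()
  k <- spec$levels[[1L]]$k
  # scale restriction: a factor with free loadings needs either a fixed
  # nonzero loading or a fixed variance at some level
  for (f in seq_len(k)) {
    any_free_loading <- FALSE
    scaled <- FALSE
    for (lm in spec$levels) {
      lab <- lm$lambda$label[, f]
      val <- lm$lambda$value[, f]
      any_free_loading <- any_free_loading || any(!is.na(lab))
      if (any(is.na(lab) & !is.na(val) & val != 0)) scaled <- TRUE
      if (is.na(lm$phi$label[f, f]) && !is.na(lm$phi$value[f, f]))
        scaled <- TRUE
    }
    if (any_free_loading && !scaled)
      findings <- c(findings, sprintf(
        "no scale restriction for factor '%s' (all loadings and variances free)",
        spec$factor_names[f]))
  }
  # negative fixed variances
  for (lm in spec$levels) {
    th <- lm$theta
    bad <- which(!is_free(th) & th$value < 0)
    if (length(bad))
      findings <- c(findings, sprintf(
        "negative fixed residual variance at level %d, indicator %d",
        lm$level, bad))
    dphi <- diag(lm$phi$value)
    dlab <- diag(lm$phi$label)
    badp <- which(is.na(dlab) & dphi < 0)
    if (length(badp))
      findings <- c(findings, sprintf(
        "negative fixed factor variance at level %d, factor %d",
        lm$level, badp))
  }
  # labels tying incompatible slot types (a loading to a variance)
  slots <- enumerate_slots(spec)
  if (nrow(slots)) {
    is_var <- slots$matrix == "theta" |
      (slots$matrix == "phi" & slots$row == slots$col)
    for (l in unique(slots$label)) {
      v <- is_var[slots$label == l]
      m <- slots$matrix[slots$label == l]
      if (any(v) && any(m == "lambda"))
        findings <- c(findings, sprintf(
          "label '%s' ties a loading to a variance (incompatible slots)", l))
    }
  }
  findings
}

# ---------------------------------------------------------------------------
# Config (YAML/JSON) serialization:  entries "fix:<value>" or
# "free:<label>[:<start>]".
# ---------------------------------------------------------------------------

entry_to_string <- function(value, label) {
  if (is.na(label)) {
    paste0("fix:", format(value, digits = 12))
  } else if (is.na(value)) {
    paste0("free:", label)
  } else {
    paste0("free:", label, ":", format(value, digits = 12))
  }
}

pattern_to_strings <- function(pat) {
  out <- matrix(mapply(entry_to_string, pat$value, pat$label),
                nrow(pat$value), ncol(pat$value))
  if (ncol(out) == 1L) as.vector(out) else apply(out, 1L, as.list,
                                                 simplify = FALSE)
}

string_to_entry <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  if (parts[1L] == "fix") {
    list(value = as.numeric(parts[2L]), label = NA_character_)
  } else if (parts[1L] == "free") {
    list(value = if (length(parts) >= 3L) as.numeric(parts[3L]) else NA_real_,
         label = parts[2L])
  } else stop("bad pattern entry '", s, "' (expected fix:<v> or free:<label>)")
}

strings_to_pattern <- function(x) {
  # YAML/JSON readers may return rows as lists or atomic vectors; a plain
  # character vector encodes a length-p column pattern
  rows <- if (is.character(x)) as.list(x) else
    lapply(x, function(r) as.character(unlist(r)))
  nr <- length(rows)
  nc <- length(rows[[1L]])
  value <- matrix(NA_real_, nr, nc)
  label <- matrix(NA_character_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    e <- string_to_entry(rows[[i]][[j]])
    value[i, j] <- e$value
    label[i, j] <- e$label
  }
  new_pattern(value, label)
}

#' Serialize a specification to a plain-text config list
#'
#' The config maps levels to matrices to entries of the form
#' \code{"fix:<value>"} or \code{"free:<label>[:<start>]"}; suitable for
#' [yaml::as.yaml()] or [jsonlite::toJSON()].
#'
#' @param spec A \code{cb_spec}.
#' @return A nested list.
#' @seealso [spec_from_config()]
#' @export
spec_to_config <- function(spec) {
  list(
    indicator_names = spec$indicator_names,
    factor_names = spec$factor_names,
    levels = lapply(spec$levels, function(lm) list(
      level = lm$level,
      loadings = pattern_to_strings(lm$lambda),
      factor_cov = pattern_to_strings(lm$phi),
      residual_var = pattern_to_strings(lm$theta))),
    intercepts = pattern_to_strings(spec$nu))
}

#' Rebuild a specification from a config list
#'
#' @param config A list as produced by [spec_to_config()] (possibly read
#'   back from YAML or JSON).
#' @return A \code{cb_spec}.
#' @export
spec_from_config <- function(config) {
  levels <- lapply(config$levels, function(lc) {
    lam <- strings_to_pattern(lc$loadings)
    phi <- strings_to_pattern(lc$factor_cov)
    theta <- strings_to_pattern(lc$residual_var)
    level_model(as.integer(lc$level), lam, phi, theta)
  })
  model_spec(levels,
             intercepts = strings_to_pattern(config$intercepts),
             indicator_names = config$indicator_names,
             factor_names = config$factor_names)
}

#' Write / read a specification as YAML
#' @param spec A \code{cb_spec}.
#' @param path File path.
#' @return \code{read_spec} returns a \code{cb_spec}; \code{write_spec}
#'   returns \code{path} invisibly.
#' @export
write_spec <- function(spec, path) {
  writeLines(yaml::as.yaml(spec_to_config(spec)), path)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  spec_from_config(yaml::read_yaml(path))
}

#' @export
print.cb_spec <- function(x, ...) {
  q <- count_free_parameters(x)
  cat(sprintf("Multilevel factor model spec: p = %d indicators, %d levels, %d factors\n",
              x$p, x$n_levels, x$levels[[1L]]$k))
  cat(sprintf("  free parameters: %d, df: %d\n", q, degrees_of_freedom(x)))
  invisible(x)
}
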