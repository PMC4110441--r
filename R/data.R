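# ---------------------------------------------------------------------------
# Hierarchical data: long-format table -> canonical nested structure ->
# sufficient statistics for the structured likelihood.
# ---------------------------------------------------------------------------

#' Prepare long-format nested data for multilevel factor analysis
#'
#' Takes one row per Level-1 unit (e.g. student), with a school identifier,
#' a class identifier and p numeric indicator columns.  Rows with missing
#' indicator values are dropped (complete-case; the count is recorded).
#' Class labels are canonicalized as (school, class) pairs so that the same
#' class label under two schools denotes two classes.  Missing class labels
#' are handled by policy: \code{"pool"} treats all such observations within
#' a school as one pseudo-class (so a school with no class information
#' contributes a single cluster), \code{"drop"} removes them.
#'
#' @param data A data frame.
#' @param school_col Name of the school (Level-3) identifier column, or
#'   \code{NULL} for two-level data (classes are then the only clustering).
#' @param class_col Name of the class (Level-2) identifier column.
#' @param indicator_cols Character vector of indicator column names.
#' @param missing_class_policy \code{"pool"} (default) or \code{"drop"}.
#' @param shared_class_labels What to do when the same raw class label
#'   appears under two schools, which violates nesting: \code{"error"}
#'   (default; the error names the label) or \code{"rename"} (treat each
#'   (school, class) pair as its own class).
#' @return An object of class \code{cb_data}: indicator matrix plus
#'   canonical school/class labels and a summary (use \code{print()}).
#' @export
preprocess <- function(data, school_col = NULL, class_col,
                       indicator_cols,
                       missing_class_policy = c("pool", "drop"),
                       shared_class_labels = c("error", "rename")) {
  missing_class_policy <- match.arg(missing_class_policy)
  shared_class_labels <- match.arg(shared_class_labels)
  data <- as.data.frame(data)
  needed <- c(school_col, class_col, indicator_cols)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "))
  Y <- as.matrix(data[indicator_cols])
  if (!is.numeric(Y)) stop("indicator columns must be numeric")

  ok <- stats::complete.cases(Y)
  n_dropped <- sum(!ok)
  data <- data[ok, , drop = FALSE]
  Y <- Y[ok, , drop = FALSE]
  if (nrow(Y) == 0L) stop("no complete rows left after dropping missing indicators")

  n_levels <- if (is.null(school_col)) 2L else 3L
  class_raw <- as.character(data[[class_col]])
  class_missing <- is.na(class_raw) | class_raw == ""
  if (n_levels == 3L) {
    school <- as.character(data[[school_col]])
    if (anyNA(school)) stop("missing school identifiers are not supported")
  } else {
    school <- rep("(all)", nrow(Y))
  }
  if (any(class_missing)) {
    if (missing_class_policy == "pool") {
      class_raw[class_missing] <- "(pooled)"
    } else {
      keep <- !class_missing
      data <- data[keep, , drop = FALSE]
      Y <- Y[keep, , drop = FALSE]
      school <- school[keep]
      class_raw <- class_raw[keep]
      if (nrow(Y) == 0L) stop("no rows left after dropping missing class labels")
    }
  }
  if (n_levels == 3L && shared_class_labels == "error") {
    # a non-missing class label reused across schools violates nesting
    chk <- class_raw != "(pooled)"
    span <- tapply(school[chk], class_raw[chk],
                   function(s) length(unique(s)))
    bad <- names(span)[span > 1L]
    if (length(bad))
      stop("class label(s) appear under more than one school: ",
           paste(utils::head(bad, 5L), collapse = ", "),
           "; use shared_class_labels = \"rename\" to canonicalize")
  }
  class_id <- paste(school, class_raw, sep = "\r")

  if (n_levels == 2L) school <- class_id  # each class is its own top cluster

  structure(list(Y = Y,
                 school = school,
                 class = class_id,
                 indicator_names = indicator_cols,
                 n_levels = n_levels,
                 n_dropped = n_dropped),
            class = "cb_data")
}

#' @export
print.cb_data <- function(x, ...) {
  s <- data_summary(x)
  cat(sprintf("Nested data: N = %d units, p = %d indicators, %d levels\n",
              s$N, s$p, x$n_levels))
  cat(sprintf("  classes: %d (mean size %.2f)\n", s$n_classes,
              s$mean_class_size))
  if (x$n_levels == 3L)
    cat(sprintf("  schools: %d (mean size %.2f)\n", s$n_schools,
                s$mean_school_size))
  if (x$n_dropped > 0)
    cat(sprintf("  dropped %d rows with missing indicators\n", x$n_dropped))
  invisible(x)
}

#' Summary counts of a nested dataset
#'
#' @param data A \code{cb_data}.
#' @return A list with N, p, n_classes, n_schools, mean_class_size,
#'   mean_school_size.
#' @export
data_summary <- function(data) {
  stopifnot(inherits(data, "cb_data"))
  N <- nrow(data$Y)
  n_classes <- length(unique(data$class))
  n_schools <- length(unique(data$school))
  list(N = N, p = ncol(data$Y),
       n_classes = n_classes, n_schools = n_schools,
       mean_class_size = N / n_classes,
       mean_school_size = N / n_schools)
}

#' Reduce nested data to sufficient statistics
#'
#' The structured multilevel-normal likelihood depends on the data only
#' through the per-class counts and mean vectors, the pooled within-class
#' scatter matrix, and the class-to-school map.  This reduction is lossless:
#' the likelihood computed from these statistics equals the likelihood of the
#' raw rows for any implied moments.  Schools are grouped by their multiset
#' of class sizes so the stacked class-mean covariance matrix (and its
#' Cholesky factor) is formed once per group.
#'
#' @param data A \code{cb_data}.
#' @return An object of class \code{cb_stats}.
#' @export
compute_sufficient_stats <- function(data) {
  stopifnot(inherits(data, "cb_data"))
  Y <- data$Y
  p <- ncol(Y)
  N <- nrow(Y)

  class_f <- factor(data$class, levels = unique(data$class))
  C <- nlevels(class_f)
  n_c <- as.integer(table(class_f))
  ybar <- rowsum(Y, class_f, reorder = FALSE) / n_c        # C x p
  # pooled within-class scatter
  Yc <- Y - ybar[as.integer(class_f), , drop = FALSE]
  S_W <- crossprod(Yc)

  # school of each class
  class_school <- data$school[match(levels(class_f), data$class)]
  school_f <- factor(class_school, levels = unique(class_school))
  n_schools <- nlevels(school_f)

  # group schools by their (sorted) class-size signature; within each school
  # order classes by size so schools in a group stack compatibly
  school_classes <- split(seq_len(C), school_f)
  groups <- list()
  sig_of <- character(n_schools)
  for (s in seq_len(n_schools)) {
    idx <- school_classes[[s]]
    idx <- idx[order(n_c[idx], idx)]
    school_classes[[s]] <- idx
    sig_of[s] <- paste(n_c[idx], collapse = ",")
  }
  for (sig in unique(sig_of)) {
    members <- which(sig_of == sig)
    sizes <- n_c[school_classes[[members[1L]]]]
    J <- length(sizes)
    # stacked class means: (J*p) x n_members
    R <- vapply(members, function(s)
      as.vector(t(ybar[school_classes[[s]], , drop = FALSE])),
      numeric(J * p))
    R <- matrix(R, nrow = J * p)
    groups[[length(groups) + 1L]] <- list(sizes = sizes, J = J, R = R,
                                          n_members = length(members))
  }

  grand_mean <- colSums(Y) / N
  school_sizes <- vapply(school_classes, function(idx) sum(n_c[idx]),
                         numeric(1))

  structure(list(p = p, N = N, C = C, n_schools = n_schools,
                 n_c = n_c, ybar = ybar, class_school = as.integer(school_f),
                 school_classes = school_classes,
                 S_W = S_W, groups = groups,
                 grand_mean = grand_mean,
                 school_sizes = school_sizes,
                 log_n_sum = sum(log(n_c)),
                 n_levels = data$n_levels,
                 indicator_names = data$indicator_names),
            class = "cb_stats")
}
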