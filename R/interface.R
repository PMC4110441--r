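# ---------------------------------------------------------------------------
# Run configuration, artifact writers, and the handlers behind the
# command-line script (inst/cli/clusterbias.R).  Text tables and JSON are
# rendered from the same objects so they always agree.
# ---------------------------------------------------------------------------

#' Read and validate a run configuration
#'
#' A YAML file with: \code{data} (CSV path), \code{school_col} (optional),
#' \code{class_col}, \code{indicators} (list of column names), \code{model}
#' (\code{doublets}: list of indicator-index sets, or a full spec as in
#' [spec_to_config()]), \code{alpha}, \code{seed}, \code{out}.
#'
#' @param path Path to a YAML config file.
#' @return A validated config list of class \code{cb_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A config list (already parsed).
#' @export
validate_run_config <- function(cfg) {
  cfg$alpha <- cfg$alpha %||% 0.05
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config field 'alpha' must lie in (0, 1), got ", cfg$alpha)
  cfg$seed <- as.integer(cfg$seed %||% 0L)
  cols <- c(cfg$school_col, cfg$class_col, unlist(cfg$indicators))
  if (anyDuplicated(cols))
    stop("config column roles overlap: ",
         paste(cols[duplicated(cols)], collapse = ", "))
  structure(cfg, class = "cb_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config_data <- function(cfg) {
  if (is.null(cfg$data)) stop("config field 'data' (CSV path) is required")
  if (!file.exists(cfg$data)) stop("data file not found: ", cfg$data)
  raw <- utils::read.csv(cfg$data, stringsAsFactors = FALSE)
  preprocess(raw,
             school_col = cfg$school_col,
             class_col = cfg$class_col %||% stop("config field 'class_col' is required"),
             indicator_cols = unlist(cfg$indicators))
}

fit_to_list <- function(fit) {
  pt <- fit$partable
  list(loglik = fit$loglik,
       converged = fit$converged,
       n_iterations = fit$n_iterations,
       gradient_norm = fit$gradient_norm,
       df = degrees_of_freedom(fit$spec),
       n_free_parameters = length(fit$estimates),
       data = fit$data_summary,
       estimates = stats::setNames(as.list(pt$estimate), pt$label),
       se = stats::setNames(as.list(pt$se), pt$label),
       boundary = stats::setNames(as.list(pt$boundary), pt$label))
}

#' Serialize a fit, report or study to JSON
#'
#' @param x A \code{cb_fit}, \code{cb_report} or \code{cb_study}.
#' @param path Output path.
#' @param config Optional config list embedded for provenance.
#' @return \code{path}, invisibly.
#' @export
write_artifact_json <- function(x, path, config = NULL) {
  obj <- if (inherits(x, "cb_fit")) {
    fit_to_list(x)
  } else if (inherits(x, "cb_report")) {
    list(fit_table = x$fit_table,
         tests = x$tests,
         wald = x$wald,
         bias_proportions = x$bias_proportions,
         factor_icc = x$factor_icc,
         observed_icc = x$observed_icc,
         alpha = x$alpha,
         data = x$data_summary)
  } else if (inherits(x, "cb_study")) {
    list(n_replicates = x$n_replicates,
         n_converged = x$n_converged,
         nonconvergence_rate = x$nonconvergence_rate,
         unreliable = x$unreliable,
         level = x$level,
         alpha = x$alpha,
         rejection_rate = as.list(x$rejection_rate),
         mc_se = as.list(x$mc_se),
         delta_chisq = x$delta_chisq,
         p_values = x$p_values,
         seed = x$seed)
  } else stop("cannot serialize object of class ", class(x)[1L])
  if (!is.null(config)) obj$config <- unclass(config)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")
  invisible(path)
}

config_doublets <- function(cfg) {
  d <- cfg$model$doublets %||% list()
  lapply(d, as.integer)
}

#' CLI handler: fit the baseline cluster-bias model
#'
#' Reads the config's data, fits the baseline specification (one common
#' factor with loadings tied across levels plus configured doublets), writes
#' a JSON artifact and prints a summary.  Returns a shell exit status: 0 on
#' convergence.
#'
#' @param cfg A \code{cb_config}.
#' @return Integer exit status, invisibly.
#' @export
cli_fit <- function(cfg) {
  dat <- load_config_data(cfg)
  print(dat)
  models <- build_cluster_bias_models(ncol(dat$Y), config_doublets(cfg),
                                      n_levels = dat$n_levels)
  fit <- fit_ml(models$baseline, dat,
                fit_options(seed = cfg$seed))
  fit <- tryCatch(standard_errors(fit), error = function(e) fit)
  print(fit)
  if (!is.null(cfg$out))
    write_artifact_json(fit, file.path(cfg$out, "fit.json"), config = cfg)
  invisible(if (fit$converged) 0L else 1L)
}

#' CLI handler: run the cluster-bias testing sequence
#'
#' @inheritParams cli_fit
#' @return Integer exit status, invisibly (0 when all fits converged).
#' @export
cli_test_bias <- function(cfg) {
  dat <- load_config_data(cfg)
  report <- cluster_bias_test(dat, doublets = config_doublets(cfg),
                              alpha = cfg$alpha,
                              options = fit_options(seed = cfg$seed))
  print(report)
  if (!is.null(cfg$out))
    write_artifact_json(report, file.path(cfg$out, "cluster_bias_report.json"),
                        config = cfg)
  ok <- all(report$fit_table$converged)
  invisible(if (ok) 0L else 1L)
}

config_design <- function(cfg) {
  s <- cfg$simulation
  if (is.null(s)) stop("config block 'simulation' is required")
  do.call(simulation_design, c(s, list(seed = cfg$seed)))
}

#' CLI handler: simulate a dataset to CSV
#'
#' Writes the dataset as long-format CSV plus a sidecar JSON with the seed
#' and design for provenance.
#'
#' @inheritParams cli_fit
#' @return Integer exit status, invisibly.
#' @export
cli_simulate <- function(cfg) {
  design <- config_design(cfg)
  dat <- simulate_dataset(design)
  df <- as.data.frame(dat)
  out <- cfg$out %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(out, "simulated_data.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  sidecar <- list(seed = design$seed,
                  design = unclass(design),
                  n_rows = nrow(df),
                  design_hash = sum(utils::head(as.integer(
                    charToRaw(paste(deparse(unclass(design)),
                                    collapse = ""))), 1e4)))
  jsonlite::write_json(sidecar, file.path(out, "simulated_data.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("wrote ", nrow(df), " rows to ", csv)
  invisible(0L)
}

#' CLI handler: run a Monte-Carlo power or type-I-error study
#'
#' Uses the config's \code{simulation} block as the generating design and a
#' \code{study} block with fields \code{M}, \code{level} and optionally
#' \code{null} (TRUE for a type-I-error study).
#'
#' @inheritParams cli_fit
#' @return Integer exit status, invisibly.
#' @export
cli_power_study <- function(cfg) {
  design <- config_design(cfg)
  st <- cfg$study %||% list()
  M <- st$M %||% 200L
  level <- st$level %||% design$n_levels
  study <- if (isTRUE(st$null)) {
    type1_error_study(design, M = M, alpha = cfg$alpha, level = level,
                      seed = cfg$seed)
  } else {
    power_study(design, M = M, alpha = cfg$alpha, level = level,
                seed = cfg$seed)
  }
  print(study)
  if (!is.null(cfg$out))
    write_artifact_json(study, file.path(cfg$out, "study.json"), config = cfg)
  invisible(if (study$unreliable) 1L else 0L)
}
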