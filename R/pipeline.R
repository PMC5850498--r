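## End-to-end orchestration: quantify -> call -> bias test -> ancestral
## reconstruction (or non-C4 mean proxy) -> model -> threshold sweep.

default_analysis <- function() {
  list(threshold = 500, thresholds = c(300, 500, 1000, 1500),
       epsilon = 1, resamples = 1e4, seed = 1, log_scale = FALSE,
       proxy = "asr")
}

#' Read and validate a pipeline configuration
#'
#' A configuration is a YAML file (or equivalent list) with either a
#' `simulate` block (generator parameters plus `seed`) or an `input` block
#' (`tree`, `counts`, `lineages`, `libraries`, `totals` paths), plus an
#' optional `analysis` block overriding `threshold` (500), `thresholds`
#' (300/500/1000/1500), `epsilon` (1), `resamples` (1e4), `seed` (1),
#' `log_scale` (FALSE) and `proxy` (`"asr"` or `"c3_mean"`), and an
#' optional `output` directory.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Validated config list.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$simulate) == is.null(config$input))
    stop("config needs exactly one of a 'simulate' or an 'input' block")
  an <- utils::modifyList(default_analysis(),
                          if (is.null(config$analysis)) list()
                          else config$analysis)
  if (!an$proxy %in% c("asr", "c3_mean"))
    stop("analysis$proxy must be 'asr' or 'c3_mean'")
  if (!is.null(config$input)) {
    need <- c("counts", "lineages", "libraries", "totals")
    miss <- setdiff(need, names(config$input))
    if (length(miss))
      stop("input block missing: ", paste(miss, collapse = ", "))
    if (is.null(config$input$tree) && an$proxy == "asr")
      stop("input block has no tree; set analysis$proxy to 'c3_mean'")
  }
  config$analysis <- an
  config
}

#' Run the whole co-option analysis pipeline
#'
#' Executes quantification, co-option calling, the resampling bias test,
#' ancestral reconstruction (or the non-C4 mean proxy), co-option-count
#' modelling and the threshold-sensitivity sweep, from either a synthetic
#' dataset or input files, as described by the config. When the config has
#' an `output` directory, all stage tables and a JSON report are written
#' there.
#'
#' @param config Path to a YAML config, a config list (see
#'   [read_config()]), or a `coopt_sim` object (analysed with default
#'   analysis settings).
#' @return Object of class `coopt_report`: list with `config`,
#'   `expression`, `calls`, `counts`, `bias`, `asr`, `model`,
#'   `sensitivity`, `seeds`, `warnings`.
#' @export
run_all <- function(config) {
  warnings <- character(0)
  if (inherits(config, "coopt_sim")) {
    sim <- config
    config <- list(simulate = list(seed = sim$seed),
                   analysis = default_analysis())
  } else {
    config <- read_config(config)
    sim <- NULL
  }
  an <- config$analysis

  ## ---- inputs -------------------------------------------------------------
  if (!is.null(config$simulate) || !is.null(sim)) {
    if (is.null(sim)) {
      sc <- config$simulate
      seed <- if (is.null(sc$seed)) 1 else sc$seed
      sc$seed <- NULL
      cfg <- do.call(sim_config, sc)
      sim <- simulate_dataset(cfg, seed = seed)
    }
    tree <- sim$tree
    counts <- sim$counts; lineages <- sim$lineages
    libraries <- sim$libraries; totals <- sim$totals
  } else {
    inp <- read_expression_inputs(config$input$counts,
                                  config$input$lineages,
                                  config$input$libraries,
                                  config$input$totals)
    counts <- inp$counts; lineages <- inp$lineages
    libraries <- inp$libraries; totals <- inp$totals
    tree <- if (!is.null(config$input$tree))
      read_newick(file = config$input$tree) else NULL
  }
  meta <- species_metadata(libraries)

  ## ---- stages -------------------------------------------------------------
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  expr <- stage("quantify",
                build_expression_matrix(counts, lineages, libraries, totals))
  calls <- stage("call",
                 call_cooption(expr, meta, lineages,
                               threshold = an$threshold))
  cc <- count_cooptions(calls)
  ev <- cooption_events(calls)
  bias <- if (nrow(ev)) {
    stage("bias-test",
          resample_null(ev, family_sizes(lineages), B = an$resamples,
                        seed = an$seed))
  } else {
    warnings <- c(warnings, "no co-option events; bias test skipped")
    NULL
  }
  use_tree <- if (an$proxy == "asr") tree else NULL
  asr <- stage("asr",
               reconstruct_ancestral_traits(expr, meta, lineages, use_tree,
                                            epsilon = an$epsilon,
                                            log_scale = an$log_scale))
  model <- if (length(calls$universe) >= 4) {
    stage("model", fit_ols(cooption_model_frame(calls, asr),
                           "n_cooptions", c("ala", "leaf_root", "family")))
  } else {
    warnings <- c(warnings, "modelling universe too small; model skipped")
    NULL
  }
  sens <- stage("sensitivity",
                threshold_sensitivity(expr, meta, lineages, use_tree,
                                      thresholds = an$thresholds,
                                      epsilon = an$epsilon,
                                      log_scale = an$log_scale))

  report <- structure(
    list(config = config, expression = expr, calls = calls, counts = cc,
         bias = bias, asr = asr, model = model, sensitivity = sens,
         seeds = list(analysis = an$seed,
                      simulate = if (!is.null(sim)) sim$seed),
         warnings = warnings),
    class = "coopt_report")
  if (!is.null(config$output)) write_report(report, config$output)
  report
}

#' Write a pipeline report to disk
#'
#' Emits per-stage TSVs (`expression.tsv`, `calls.tsv`, `counts.tsv`,
#' `ancestral_traits.tsv`, `sensitivity.tsv`) and a machine-readable
#' `report.json` with the config echo, bias-test summary, model table and
#' seeds.
#'
#' @param report A `coopt_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "coopt_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$expression, "expression.tsv")
  wt(report$calls$calls, "calls.tsv")
  wt(report$counts$counts, "counts.tsv")
  wt(report$asr, "ancestral_traits.tsv")
  wt(report$sensitivity$table, "sensitivity.tsv")
  js <- list(
    config = report$config[setdiff(names(report$config), "output")],
    n_distinct_cooptions = report$counts$n_distinct,
    max_cooption_count = report$counts$max_count,
    bias = if (!is.null(report$bias))
      report$bias[c("observed", "null_mean", "null_sd", "p_value", "B",
                    "seed")],
    model = if (!is.null(report$model))
      list(anova = report$model$anova, r_squared = report$model$r_squared,
           n = report$model$n),
    degenerate_thresholds = report$sensitivity$degenerate,
    seeds = report$seeds,
    warnings = report$warnings)
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' @export
print.coopt_report <- function(x, ...) {
  cat("C4 co-option pipeline report\n")
  cat(sprintf("  lineages co-opted >= once: %d (max count %d)\n",
              x$counts$n_distinct, x$counts$max_count))
  if (!is.null(x$bias))
    cat(sprintf("  bias test: observed %d vs null %.2f +/- %.2f, P = %.4g\n",
                x$bias$observed, x$bias$null_mean, x$bias$null_sd,
                x$bias$p_value))
  if (!is.null(x$model)) {
    a <- x$model$anova[x$model$anova$term == "ala", ]
    cat(sprintf(
      "  ancestral leaf abundance: F = %.2f (df %d, %d), P = %.4g, R^2 = %.2f\n",
      a$F, a$df_term, a$df_resid, a$p, x$model$r_squared))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
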