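## OLS modelling of per-lineage co-option counts on ancestral expression
## traits, with sequential (Type I) ANOVA, exactly the "anova on lm"
## workflow.  The modelling universe is the lineages of families co-opted
## at least once.

#' Assemble the per-lineage modelling frame
#'
#' Joins co-option counts with reconstructed ancestral traits, restricted
#' to the modelling universe (lineages of families with at least one
#' co-option).
#'
#' @param calls A `cooption_calls` object.
#' @param asr Output of [reconstruct_ancestral_traits()].
#' @return data.frame `lineage_id`, `family` (factor), `n_cooptions`,
#'   `ala` (ancestral leaf abundance), `leaf_root` (ancestral leaf/root
#'   ratio).
#' @export
cooption_model_frame <- function(calls, asr) {
  stopifnot(inherits(calls, "cooption_calls"))
  counts <- calls$counts[calls$counts$lineage_id %in% calls$universe, ]
  wide <- merge(
    stats::setNames(asr[asr$trait == "leaf_rpkm",
                        c("lineage_id", "root_estimate")],
                    c("lineage_id", "ala")),
    stats::setNames(asr[asr$trait == "leaf_root_ratio",
                        c("lineage_id", "root_estimate")],
                    c("lineage_id", "leaf_root")),
    by = "lineage_id")
  df <- merge(counts[, c("lineage_id", "family_id", "n_cooptions")], wide,
              by = "lineage_id")
  df$family <- factor(df$family_id)
  df <- df[order(df$lineage_id),
           c("lineage_id", "family", "n_cooptions", "ala", "leaf_root")]
  rownames(df) <- NULL
  df
}

#' Sequential-ANOVA linear model of co-option counts
#'
#' Ordinary least squares via [stats::lm()] with terms entered in the
#' given order, followed by sequential (Type I) analysis of variance:
#' each term's F is computed on its extra sum of squares given the terms
#' before it. Factors are encoded as (levels - 1) treatment contrasts.
#'
#' @param data data.frame holding the response and predictors.
#' @param response Name of the response column.
#' @param terms Character vector of predictor columns, in the order they
#'   enter the sequential decomposition.
#' @param family `"gaussian"` (the default, plain OLS) or `"poisson"`
#'   (log-link GLM with analysis of deviance instead of ANOVA).
#' @return Object of class `cooption_lm`: list with `fit` (the `lm`),
#'   `anova` (data.frame `term`, `F`, `df_term`, `df_resid`, `p`),
#'   `r_squared`, `n`, `terms`, `coefficients`.
#' @examples
#' d <- data.frame(y = c(1, 2, 3), x = c(1, 2, 3))
#' fit_ols(d, "y", "x")$r_squared  # 1
#' @export
fit_ols <- function(data, response, terms, family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data), response %in% names(data),
            all(terms %in% names(data)))
  data <- droplevels(data[stats::complete.cases(
    data[, c(response, terms), drop = FALSE]), , drop = FALSE])
  form <- stats::reformulate(terms, response = response)
  model_df <- sum(vapply(terms, function(t)
    if (is.factor(data[[t]])) nlevels(data[[t]]) - 1L else 1L, integer(1)))
  if (nrow(data) < model_df + 2)
    stop("too few observations (", nrow(data), ") for ", model_df,
         " model df")

  if (family == "poisson") {
    fit <- stats::glm(form, data = data, family = stats::poisson())
    an <- stats::anova(fit, test = "Chisq")
    tab <- data.frame(term = rownames(an)[-1], F = NA_real_,
                      df_term = an$Df[-1], df_resid = an$`Resid. Df`[-1],
                      p = an$`Pr(>Chi)`[-1], stringsAsFactors = FALSE)
    return(structure(list(fit = fit, anova = tab, r_squared = NA_real_,
                          n = nrow(data), terms = terms, family = family,
                          coefficients = stats::coef(fit)),
                     class = "cooption_lm"))
  }

  fit <- stats::lm(form, data = data)
  if (fit$rank < model_df + 1) {
    al <- stats::alias(fit)$Complete
    stop("rank-deficient design; aliased term(s): ",
         paste(rownames(al), collapse = ", "))
  }
  an <- stats::anova(fit)
  keep <- rownames(an) != "Residuals"
  tab <- data.frame(term = rownames(an)[keep],
                    F = an$`F value`[keep],
                    df_term = an$Df[keep],
                    df_resid = an$Df[!keep],
                    p = an$`Pr(>F)`[keep],
                    stringsAsFactors = FALSE)
  structure(list(fit = fit, anova = tab,
                 r_squared = summary(fit)$r.squared,
                 n = nrow(data), terms = terms, family = family,
                 coefficients = stats::coef(fit)),
            class = "cooption_lm")
}

#' @export
print.cooption_lm <- function(x, ...) {
  cat(sprintf("Co-option count model (%s), n = %d, R^2 = %.3f\n",
              x$family, x$n,
              if (is.na(x$r_squared)) NA else x$r_squared))
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' Single-predictor test of co-option frequency
#'
#' One-predictor OLS; the F statistic equals the squared t of the slope.
#'
#' @param response Numeric response vector (co-option counts).
#' @param predictor Numeric predictor (e.g. ancestral leaf abundance).
#' @return List with `F`, `df_term`, `df_resid`, `p`, `r_squared`,
#'   `slope`.
#' @export
single_factor_test <- function(response, predictor) {
  ok <- is.finite(response) & is.finite(predictor)
  response <- response[ok]; predictor <- predictor[ok]
  if (length(unique(predictor)) < 2) stop("constant predictor")
  d <- data.frame(y = response, x = predictor)
  m <- fit_ols(d, "y", "x")
  slope <- unname(m$coefficients["x"])
  t2 <- (slope / summary(m$fit)$coefficients["x", "Std. Error"])^2
  stopifnot(abs(t2 - m$anova$F) < 1e-6 * max(1, m$anova$F))
  list(F = m$anova$F, df_term = m$anova$df_term,
       df_resid = m$anova$df_resid, p = m$anova$p,
       r_squared = m$r_squared, slope = slope)
}

#' Threshold-sensitivity sweep of the co-option model
#'
#' Re-runs calling, counting and sequential-ANOVA modelling at each rpkm
#' threshold. The ancestral reconstructions depend only on non-C4
#' expression, so they are computed once and reused. Thresholds that
#' produce no co-opted lineage (or a modelling frame too small to fit) are
#' marked degenerate and contribute no term rows.
#'
#' @param expr An `expression_matrix`.
#' @param meta Species-level or library metadata.
#' @param lineages data.frame `lineage_id`, `family_id`.
#' @param tree A `phylo` object, or `NULL` for the non-C4 mean proxy.
#' @param thresholds Numeric vector of rpkm thresholds
#'   (default `c(300, 500, 1000, 1500)`).
#' @param epsilon,log_scale Passed to [reconstruct_ancestral_traits()].
#' @return Object of class `threshold_sweep`: list with `table`
#'   (data.frame `threshold`, `term`, `F`, `df_term`, `df_resid`, `p`),
#'   `fits` (named list of `cooption_lm` or `NULL`), `degenerate`
#'   (thresholds with no fit), `asr`.
#' @export
threshold_sensitivity <- function(expr, meta, lineages, tree = NULL,
                                  thresholds = c(300, 500, 1000, 1500),
                                  epsilon = 1, log_scale = FALSE) {
  asr <- reconstruct_ancestral_traits(expr, meta, lineages, tree,
                                      epsilon = epsilon,
                                      log_scale = log_scale)
  fits <- list(); rows <- list(); degenerate <- numeric(0)
  for (T in thresholds) {
    calls <- call_cooption(expr, meta, lineages, threshold = T)
    key <- as.character(T)
    if (!length(calls$universe)) {
      degenerate <- c(degenerate, T)
      fits[[key]] <- NULL
      next
    }
    df <- cooption_model_frame(calls, asr)
    fit <- tryCatch(
      fit_ols(df, "n_cooptions", c("ala", "leaf_root", "family")),
      error = function(e) NULL)
    if (is.null(fit)) {
      degenerate <- c(degenerate, T)
      next
    }
    fits[[key]] <- fit
    rows[[key]] <- cbind(threshold = T, fit$anova)
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(threshold = numeric(0), term = character(0), F = numeric(0),
               df_term = integer(0), df_resid = integer(0), p = numeric(0))
  rownames(table) <- NULL
  structure(list(table = table, fits = fits, degenerate = degenerate,
                 asr = asr, thresholds = thresholds),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("Threshold sensitivity of the co-option model\n")
  print(x$table, row.names = FALSE)
  if (length(x$degenerate))
    cat("degenerate thresholds (no fit):",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}
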