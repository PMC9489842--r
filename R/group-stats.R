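# Mixed-effects comparison of per-network variables between diagnoses with a
# random intercept per cell line:
#   y ~ beta_dx * diagnosis + beta_n * n_neurons + beta_n2 * n_neurons^2
#       + (1 | cell_line_id)
# Diagnosis is coded 1 for the case group (SZ) and 0 for controls (HC); the
# diagnosis effect is tested with a Wald Z on beta_dx.

#' Validate and normalize a variable table
#'
#' @param table data frame with columns `network_id`, `cell_line_id`,
#'   `diagnosis` (0/1 numeric, or labels where `"SZ"` maps to 1 and `"HC"`
#'   to 0), `n_neurons`, and the response `y`.
#' @return the table with `diagnosis` coerced to 0/1 and
#'   `n_possible_connections` (`n(n-1)/2`) added if absent.
#' @export
variable_table <- function(table) {
  req <- c("network_id", "cell_line_id", "diagnosis", "n_neurons", "y")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop_fcdyn(paste("variable table lacks columns:",
                     paste(missing_cols, collapse = ", ")),
               "fcdyn_invalid_input")
  }
  if (anyNA(table$y)) {
    stop_fcdyn("missing responses are not allowed", "fcdyn_invalid_input")
  }
  if (is.character(table$diagnosis) || is.factor(table$diagnosis)) {
    table$diagnosis <- as.integer(as.character(table$diagnosis) == "SZ")
  }
  if (!all(table$diagnosis %in% c(0, 1))) {
    stop_fcdyn("diagnosis must be 0/1 (or HC/SZ labels)", "fcdyn_invalid_input")
  }
  if (is.null(table$n_possible_connections)) {
    table$n_possible_connections <-
      table$n_neurons * (table$n_neurons - 1) / 2
  }
  per_dx <- tapply(table$cell_line_id, table$diagnosis,
                   function(x) length(unique(x)))
  if (any(per_dx < 2)) {
    warning("fewer than 2 cell lines in some diagnosis group; the random ",
            "intercept is weakly identified", call. = FALSE)
  }
  table
}

#' Center the neuron-count covariates
#'
#' Adds `n_neurons_c` (mean-centered neuron count) and `n_neurons_sq_c`
#' (square of the centered count, itself re-centered) to the table. The
#' response and grouping columns are untouched; centering changes only the
#' intercept and covariate coefficients, not the diagnosis effect.
#'
#' @param table a [variable_table()].
#' @return the table with the two centered columns.
#' @export
center_covariates <- function(table) {
  table <- variable_table(table)
  nn <- table$n_neurons
  nn_c <- nn - mean(nn)
  sq <- nn_c^2
  table$n_neurons_c <- nn_c
  table$n_neurons_sq_c <- sq - mean(sq)
  table
}

#' Fit the mixed model for the diagnosis effect
#'
#' REML fit of `y ~ diagnosis [+ centered covariates] + (1 | cell_line_id)`
#' via `lme4::lmer`, with a Wald Z test on the diagnosis coefficient
#' (p from the standard normal, the convention for this model's reported
#' significance). A singular random-intercept fit (variance estimated at 0)
#' is kept, with a logged warning; the fixed effects then coincide with
#' ordinary least squares.
#'
#' @param table a [variable_table()]; centered covariate columns are created
#'   when needed.
#' @param include_covariates add the centered linear and quadratic
#'   neuron-count terms as fixed effects (default TRUE).
#' @param use_reml REML (default TRUE) or ML, the latter used for deviance
#'   comparison of models with different fixed effects.
#' @return a `mixed_model_result` list: `beta_diagnosis`, `se_diagnosis`,
#'   `z_diagnosis`, `p_diagnosis`, `beta_nneurons`, `beta_nneurons_sq`,
#'   `random_intercept_variance`, `residual_variance`, `deviance` (-2 log L,
#'   from the ML refit), `singular`, `covariates_included`, `n_rows`,
#'   `n_cell_lines`, and the underlying `fit`.
#' @export
fit_mixed_model <- function(table, include_covariates = TRUE,
                            use_reml = TRUE) {
  table <- center_covariates(table)
  if (nrow(table) < 10L) {
    stop_fcdyn("need at least 10 networks to fit the mixed model",
               "fcdyn_invalid_input")
  }
  if (length(unique(table$cell_line_id)) < 2L) {
    stop_fcdyn("need at least 2 cell lines for a random intercept",
               "fcdyn_invalid_input")
  }
  form <- if (include_covariates) {
    y ~ diagnosis + n_neurons_c + n_neurons_sq_c + (1 | cell_line_id)
  } else {
    y ~ diagnosis + (1 | cell_line_id)
  }
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = table, REML = use_reml,
                                control = lmer_control())),
    error = function(e) {
      stop_fcdyn(paste("mixed-model fit failed:", conditionMessage(e)),
                 "fcdyn_fit_failure")
    })
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("random-intercept variance estimated at its boundary (0); ",
            "fixed effects equal the ordinary-least-squares solution",
            call. = FALSE)
  }
  co <- summary(fit)$coefficients
  beta <- co["diagnosis", "Estimate"]
  se <- co["diagnosis", "Std. Error"]
  z <- beta / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    beta_diagnosis = beta,
    se_diagnosis = se,
    z_diagnosis = z,
    p_diagnosis = 2 * stats::pnorm(-abs(z)),
    beta_nneurons = if (include_covariates) co["n_neurons_c", "Estimate"] else NA_real_,
    beta_nneurons_sq = if (include_covariates) co["n_neurons_sq_c", "Estimate"] else NA_real_,
    random_intercept_variance = vc$vcov[vc$grp == "cell_line_id"],
    residual_variance = vc$vcov[vc$grp == "Residual"],
    deviance = ml_deviance(form, table),
    singular = singular,
    covariates_included = include_covariates,
    n_rows = nrow(table),
    n_cell_lines = length(unique(table$cell_line_id)),
    fit = fit
  ), class = "mixed_model_result")
}

# singular fits are kept (variance pinned at the boundary) and the
# one-network-per-cell-line degenerate case, where the intercept is
# confounded with the residual, must still return a fit
lmer_control <- function() {
  lme4::lmerControl(check.conv.singular = "ignore",
                    check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.rankZ = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    # quadratic neuron counts dwarf the 0/1 diagnosis column
                    # by design; the advisory is expected, not actionable
                    check.scaleX = "ignore")
}

# -2 log likelihood under ML (deviances of models with different fixed
# effects are only comparable under ML, not REML)
ml_deviance <- function(form, table) {
  fit_ml <- suppressMessages(lme4::lmer(form, data = table, REML = FALSE,
                                        control = lmer_control()))
  as.numeric(-2 * stats::logLik(fit_ml))
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(
    "<mixed_model_result> beta_diagnosis = %.4g (SE %.3g), Z = %.3g, p = %.3g\n",
    x$beta_diagnosis, x$se_diagnosis, x$z_diagnosis, x$p_diagnosis))
  cat(sprintf("  covariates: %s; random-intercept var = %.3g%s; ML deviance = %.4g\n",
              if (x$covariates_included) "n_neurons + n_neurons^2" else "none",
              x$random_intercept_variance,
              if (x$singular) " (boundary)" else "",
              x$deviance))
  invisible(x)
}

#' Deviance-based choice between covariate-free and covariate-adjusted models
#'
#' Fits both models, compares their ML deviances (a likelihood-ratio
#' statistic on 2 degrees of freedom, the linear and quadratic neuron-count
#' terms), and selects the adjusted model when the LRT p-value falls below
#' `threshold`. The final reported fits are REML as usual; both are
#' returned.
#'
#' @param table a [variable_table()].
#' @param threshold LRT significance threshold for adopting the covariates
#'   (default 0.05).
#' @return list with `selected` (`"adjusted"` or `"unadjusted"`),
#'   `deviance_difference`, `lrt_p`, `threshold`, and both fits
#'   (`fit_unadjusted`, `fit_adjusted`).
#' @export
deviance_select <- function(table, threshold = 0.05) {
  assert_scalar(threshold, "threshold", lower = 0, upper = 1)
  fit0 <- fit_mixed_model(table, include_covariates = FALSE)
  fit1 <- fit_mixed_model(table, include_covariates = TRUE)
  d <- fit0$deviance - fit1$deviance
  p <- stats::pchisq(max(d, 0), df = 2L, lower.tail = FALSE)
  list(selected = if (p < threshold) "adjusted" else "unadjusted",
       deviance_difference = d, lrt_p = p, threshold = threshold,
       fit_unadjusted = fit0, fit_adjusted = fit1)
}

#' Compare all FC variables between groups
#'
#' Runs [deviance_select()] per variable and reports the selected model's
#' diagnosis effect, optionally Bonferroni-adjusting p-values over the
#' variable set (off by default: per-variable p-values are the convention
#' for these nine dynamics variables).
#'
#' @param variables data frame with one row per network: metadata columns
#'   (`network_id`, `cell_line_id`, `diagnosis`, `n_neurons`) plus one
#'   column per response variable.
#' @param responses names of response columns (default: the nine FC
#'   variables present in `variables`).
#' @param bonferroni apply Bonferroni correction across responses.
#' @param threshold deviance-selection threshold (see [deviance_select()]).
#' @return data frame with one row per response: estimate, Z, p (adjusted if
#'   requested), selected covariate set, sample sizes.
#' @export
compare_groups <- function(variables, responses = NULL, bonferroni = FALSE,
                           threshold = 0.05) {
  if (is.null(responses)) {
    responses <- intersect(fc_variable_names(), names(variables))
  }
  rows <- lapply(responses, function(v) {
    tab <- variables
    tab$y <- tab[[v]]
    tab <- tab[!is.na(tab$y), , drop = FALSE]
    sel <- deviance_select(tab, threshold = threshold)
    fit <- if (sel$selected == "adjusted") sel$fit_adjusted else sel$fit_unadjusted
    data.frame(variable = v,
               beta_diagnosis = fit$beta_diagnosis,
               z = fit$z_diagnosis,
               p = fit$p_diagnosis,
               covariates = sel$selected,
               n_networks = fit$n_rows,
               n_cell_lines = fit$n_cell_lines,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p <- pmin(1, out$p * nrow(out))
  out
}
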