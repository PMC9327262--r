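# Cohort-level statistical layer: per-parameter age regressions with 95%
# CIs and t-based p-values, male/female mean comparisons (Student's
# t-test), slope-comparison Z-tests between the sexes, Bonferroni
# correction of the significance level, effect-size projections, normative
# standardisation, and the distribution / trade-off checks used to
# validate the tasks.

#' Linear regression of a parameter on age
#'
#' Ordinary least squares of `parameter ~ age` over the cohort table.
#' Missing parameter values are dropped (count reported as an attribute);
#' the p-value tests the null of zero slope with `n - 2` degrees of
#' freedom.
#'
#' @param cohort Cohort table (see [build_cohort_table()]): needs `age`
#'   plus the parameter column.
#' @param parameter Column name.
#' @return A `regression_result`: list with `parameter`, `slope`,
#'   `intercept`, `se`, `ci` (95%, length 2), `p`, `n`.
#' @export
age_regression <- function(cohort, parameter) {
  if (!parameter %in% names(cohort)) {
    stop("no column '", parameter, "' in cohort table")
  }
  y <- cohort[[parameter]]
  x <- cohort$age
  keep <- is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete rows for regression")
  if (sd(x) == 0) stop("age has zero variance; slope is unidentifiable")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  res <- list(
    parameter = parameter,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    se = sm$coefficients[2, 2],
    ci = unname(confint(fit, "x", level = 0.95)[1, ]),
    p = sm$coefficients[2, 4],
    n = length(x)
  )
  attr(res, "n_dropped") <- dropped
  class(res) <- "regression_result"
  res
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> %s: slope %.4g [%.4g, %.4g], p = %.3g (n = %d)\n",
    x$parameter, x$slope, x$ci[1], x$ci[2], x$p, x$n))
  invisible(x)
}

#' Male/female mean difference (Student's t-test)
#'
#' Pooled-variance two-sample t-test of the male - female difference in
#' mean parameter value, with its 95% confidence interval. Welch's
#' correction is available behind `pooled = FALSE`.
#'
#' @inheritParams age_regression
#' @param pooled Use the pooled-variance (classic Student) test.
#' @return List with `difference` (male - female), `ci`, `p`, `n_male`,
#'   `n_female`.
#' @export
sex_difference <- function(cohort, parameter, pooled = TRUE) {
  y <- cohort[[parameter]]
  g <- cohort$sex
  keep <- is.finite(y) & g %in% c("male", "female")
  y <- y[keep]; g <- g[keep]
  if (sum(g == "male") < 2 || sum(g == "female") < 2) {
    stop("need at least 2 participants of each sex")
  }
  tt <- t.test(y[g == "male"], y[g == "female"], var.equal = pooled)
  list(parameter = parameter,
       difference = unname(tt$estimate[1] - tt$estimate[2]),
       ci = as.numeric(tt$conf.int),
       p = tt$p.value,
       n_male = sum(g == "male"),
       n_female = sum(g == "female"))
}

#' Compare two regression slopes with a Z-test
#'
#' Tests whether two independently fitted regression slopes are equal:
#' `Z = (b1 - b2) / sqrt(SE1^2 + SE2^2)`, two-tailed p from the standard
#' normal. Typically used with the male and female age regressions of one
#' parameter.
#'
#' @param reg1,reg2 `regression_result`s (conventionally male, female), or
#'   lists with `slope` and `se`.
#' @return A `slope_comparison`: list with `b1`, `b2`, `se1`, `se2`, `z`,
#'   `p`.
#' @examples
#' compare_slopes(list(slope = -0.0111, se = 0.00089),
#'                list(slope = -0.0099, se = 0.00077))
#' @export
compare_slopes <- function(reg1, reg2) {
  if (!is.finite(reg1$se) || !is.finite(reg2$se) ||
      reg1$se <= 0 || reg2$se <= 0) {
    stop("slope standard errors must be positive")
  }
  z <- (reg1$slope - reg2$slope) / sqrt(reg1$se^2 + reg2$se^2)
  res <- list(b1 = reg1$slope, b2 = reg2$slope,
              se1 = reg1$se, se2 = reg2$se,
              z = z, p = 2 * pnorm(-abs(z)))
  class(res) <- "slope_comparison"
  res
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("<slope_comparison> b1 = %.4g, b2 = %.4g, Z = %.3f, p = %.4f\n",
              x$b1, x$b2, x$z, x$p))
  invisible(x)
}

#' Reconstruct a slope SE from a printed 95% confidence interval
#'
#' `SE = (upper - lower) / (2 * 1.96)`, the normal-quantile convention used
#' when back-computing from published tables.
#'
#' @param lower,upper CI bounds.
#' @return Standard error.
#' @export
se_from_ci <- function(lower, upper) {
  (upper - lower) / (2 * qnorm(0.975))
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise level (default 0.05).
#' @param n_comparisons Number of comparisons in the family.
#' @return `alpha / n_comparisons`.
#' @examples
#' bonferroni(0.05, 68)   # 7.4e-4 at two significant figures
#' @export
bonferroni <- function(alpha = 0.05, n_comparisons) {
  if (n_comparisons < 1) stop("'n_comparisons' must be >= 1")
  alpha / n_comparisons
}

#' Project a regression slope to an effect size
#'
#' `slope * years * scale`: converts a per-year slope to a change over a
#' span of years, optionally rescaled (e.g. a percent-of-task slope times
#' 300 targets/100 to object counts).
#'
#' @param slope Units per year.
#' @param years Span in years.
#' @param scale Optional multiplier (default 1).
#' @return Projected change.
#' @examples
#' project_effect(0.0005, 10)               # 0.005 cm/s per decade
#' project_effect(-0.1058 / 100, 10, 300)   # about -3.17 objects
#' @export
project_effect <- function(slope, years, scale = 1) {
  slope * years * scale
}

#' Fit a normative model on a reference cohort
#'
#' Per-parameter linear normative expectation in age and sex with a
#' residual scale, used to standardise participants against the reference
#' (healthy-control) cohort. Two standardisations are available per
#' parameter: `"z"` (residual over residual SD; two-sided parameters) and
#' `"zeta"` (rank-based inverse-normal transform of the residuals;
#' one-sided or clearly non-Gaussian parameters).
#'
#' @param reference Cohort table of the reference population (>= 30 rows).
#' @param parameters Character vector of parameter columns.
#' @param types Named character vector over `parameters` with values
#'   `"z"`/`"zeta"`; unnamed parameters default to `"z"`.
#' @return A `normative_model`.
#' @export
fit_normative <- function(reference, parameters, types = NULL) {
  if (nrow(reference) < 30) {
    stop("need at least 30 reference rows to fit a normative model")
  }
  tp <- setNames(rep("z", length(parameters)), parameters)
  if (!is.null(types)) tp[names(types)] <- types
  fits <- lapply(parameters, function(pn) {
    y <- reference[[pn]]
    keep <- is.finite(y) & is.finite(reference$age)
    df <- data.frame(y = y[keep], age = reference$age[keep],
                     male = as.numeric(reference$sex[keep] == "male"))
    if (nrow(df) < 10) return(NULL)
    fit <- lm(y ~ age + male, data = df)
    list(coef = coef(fit), sigma = summary(fit)$sigma,
         resid = sort(fit$residuals))
  })
  names(fits) <- parameters
  structure(list(parameters = parameters, types = tp, fits = fits),
            class = "normative_model")
}

normative_z <- function(model, row) {
  vapply(model$parameters, function(pn) {
    f <- model$fits[[pn]]
    y <- row[[pn]]
    if (is.null(f) || !length(y) || !is.finite(y)) return(NA_real_)
    expected <- f$coef[1] + f$coef[2] * row$age +
      f$coef[3] * as.numeric(row$sex == "male")
    r <- y - expected
    if (model$types[[pn]] == "zeta") {
      # rank-based inverse-normal position of the residual among the
      # reference residuals (Blom offsets)
      k <- findInterval(r, f$resid) + 0.5
      n <- length(f$resid)
      qnorm((k - 0.375) / (n + 0.25))
    } else {
      unname(r / f$sigma)
    }
  }, numeric(1))
}

#' Task score against a normative model
#'
#' Root sum of squares of the participant's standardised deviations from
#' the normative expectation: 0 is best (exactly at expectation), larger
#' is worse. Missing parameters are excluded with a warning reporting the
#' count.
#'
#' @param parameter_row One-row cohort-table slice (needs `age`, `sex` and
#'   the model's parameter columns).
#' @param model A [fit_normative()] model.
#' @return Non-negative score.
#' @export
task_score <- function(parameter_row, model) {
  z <- normative_z(model, parameter_row)
  miss <- sum(!is.finite(z))
  if (miss > 0) {
    warning(miss, " parameter(s) missing; excluded from the task score")
  }
  sqrt(sum(z[is.finite(z)]^2))
}

#' Fill the task-score column of a cohort table
#'
#' Fits the normative model on the table itself (in-sample reference) and
#' computes every row's score.
#'
#' @param cohort Cohort table.
#' @param parameters Parameters entering the score; defaults to a standard
#'   two-sided set present in the table.
#' @return The cohort table with `task_score` filled.
#' @export
add_task_scores <- function(cohort,
                            parameters = c("mean_hand_speed_left",
                                           "mean_hand_speed_right",
                                           "hand_bias_of_hits",
                                           "median_error",
                                           "steady_state_rate",
                                           "targets_hit")) {
  parameters <- intersect(parameters, names(cohort))
  parameters <- parameters[vapply(parameters, function(pn) {
    sum(is.finite(cohort[[pn]])) >= 10
  }, logical(1))]
  if (nrow(cohort) < 30 || !length(parameters)) {
    warning("cohort too small for an in-sample normative model; ",
            "task scores left NA")
    return(cohort)
  }
  model <- fit_normative(cohort, parameters)
  cohort$task_score <- vapply(seq_len(nrow(cohort)), function(i) {
    suppressWarnings(task_score(cohort[i, , drop = FALSE], model))
  }, numeric(1))
  cohort
}

#' Kolmogorov-Smirnov check against normality
#'
#' One-sample KS comparison of the values with a normal distribution at
#' their own mean and SD; used to check that a performance distribution is
#' roughly Gaussian with neither floor nor ceiling effects.
#'
#' @param values Numeric vector (>= 8 values, non-constant).
#' @return List with `statistic` and `p`.
#' @export
distribution_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8) stop("need at least 8 values")
  if (sd(values) == 0) stop("constant input: distribution check undefined")
  ks <- suppressWarnings(
    ks.test(values, "pnorm", mean(values), sd(values)))
  list(statistic = unname(ks$statistic), p = ks$p.value)
}

#' Target/distractor trade-off regression (OHA)
#'
#' OLS of the proportion of distractors avoided on the proportion of
#' targets hit across OHA trials. A positive slope means skilled
#' participants are better at both objectives (no trade-off); the
#' intercept measures baseline success at avoiding distractors.
#'
#' @param cohort Cohort table with columns `prop_targets_hit` and
#'   `prop_distractors_avoided` (fractions in `[0, 1]`), or an OHA table
#'   carrying `targets_hit` and `distractor` counts from which they can be
#'   derived via `n_targets`/`n_distractors` attributes.
#' @return A `regression_result` (slope, intercept, CI, p).
#' @export
tradeoff_regression <- function(cohort) {
  need <- c("prop_targets_hit", "prop_distractors_avoided")
  if (!all(need %in% names(cohort))) {
    stop("cohort must carry columns ", paste(need, collapse = " and "))
  }
  x <- cohort$prop_targets_hit
  y <- cohort$prop_distractors_avoided
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete rows")
  if (sd(x) == 0) stop("proportion of targets hit has zero variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  res <- list(parameter = "prop_distractors_avoided ~ prop_targets_hit",
              slope = unname(coef(fit)[2]),
              intercept = unname(coef(fit)[1]),
              se = sm$coefficients[2, 2],
              ci = unname(confint(fit, "x")[1, ]),
              p = sm$coefficients[2, 4],
              n = length(x))
  class(res) <- "regression_result"
  res
}

#' Full cohort analysis
#'
#' Runs the whole statistical battery over a cohort table: one age
#' regression per parameter, one male/female mean comparison per
#' parameter, and one male-vs-female slope-comparison Z-test per
#' parameter, each flagged against the Bonferroni-corrected significance
#' level. Parameters absent for the task (all-`NA` columns) are skipped.
#'
#' @param cohort Cohort table for one task.
#' @param parameters Parameter columns to analyse; defaults to every
#'   standard parameter present.
#' @param alpha Family-wise significance level.
#' @param n_comparisons Size of the comparison family used for the
#'   Bonferroni correction (a configured value, not inferred).
#' @return An `analysis_bundle`: list of data frames `age_effects`,
#'   `sex_effects`, `slope_comparisons`, plus `corrected_alpha`.
#' @export
analyze_cohort <- function(cohort, parameters = NULL, alpha = 0.05,
                           n_comparisons = 68) {
  std <- c("mean_hand_speed_left", "mean_hand_speed_right",
           "mean_hand_speed_bias", "movement_area_left",
           "movement_area_right", "movement_area_bias",
           "hand_bias_of_hits", "hand_selection_overlap",
           "hand_transition", "miss_bias", "median_error",
           "distractor_proportion", "object_processing_rate",
           "targets_hit", "steady_state_rate", "task_score")
  if (is.null(parameters)) parameters <- intersect(std, names(cohort))
  usable <- parameters[vapply(parameters, function(pn) {
    sum(is.finite(cohort[[pn]])) >= 3
  }, logical(1))]
  skipped <- setdiff(parameters, usable)
  corrected <- bonferroni(alpha, n_comparisons)

  age_rows <- lapply(usable, function(pn) {
    r <- age_regression(cohort, pn)
    data.frame(parameter = pn, slope = r$slope, intercept = r$intercept,
               se = r$se, ci_lower = r$ci[1], ci_upper = r$ci[2], p = r$p,
               n = r$n, significant = r$p < corrected,
               stringsAsFactors = FALSE)
  })

  both_sexes <- all(c("male", "female") %in% cohort$sex)
  sex_rows <- if (both_sexes) lapply(usable, function(pn) {
    s <- tryCatch(sex_difference(cohort, pn), error = function(e) NULL)
    if (is.null(s)) return(NULL)
    data.frame(parameter = pn, difference = s$difference,
               ci_lower = s$ci[1], ci_upper = s$ci[2], p = s$p,
               significant = s$p < corrected, stringsAsFactors = FALSE)
  }) else list()

  slope_rows <- if (both_sexes) lapply(usable, function(pn) {
    rm_ <- tryCatch(age_regression(cohort[cohort$sex == "male", ], pn),
                    error = function(e) NULL)
    rf_ <- tryCatch(age_regression(cohort[cohort$sex == "female", ], pn),
                    error = function(e) NULL)
    if (is.null(rm_) || is.null(rf_)) return(NULL)
    cmp <- compare_slopes(rm_, rf_)
    data.frame(parameter = pn, b_male = cmp$b1, b_female = cmp$b2,
               z = cmp$z, p = cmp$p, significant = cmp$p < corrected,
               stringsAsFactors = FALSE)
  }) else list()

  bundle <- list(
    age_effects = do.call(rbind, age_rows),
    sex_effects = do.call(rbind, Filter(Negate(is.null), sex_rows)),
    slope_comparisons = do.call(rbind, Filter(Negate(is.null), slope_rows)),
    corrected_alpha = corrected,
    skipped = skipped
  )
  class(bundle) <- "analysis_bundle"
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat(sprintf("<analysis_bundle> corrected alpha %.3g\n", x$corrected_alpha))
  if (!is.null(x$age_effects)) {
    sig <- x$age_effects$parameter[x$age_effects$significant]
    cat(sprintf("  age effects: %d parameters, %d significant%s\n",
                nrow(x$age_effects), length(sig),
                if (length(sig)) paste0(" (", paste(sig, collapse = ", "), ")")
                else ""))
  }
  if (!is.null(x$sex_effects) && nrow(x$sex_effects)) {
    cat(sprintf("  sex effects: %d parameters, %d significant\n",
                nrow(x$sex_effects), sum(x$sex_effects$significant)))
  }
  if (length(x$skipped)) {
    cat("  skipped (insufficient data):",
        paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an analysis bundle to delimited tables and a text report
#'
#' @param bundle An `analysis_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("age_effects", "sex_effects", "slope_comparisons")) {
    tab <- bundle[[nm]]
    if (!is.null(tab) && nrow(tab)) {
      write_delim6(tab, file.path(dir, paste0(nm, ".csv")))
    }
  }
  rep_path <- file.path(dir, "report.txt")
  con <- file(rep_path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("Cohort analysis report"), con)
  writeLines(sprintf("Corrected significance level: %.3g",
                     bundle$corrected_alpha), con)
  if (!is.null(bundle$age_effects)) {
    writeLines("", con)
    writeLines("Age effects (slope per year):", con)
    a <- bundle$age_effects
    writeLines(sprintf("  %-24s %+.4g [%+.4g, %+.4g]  p = %.3g%s",
                       a$parameter, a$slope, a$ci_lower, a$ci_upper, a$p,
                       ifelse(a$significant, "  *", "")), con)
  }
  if (!is.null(bundle$sex_effects) && nrow(bundle$sex_effects)) {
    writeLines("", con)
    writeLines("Sex effects (male - female):", con)
    s <- bundle$sex_effects
    writeLines(sprintf("  %-24s %+.4g [%+.4g, %+.4g]  p = %.3g%s",
                       s$parameter, s$difference, s$ci_lower, s$ci_upper,
                       s$p, ifelse(s$significant, "  *", "")), con)
  }
  if (!is.null(bundle$slope_comparisons) && nrow(bundle$slope_comparisons)) {
    writeLines("", con)
    writeLines("Male vs female age slopes (Z-test):", con)
    z <- bundle$slope_comparisons
    writeLines(sprintf("  %-24s b_m %+.4g, b_f %+.4g, Z = %+.3f, p = %.3g%s",
                       z$parameter, z$b_male, z$b_female, z$z, z$p,
                       ifelse(z$significant, "  *", "")), con)
  }
  if (length(bundle$skipped)) {
    writeLines("", con)
    writeLines(paste("Skipped parameters:",
                     paste(bundle$skipped, collapse = ", ")), con)
  }
  invisible(dir)
}
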