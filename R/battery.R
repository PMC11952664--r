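# The eight-model battery:
#   1: violence     ~ sex
#   2: depression   ~ sex + violence + sex:violence
#   3: expansion    ~ sex + violence + sex:violence
#   4: connectivity ~ sex + violence + sex:violence
#   5: depression   ~ sex + expansion + sex:expansion
#   6: depression   ~ sex + connectivity + sex:connectivity
#   7: depression   ~ sex + violence + expansion + sex:expansion
#   8: depression   ~ sex + violence + connectivity + sex:connectivity
# Coefficient labels follow the subscript convention: 0 intercept, 1 sex,
# 2 violence, 3 sex:violence, 4 network metric, 5 sex:metric.
battery_model_spec <- function(k) {
  stopifnot(k %in% 1:8)
  metric <- switch(as.character(k), "3" = , "5" = , "7" = "expansion",
                   "4" = , "6" = , "8" = "connectivity", NULL)
  lhs <- switch(as.character(k), "1" = "violence", "3" = "expansion",
                "4" = "connectivity", "depression")
  rhs <- switch(as.character(k),
    "1" = c("sex"),
    "2" = c("sex", "violence", "sex:violence"),
    "3" = c("sex", "violence", "sex:violence"),
    "4" = c("sex", "violence", "sex:violence"),
    "5" = c("sex", metric, paste0("sex:", metric)),
    "6" = c("sex", metric, paste0("sex:", metric)),
    "7" = c("sex", "violence", metric, paste0("sex:", metric)),
    "8" = c("sex", "violence", metric, paste0("sex:", metric))
  )
  labels <- c("(Intercept)" = "beta0", "sex" = "beta1", "violence" = "beta2",
              "sex:violence" = "beta3")
  if (k %in% 5:8) {
    # the metric enters the right-hand side only in models 5-8
    labels[metric] <- "beta4"
    labels[paste0("sex:", metric)] <- "beta5"
  }
  list(k = k, lhs = lhs, rhs = rhs, labels = labels)
}

battery_covariates <- function(spec, covariate_set) {
  demo <- c("age", "black", "white", "hispanic", "bmi_pct", "puberty", "ipr")
  lag <- paste0(spec$lhs, "_t1")
  switch(covariate_set,
    none = character(0),
    demographic = demo,
    lagged = lag,
    both = c(demo, lag),
    stop_config("unknown covariate_set '%s'", covariate_set)
  )
}

indicator_columns <- function(table) {
  vapply(table, function(x) {
    is.numeric(x) && all(x[!is.na(x)] %in% c(0, 1))
  }, logical(1))
}

#' Standardize a phenotype table
#'
#' Z-scores every non-indicator numeric column on the analysis sample (mean 0,
#' variance 1); indicator columns (sex, race/ethnicity flags, and any column
#' taking only values 0/1) are left untouched. Interaction terms are never
#' stored in the table: the battery constructs them after scaling as products
#' of scaled and indicator columns. Idempotent on already-scaled columns.
#'
#' @param table A phenotype `data.frame`.
#' @return The table with non-indicator columns z-scored.
#' @export
standardize_phenotypes <- function(table) {
  stopifnot(is.data.frame(table))
  ind <- indicator_columns(table)
  for (nm in names(table)[!ind]) {
    x <- table[[nm]]
    if (!is.numeric(x)) next
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop_config("column '%s' has zero variance and cannot be standardized", nm)
    }
    table[[nm]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Fit one model of the moderated regression battery
#'
#' Ordinary least squares on exactly the regressors of equation `k` plus the
#' requested sensitivity covariate set: `"none"`, `"demographic"` (age, Black,
#' White, Hispanic, BMI percentile, puberty category, income-to-poverty
#' ratio), `"lagged"` (the dependent variable at time 1), or `"both"`.
#' Coefficients are labelled by the battery's subscript scheme; p-values come
#' from the t distribution on the residual degrees of freedom. The data are
#' used as supplied — standardize first (see [standardize_phenotypes()]) to
#' obtain coefficients on the reported scale.
#'
#' @param k Model index 1..8.
#' @param table Phenotype `data.frame` (complete for the needed columns).
#' @param covariate_set One of `"none"`, `"demographic"`, `"lagged"`, `"both"`.
#' @return A `battery_fit`: coefficient table (`term`, `label`, `estimate`,
#'   `se`, `t`, `p`), `df_residual`, `sigma2`, `n`.
#' @export
fit_battery_model <- function(k, table, covariate_set = "none") {
  spec <- battery_model_spec(k)
  covs <- battery_covariates(spec, covariate_set)
  need <- unique(c(spec$lhs, unlist(strsplit(spec$rhs, ":", fixed = TRUE)), covs))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop_config("table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  dat <- table[, need, drop = FALSE]
  if (anyNA(dat)) stop_config("model %d requires complete cases; impute first", k)
  fml <- stats::as.formula(
    paste(spec$lhs, "~", paste(c(spec$rhs, covs), collapse = " + "))
  )
  fit <- stats::lm(fml, data = dat)
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    stop_config("rank deficiency in model %d: collinear column(s) %s",
                k, paste(names(stats::coef(fit))[alias], collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  terms_ <- rownames(ct)
  labels <- spec$labels[terms_]
  labels[is.na(labels)] <- terms_[is.na(spec$labels[terms_])]
  out <- data.frame(
    term = terms_,
    label = unname(labels),
    estimate = ct[, 1], se = ct[, 2], t = ct[, 3], p = ct[, 4],
    row.names = NULL
  )
  structure(
    list(k = k, covariate_set = covariate_set, coefficients = out,
         df_residual = fit$df.residual, sigma2 = sm$sigma^2,
         n = length(fit$residuals)),
    class = "battery_fit"
  )
}

#' @export
print.battery_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Model %d (covariates: %s), n = %d, residual df = %d\n",
              x$k, x$covariate_set, x$n, x$df_residual))
  print(cbind(x$coefficients[, c("term", "label")],
              round(x$coefficients[, c("estimate", "se", "t", "p")], digits)),
        row.names = FALSE)
  invisible(x)
}

#' Sex-stratified Pearson correlation
#'
#' Pearson correlation between two columns within one sex, with
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom and a
#' two-sided p-value.
#'
#' @param table Phenotype `data.frame` with a `sex` column.
#' @param x,y Column names.
#' @param sex_level 1 (female) or 0 (male).
#' @return List with `r`, `t`, `df`, `p`, `n`.
#' @export
stratified_correlation <- function(table, x, y, sex_level) {
  sub <- table[table$sex == sex_level, c(x, y)]
  sub <- sub[stats::complete.cases(sub), ]
  n <- nrow(sub)
  if (n < 3L) stop_config("subsample for sex == %s has fewer than 3 cases", sex_level)
  if (stats::sd(sub[[x]]) == 0 || stats::sd(sub[[y]]) == 0) {
    stop_config("zero variance in '%s' or '%s' within the stratum", x, y)
  }
  r <- stats::cor(sub[[x]], sub[[y]])
  corr_t_from_r(r, n)
}

#' t statistic from a correlation
#'
#' The exact identity `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `df = n - 2`
#' and a two-sided p-value; usable directly on printed correlations.
#'
#' @param r Pearson correlation.
#' @param n Sample size.
#' @return List with `r`, `t`, `df`, `p`, `n`.
#' @export
corr_t_from_r <- function(r, n) {
  df <- n - 2L
  t <- r * sqrt(df) / sqrt(1 - r^2)
  list(r = r, t = t, df = df, p = 2 * stats::pt(-abs(t), df), n = n)
}

#' One-way two-group ANOVA F from summary statistics
#'
#' Recovers the two-group one-way ANOVA from group sizes, means and SDs:
#' between-group mean square over the pooled within-group mean square, on
#' `(1, n1 + n2 - 2)` degrees of freedom. Identical to the square of the
#' pooled-variance two-sample t statistic.
#'
#' @param n1,mean1,sd1 First group's size, mean, SD.
#' @param n2,mean2,sd2 Second group's size, mean, SD.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
two_group_f <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  n <- n1 + n2
  gm <- (n1 * mean1 + n2 * mean2) / n
  ssb <- n1 * (mean1 - gm)^2 + n2 * (mean2 - gm)^2
  msw <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n - 2)
  F <- if (msw == 0) {
    if (ssb == 0) 0 else Inf
  } else {
    ssb / msw
  }
  list(F = F, df1 = 1L, df2 = n - 2L,
       p = stats::pf(F, 1, n - 2, lower.tail = FALSE))
}

#' Impute missing time-1 network metrics
#'
#' Fills missing time-1 salience-network metrics (`expansion_t1`,
#' `connectivity_t1`) with predictions from OLS regressions fitted on complete
#' cases, using only time-1 predictors (age, race/ethnicity indicators, BMI
#' percentile, puberty, income-to-poverty ratio and depression, all at time
#' 1). Time-2 columns are never consulted. Indices of imputed rows are
#' recorded in the `"imputation"` attribute.
#'
#' @param table Phenotype `data.frame`.
#' @param targets Columns to impute when missing.
#' @return The table with targets filled in.
#' @export
impute_metrics_time1 <- function(table,
                                 targets = c("expansion_t1", "connectivity_t1")) {
  predictors <- intersect(
    c("age_t1", "black", "white", "hispanic", "bmi_pct_t1", "puberty_t1",
      "ipr_t1", "depression_t1"),
    names(table)
  )
  if (!length(predictors)) stop_config("no time-1 predictor columns found")
  log_ <- list()
  for (tgt in intersect(targets, names(table))) {
    miss <- is.na(table[[tgt]])
    if (!any(miss)) next
    if (all(miss)) stop_config("all values of '%s' are missing", tgt)
    complete <- !miss & stats::complete.cases(table[, predictors, drop = FALSE])
    if (sum(complete) < 10L) {
      stop_config("fewer than 10 complete cases to impute '%s'", tgt)
    }
    fml <- stats::as.formula(paste(tgt, "~", paste(predictors, collapse = " + ")))
    fit <- stats::lm(fml, data = table[complete, , drop = FALSE])
    pred <- stats::predict(fit, newdata = table[miss, , drop = FALSE])
    table[[tgt]][miss] <- pred
    log_[[tgt]] <- which(miss)
  }
  attr(table, "imputation") <- log_
  table
}

#' Run the full moderated regression battery
#'
#' Imputes missing time-1 network metrics, standardizes the table, fits all 8
#' models under each of the 4 covariate sets (32 fits), and computes the
#' sex-stratified correlations of depression with violence and with
#' connectivity, plus the two-group ANOVA F for violence by sex (from the raw,
#' unscaled counts). No multiple-testing correction is applied across the
#' battery; the total number of fitted models is reported.
#'
#' @param table Phenotype `data.frame` (raw scale).
#' @param covariate_sets Covariate sets to run (default all four).
#' @return A `battery_report`: `fits` (tidy coefficient `data.frame`),
#'   `correlations`, `violence_anova`, `group_means`, `n`, `n_fits`.
#' @export
run_battery <- function(table,
                        covariate_sets = c("none", "lagged", "demographic", "both")) {
  if (anyNA(table[, intersect(c("expansion_t1", "connectivity_t1"), names(table))])) {
    table <- impute_metrics_time1(table)
  }
  raw <- table
  std <- standardize_phenotypes(table)
  rows <- list()
  fits <- list()
  for (k in 1:8) {
    for (cs in covariate_sets) {
      f <- fit_battery_model(k, std, cs)
      fits[[length(fits) + 1L]] <- f
      co <- f$coefficients
      co$model <- k; co$covariate_set <- cs; co$df <- f$df_residual
      rows[[length(rows) + 1L]] <- co
    }
  }
  tidy <- do.call(rbind, rows)[, c("model", "covariate_set", "term", "label",
                                   "estimate", "se", "t", "p", "df")]
  group_means <- c(
    female = mean(raw$violence[raw$sex == 1]),
    male = mean(raw$violence[raw$sex == 0])
  )
  anova_f <- two_group_f(
    sum(raw$sex == 1), group_means[["female"]], stats::sd(raw$violence[raw$sex == 1]),
    sum(raw$sex == 0), group_means[["male"]], stats::sd(raw$violence[raw$sex == 0])
  )
  correlations <- list(
    violence_depression_female = stratified_correlation(std, "violence", "depression", 1),
    violence_depression_male = stratified_correlation(std, "violence", "depression", 0),
    connectivity_depression_female = stratified_correlation(std, "connectivity", "depression", 1),
    connectivity_depression_male = stratified_correlation(std, "connectivity", "depression", 0)
  )
  structure(
    list(fits = tidy, models = fits, correlations = correlations,
         violence_anova = anova_f, group_means = group_means,
         n = nrow(table), n_fits = length(fits)),
    class = "battery_report"
  )
}

#' @export
print.battery_report <- function(x, digits = 3, ...) {
  cat(sprintf("Moderated regression battery: %d model fits on n = %d subjects\n",
              x$n_fits, x$n))
  cat(sprintf("Violence by sex: means %.2f (F) / %.2f (M), F(%d,%d) = %.2f, p = %.2g\n",
              x$group_means[["female"]], x$group_means[["male"]],
              x$violence_anova$df1, x$violence_anova$df2,
              x$violence_anova$F, x$violence_anova$p))
  for (nm in names(x$correlations)) {
    cc <- x$correlations[[nm]]
    cat(sprintf("  %s: r = %.3f, t(%d) = %.3f, p = %.3g\n",
                nm, cc$r, cc$df, cc$t, cc$p))
  }
  key <- x$fits[x$fits$covariate_set == "none" &
                  x$fits$label %in% c("beta1", "beta3", "beta5"), ]
  cat("Key unadjusted coefficients:\n")
  print(cbind(key[, c("model", "label", "term")],
              round(key[, c("estimate", "se", "t", "p")], digits)),
        row.names = FALSE)
  cat(sprintf("(no multiple-testing correction across the %d fitted models)\n",
              x$n_fits))
  invisible(x)
}
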