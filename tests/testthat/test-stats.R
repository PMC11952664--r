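test_that("standardization z-scores non-indicators and spares indicators", {
  tab <- simulate_phenotypes(100, seed = 51)
  std <- standardize_phenotypes(tab)
  for (nm in c("violence", "depression", "age", "ipr")) {
    expect_equal(mean(std[[nm]]), 0, tolerance = 1e-12)
    expect_equal(var(std[[nm]]), 1, tolerance = 1e-12)
  }
  for (nm in c("sex", "black", "white", "hispanic")) {
    expect_identical(std[[nm]], tab[[nm]])
  }
  expect_equal(standardize_phenotypes(std), std, tolerance = 1e-12)

  tab$age <- 16
  expect_error(standardize_phenotypes(tab), "'age'")
})

test_that("all eight models interpolate noiseless data exactly", {
  betas <- list(c(0.5, -1), c(1, 0.4, 0.1, 0.337), c(0, 0.2, -0.1, 0.05),
                c(-1, 0.3, 0.02, -0.2), c(2, 0.242, 0.5, -0.3),
                c(0, 0.238, 0.4, -0.326), c(1, 0.1, 0.2, 0.3, -0.4),
                c(0, -0.1, 0.25, 0.15, 0.05))
  for (k in 1:8) {
    fix <- exact_battery_table(k, betas[[k]])
    # summary.lm warns about the (intended) perfect fit
    fit <- suppressWarnings(fit_battery_model(k, fix$table, "none"))
    expect_equal(fit$coefficients$estimate, betas[[k]], tolerance = 1e-10)
    expect_equal(fit$df_residual, nrow(fix$table) - length(betas[[k]]))
  }
})

test_that("coefficient labels follow the subscript scheme", {
  tab <- simulate_phenotypes(80, seed = 52)
  f2 <- fit_battery_model(2, tab, "none")
  expect_equal(f2$coefficients$label, c("beta0", "beta1", "beta2", "beta3"))
  f7 <- fit_battery_model(7, tab, "none")
  expect_equal(f7$coefficients$label,
               c("beta0", "beta1", "beta2", "beta4", "beta5"))
  f3 <- fit_battery_model(3, tab, "none")
  expect_equal(f3$coefficients$label, c("beta0", "beta1", "beta2", "beta3"))
})

test_that("degrees of freedom are exact for every model and covariate set", {
  n <- 220
  tab <- simulate_phenotypes(n, seed = 53)
  p_base <- c(2, 4, 4, 4, 4, 4, 5, 5)
  extra <- c(none = 0, lagged = 1, demographic = 7, both = 8)
  for (k in 1:8) {
    for (cs in names(extra)) {
      fit <- fit_battery_model(k, tab, cs)
      expect_equal(fit$df_residual, n - p_base[k] - extra[[cs]],
                   info = sprintf("model %d, %s", k, cs))
    }
  }
  # the worked case: model 2, no covariates, n = 220 -> 4 coefficients
  expect_equal(fit_battery_model(2, tab, "none")$df_residual, 216L)
})

test_that("standardized estimates are invariant to affine input rescaling", {
  tab <- simulate_phenotypes(150, seed = 54)
  rescaled <- tab
  rescaled$violence <- tab$violence * 7 + 2
  rescaled$depression <- tab$depression * 0.1 - 5
  f1 <- fit_battery_model(2, standardize_phenotypes(tab), "none")
  f2 <- fit_battery_model(2, standardize_phenotypes(rescaled), "none")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("stratified correlation reproduces the t-from-r identity", {
  # printed female stratum: r = 0.264 on 141 subjects -> t(139) = 3.23
  out <- corr_t_from_r(0.264, 141)
  expect_equal(out$df, 139L)
  expect_equal(out$t, 3.227, tolerance = 1e-3)
  expect_lt(out$p, 0.01)

  tab <- data.frame(sex = rep(1, 20), a = 1:20, b = 2 * (1:20))
  perfect <- stratified_correlation(tab, "a", "b", 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-12)

  # agreement with cor.test on a random stratum
  set.seed(55)
  tab2 <- data.frame(sex = rep(c(0, 1), each = 30),
                     a = rnorm(60), b = rnorm(60))
  mine <- stratified_correlation(tab2, "a", "b", 0)
  ref <- cor.test(tab2$a[tab2$sex == 0], tab2$b[tab2$sex == 0])
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("t-based p agrees with a permutation null on a small sample", {
  set.seed(56)
  n <- 12
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  r_obs <- cor(x, y)
  B <- 100000
  r_perm <- vapply(seq_len(B), function(b) cor(x, sample(y)), numeric(1))
  p_perm <- mean(abs(r_perm) >= abs(r_obs))
  p_t <- corr_t_from_r(r_obs, n)$p
  mc_se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(p_perm - p_t), 3 * mc_se + 0.02)   # small-n normal-theory slack
})

test_that("summary-statistic ANOVA matches the squared two-sample t", {
  out <- two_group_f(141, 1.16, 2.37, 79, 2.95, 5.05)
  expect_equal(out$F, 12.7, tolerance = 0.05)
  expect_equal(out$df1, 1L); expect_equal(out$df2, 218L)

  # algebraic identity: F equals the square of the pooled-variance t
  sp2 <- ((141 - 1) * 2.37^2 + (79 - 1) * 5.05^2) / 218
  t_pooled <- (1.16 - 2.95) / sqrt(sp2 * (1 / 141 + 1 / 79))
  expect_equal(out$F, t_pooled^2, tolerance = 1e-12)

  expect_equal(two_group_f(10, 3, 1, 10, 3, 1)$F, 0)
})

test_that("time-1 imputation uses only time-1 predictors", {
  tab <- simulate_phenotypes(100, seed = 57)
  expect_identical(impute_metrics_time1(tab), tab, ignore_attr = TRUE)

  # metric that is an exact linear function of time-1 covariates
  tab$expansion_t1 <- 0.3 * tab$age_t1 - 0.2 * tab$ipr_t1 +
    0.5 * tab$depression_t1 + 1
  truth <- tab$expansion_t1
  drop_idx <- sample(100, 20)
  tab$expansion_t1[drop_idx] <- NA
  filled <- impute_metrics_time1(tab)
  expect_equal(filled$expansion_t1[drop_idx], truth[drop_idx],
               tolerance = 1e-8)
  expect_equal(attr(filled, "imputation")$expansion_t1, sort(drop_idx))

  # perturbing a time-2 column leaves imputations unchanged
  tab2 <- tab
  tab2$depression <- tab2$depression + 100
  tab2$expansion <- -tab2$expansion
  filled2 <- impute_metrics_time1(tab2)
  expect_equal(filled2$expansion_t1[drop_idx], filled$expansion_t1[drop_idx])
})

test_that("the battery report carries 32 fits and its decompositions", {
  tab <- simulate_phenotypes(220, missing_t1_frac = 0.1, seed = 58)
  report <- run_battery(tab)
  expect_equal(report$n_fits, 32L)
  expect_equal(nrow(unique(report$fits[, c("model", "covariate_set")])), 32L)
  expect_named(report$correlations,
               c("violence_depression_female", "violence_depression_male",
                 "connectivity_depression_female", "connectivity_depression_male"))
  expect_equal(report$violence_anova$df2, 218L)
  expect_output(print(report), "32 model fits")
})
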