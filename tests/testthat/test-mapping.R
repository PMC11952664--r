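make_posterior <- function(mean_mat, se_mat) {
  structure(list(mean = mean_mat, se = se_mat), class = "posterior_map")
}

make_mask <- function(mask, alpha = 0.01) {
  structure(list(mask = mask, alpha = alpha, n_tests = length(mask),
                 network = 1L),
            class = "membership_mask")
}

make_engagement <- function(values, svar) {
  structure(list(values = values, sampling_var = svar),
            class = "engagement_map")
}

make_prior <- function(mean_mat, between) {
  structure(list(mean = mean_mat, between_var = between, n_sessions_used = 2L),
            class = "prior_maps")
}

test_that("conjugate-normal update obeys its limiting cases", {
  raw <- make_engagement(matrix(2, 4, 1), matrix(1, 4, 1))
  mu <- matrix(0, 4, 1)

  flat <- fit_posterior_map(raw, make_prior(mu, matrix(Inf, 4, 1)))
  expect_equal(flat$mean, raw$values)           # uninformative prior

  dogmatic <- fit_posterior_map(raw, make_prior(mu, matrix(0, 4, 1)),
                                se_floor = 1e-3)
  expect_equal(dogmatic$mean, mu)               # prior variance zero
  expect_equal(dogmatic$se, matrix(1e-3, 4, 1)) # configured floor

  # prior mean 0, between-var 1, raw 2, sampling var 1
  bal <- fit_posterior_map(raw, make_prior(mu, matrix(1, 4, 1)), se_floor = 1e-3)
  expect_equal(bal$mean, matrix(1, 4, 1))
  expect_equal(bal$se^2, matrix(0.5, 4, 1))
})

test_that("posterior mean always lies between raw estimate and prior mean", {
  set.seed(41)
  V <- 200
  raw <- make_engagement(matrix(rnorm(V), V, 1),
                         matrix(rexp(V) + 0.1, V, 1))
  prior <- make_prior(matrix(rnorm(V), V, 1), matrix(rexp(V) + 0.1, V, 1))
  post <- fit_posterior_map(raw, prior)
  lo <- pmin(raw$values, prior$mean); hi <- pmax(raw$values, prior$mean)
  expect_true(all(post$mean >= lo - 1e-12 & post$mean <= hi + 1e-12))
})

test_that("membership test agrees with the normal tail at the Bonferroni level", {
  V <- 20484
  post <- make_posterior(matrix(c(5, -3, 4, rep(0, V - 3)), V, 1),
                         matrix(c(1, 0.1, 1, rep(1, V - 3)), V, 1))
  mask <- test_membership(post, 1, alpha = 0.01)
  # z = 5: one-sided p ~ 2.87e-7 < 0.01 / 20484 ~ 4.88e-7
  expect_lt(pnorm(5, lower.tail = FALSE), 0.01 / V)
  expect_true(mask$mask[1])
  # negative engagement is excluded regardless of magnitude
  expect_false(mask$mask[2])
  # z = 4: one-sided p ~ 3.17e-5 exceeds the corrected threshold
  expect_gt(pnorm(4, lower.tail = FALSE), 0.01 / V)
  expect_false(mask$mask[3])
  expect_equal(mask$n_tests, V)
  expect_error(test_membership(post, 1, alpha = 1.2), "alpha")
})

test_that("expansion is the member fraction and is monotone in alpha", {
  expect_equal(expansion(make_mask(c(rep(TRUE, 1024), rep(FALSE, 20484 - 1024)))),
               1024 / 20484)
  expect_equal(expansion(make_mask(rep(TRUE, 10))), 1)
  expect_equal(expansion(make_mask(rep(FALSE, 10))), 0)

  set.seed(42)
  V <- 3000
  post <- make_posterior(matrix(rnorm(V, 1, 2), V, 1), matrix(0.5, V, 1))
  ex <- vapply(c(1e-4, 0.01, 0.05), function(a) {
    expansion(test_membership(post, 1, alpha = a))
  }, numeric(1))
  expect_true(all(diff(ex) >= 0))
  # Bonferroni membership is contained in uncorrected membership
  corr <- test_membership(post, 1, alpha = 0.01)$mask
  uncorr <- test_membership(post, 1, alpha = 0.01, correction = "none")$mask
  expect_true(all(uncorr[corr]))
})

test_that("connectivity averages pairwise correlations of member vertices", {
  # exact construction: pairwise correlations 0.2, 0.4, 0.6 average to 0.4
  R <- matrix(c(1, 0.2, 0.4, 0.2, 1, 0.6, 0.4, 0.6, 1), 3)
  dat <- series_with_correlations(R, n_time = 40)
  bold <- bold_run(dat, tr = 1)
  expect_equal(connectivity(bold, make_mask(rep(TRUE, 3))), 0.4,
               tolerance = 1e-10)

  # identical member series correlate at exactly 1
  twin <- bold_run(rbind(dat[1, ], dat[1, ], dat[3, ]), tr = 1)
  expect_equal(connectivity(twin, make_mask(c(TRUE, TRUE, FALSE))), 1)

  # fewer than two members -> missing
  expect_true(is.na(connectivity(bold, make_mask(c(TRUE, FALSE, FALSE)))))

  # a zero-variance member invalidates the subject
  flat <- bold_run(rbind(dat[1, ], rep(2, 40)), tr = 1)
  out <- connectivity(flat, make_mask(c(TRUE, TRUE)))
  expect_true(is.na(out))
  expect_false(attr(out, "valid"))
})

test_that("masked-correlation shortcut equals the naive double loop", {
  set.seed(43)
  for (m in c(5, 23, 50)) {
    dat <- matrix(rnorm(m * 30), m, 30)
    bold <- bold_run(dat, tr = 1)
    fast <- connectivity(bold, make_mask(rep(TRUE, m)))
    acc <- 0
    for (i in 1:(m - 1)) for (j in (i + 1):m) acc <- acc + cor(dat[i, ], dat[j, ])
    expect_equal(fast, acc / (m * (m - 1) / 2), tolerance = 1e-12)
  }
})

test_that("estimated expansion approaches the true support fraction", {
  run_setting <- function(n_time, amplitude) {
    atlas <- make_parcel_atlas(400, 8, seed = 3)
    # true support is exactly the parcel: engagement outside it is zero
    truth <- default_prior_truth(atlas, within = 1, between_sd = 0.1,
                                 between_sd_out = 0)
    subs <- simulate_subject_engagement(atlas, truth$mean, truth$var, 6, seed = 4)
    pairs <- list(); cleans <- list()
    for (i in seq_along(subs)) {
      sess <- simulate_bold_session(subs[[i]], atlas, n_time = n_time, tr = 0.5,
                                    nuisance_magnitudes = list(noise_sd = 1),
                                    signal_amplitude = amplitude,
                                    seed = 100 + i)
      cleans[[i]] <- sess$bold
      pairs[[i]] <- lapply(split_halves(sess$bold), function(h) {
        normalize_engagement(parcel_dual_regression(h, atlas))
      })
    }
    prior <- estimate_prior(pairs)
    f_true <- mean(atlas$labels == atlas$salience_index)
    ex <- vapply(seq_along(subs), function(i) {
      raw <- normalize_engagement(parcel_dual_regression(cleans[[i]], atlas))
      post <- fit_posterior_map(raw, prior)
      expansion(test_membership(post, atlas$salience_index, alpha = 0.01))
    }, numeric(1))
    abs(mean(ex) - f_true)
  }
  weak <- run_setting(n_time = 100, amplitude = 0.4)
  strong <- run_setting(n_time = 400, amplitude = 2)
  expect_lt(strong, weak)        # monotone approach as T and signal grow
  expect_lt(strong, 0.05)
})
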