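#' Empirical-Bayes posterior engagement maps
#'
#' Vertex-wise conjugate-normal update combining a subject's noisy
#' dual-regression estimate with the population prior: the posterior mean is
#' the precision-weighted average of prior mean and raw estimate,
#' `(prior/tau2 + raw/s2) / (1/tau2 + 1/s2)`, and the posterior variance is
#' `1 / (1/tau2 + 1/s2)`, where `tau2` is the between-subject prior variance
#' and `s2` the sampling variance of the raw estimate. The degree of shrinkage
#' is thus set automatically by the prior variance and the data. Where
#' `tau2 = 0` the posterior collapses to the prior mean with standard error
#' `se_floor`; where `tau2` is infinite the raw estimate is returned
#' unshrunk.
#'
#' @param raw An `engagement_map` for one subject.
#' @param prior A `prior_maps` object.
#' @param se_floor Standard error reported where the posterior variance
#'   degenerates to zero (default 0.05, i.e. 5% of a unit-SD normalized map:
#'   the posterior can never claim more certainty than the prior mean itself
#'   carries).
#' @return A `posterior_map` with `mean` and `se` (`V x K`).
#' @export
fit_posterior_map <- function(raw, prior, se_floor = 0.05) {
  stopifnot(inherits(raw, "engagement_map"), inherits(prior, "prior_maps"))
  if (!identical(dim(raw$values), dim(prior$mean))) {
    stop_config("raw map is %s but prior is %s",
                paste(dim(raw$values), collapse = "x"),
                paste(dim(prior$mean), collapse = "x"))
  }
  tau2 <- prior$between_var
  s2 <- raw$sampling_var
  if (any(s2 <= 0, na.rm = TRUE)) stop_config("sampling variances must be positive")
  prec <- 1 / tau2 + 1 / s2                   # tau2 = 0 -> Inf, handled below
  post_var <- 1 / prec
  post_mean <- (prior$mean / tau2 + raw$values / s2) * post_var
  dogmatic <- tau2 == 0
  post_mean[dogmatic] <- prior$mean[dogmatic]
  post_var[dogmatic] <- 0
  flat_only <- is.infinite(s2) & !dogmatic    # no data: fall back to the prior
  post_mean[flat_only] <- prior$mean[flat_only]
  post_var[flat_only] <- tau2[flat_only]
  se <- sqrt(post_var)
  se[se < se_floor] <- se_floor
  structure(list(mean = post_mean, se = se), class = "posterior_map")
}

#' @export
print.posterior_map <- function(x, ...) {
  cat(sprintf("<posterior_map> %d vertices x %d networks\n",
              nrow(x$mean), ncol(x$mean)))
  invisible(x)
}

#' Vertex-wise network membership test
#'
#' Tests, at every vertex, whether the posterior engagement in the chosen
#' network is positive: a vertex is a member iff its posterior mean exceeds 0
#' AND the one-sided normal p-value of `mean / se` falls below the
#' Bonferroni-corrected level `alpha / V` (the number of tests is all `V`
#' vertices). Vertices with negative engagement are never members. A two-sided
#' variant (test at `alpha / V` two-sided, then drop negatives) is available
#' via `two_sided = TRUE`.
#'
#' @param posterior A `posterior_map`.
#' @param network Network index in `1..K`.
#' @param alpha Significance level (default 0.01).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param two_sided Use the two-sided-then-drop-negatives variant.
#' @return A `membership_mask` with `mask` (logical length `V`), `alpha`,
#'   `n_tests`.
#' @export
test_membership <- function(posterior, network, alpha = 0.01,
                            correction = c("bonferroni", "none"),
                            two_sided = FALSE) {
  stopifnot(inherits(posterior, "posterior_map"))
  correction <- match.arg(correction)
  K <- ncol(posterior$mean)
  V <- nrow(posterior$mean)
  if (network < 1L || network > K) stop_config("network must lie in 1..%d", K)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_config("alpha must lie in (0, 1)")
  }
  m <- posterior$mean[, network]
  se <- posterior$se[, network]
  z <- m / se
  p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
  thr <- if (correction == "bonferroni") alpha / V else alpha
  structure(
    list(mask = (m > 0) & (p < thr), alpha = alpha, n_tests = V,
         network = as.integer(network)),
    class = "membership_mask"
  )
}

#' @export
print.membership_mask <- function(x, ...) {
  cat(sprintf("<membership_mask> %d / %d vertices in network %d (alpha = %g)\n",
              sum(x$mask), x$n_tests, x$network, x$alpha))
  invisible(x)
}

#' Network expansion
#'
#' The proportion of all vertices classified as significant members of the
#' network — how much of the cortical sheet the individual's network covers.
#'
#' @param mask A `membership_mask`.
#' @return A number in `[0, 1]`.
#' @export
expansion <- function(mask) {
  stopifnot(inherits(mask, "membership_mask"))
  mean(mask$mask)
}

#' Within-network connectivity
#'
#' Mean Pearson correlation of the BOLD time series over all unordered pairs
#' of member vertices, computed on the full-length nuisance-regressed session.
#' Returns `NA` when fewer than two vertices are members; a member vertex with
#' zero temporal variance renders the metric `NA` with attribute
#' `valid = FALSE` (the subject is metric-invalid).
#'
#' @param bold The nuisance-regressed [bold_run()].
#' @param mask A `membership_mask` over the same vertices.
#' @return Mean pairwise correlation in `[-1, 1]`, or `NA`.
#' @export
connectivity <- function(bold, mask) {
  stopifnot(inherits(bold, "bold_run"), inherits(mask, "membership_mask"))
  if (nrow(bold$data) != length(mask$mask)) {
    stop_config("mask length (%d) does not match vertices (%d)",
                length(mask$mask), nrow(bold$data))
  }
  idx <- which(mask$mask)
  m <- length(idx)
  if (m < 2L) return(NA_real_)
  Z <- bold$data[idx, , drop = FALSE]
  Z <- Z - rowMeans(Z)
  norms <- sqrt(rowSums(Z^2))
  if (any(norms == 0)) {
    out <- NA_real_
    attr(out, "valid") <- FALSE
    return(out)
  }
  U <- Z / norms
  # sum of all pairwise correlations = ||sum of unit rows||^2
  total <- sum(colSums(U)^2)
  (total - m) / (m * (m - 1))
}

#' Per-subject salience-network metrics
#'
#' Convenience wrapper producing expansion, connectivity and a validity flag
#' for one subject from a posterior map and a processed session.
#'
#' @param posterior A `posterior_map`.
#' @param bold The nuisance-regressed full-length [bold_run()].
#' @param network Network index (the salience network).
#' @param alpha,correction Passed to [test_membership()].
#' @param invalid Force the subject metric-invalid (e.g. low-variance vertices).
#' @return List with `expansion`, `connectivity`, `valid`.
#' @export
network_metrics <- function(posterior, bold, network, alpha = 0.01,
                            correction = "bonferroni", invalid = FALSE) {
  mask <- test_membership(posterior, network, alpha = alpha,
                          correction = correction)
  conn <- connectivity(bold, mask)
  valid <- !invalid && !isFALSE(attr(conn, "valid"))
  list(
    expansion = expansion(mask),
    connectivity = as.numeric(conn),
    valid = valid
  )
}
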