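#' Parcel-seeded dual regression
#'
#' Two-stage estimate of per-vertex network engagement. Stage 1 averages the
#' time series over the vertices of each parcel, giving `K` network time
#' courses. Stage 2 regresses every vertex's time series on those `K` time
#' courses jointly; the multiple-regression coefficients are the engagement
#' values, and their OLS coefficient variances are returned as vertex-wise
#' sampling variances. A network whose seed time course is identically zero is
#' dropped from the regression: its engagement is set to 0 with infinite
#' sampling variance. Collinear parcel time courses are an error naming the
#' offending parcels.
#'
#' @param bold A [bold_run()] (normally nuisance-regressed).
#' @param atlas The `atlas_spec` seeding the regression.
#' @return An `engagement_map` with `values` and `sampling_var` (`V x K`).
#' @export
parcel_dual_regression <- function(bold, atlas) {
  stopifnot(inherits(bold, "bold_run"))
  check_atlas(atlas)
  Y <- bold$data
  V <- nrow(Y); T_ <- ncol(Y); K <- atlas$K
  if (V != atlas$V) {
    stop_config("BOLD has %d vertices but atlas expects %d", V, atlas$V)
  }
  # stage 1: mean time course within each parcel (K x T)
  tc <- rowsum(Y, group = atlas$labels, reorder = TRUE) /
    as.numeric(table(atlas$labels))
  keep <- apply(tc, 1L, function(x) any(x != 0))
  X <- t(tc[keep, , drop = FALSE])                       # T x K'
  k_eff <- ncol(X)
  if (T_ <= k_eff) stop_config("too few frames (%d) for %d regressors", T_, k_eff)
  qrX <- qr(X)
  if (qrX$rank < k_eff) {
    bad <- which(keep)[qrX$pivot[(qrX$rank + 1L):k_eff]]
    stop_config("collinear parcel time courses for parcel(s): %s",
                paste(bad, collapse = ", "))
  }
  # stage 2: joint OLS of every vertex on the K time courses
  B <- qr.coef(qrX, t(Y))                                # K' x V
  fitted <- X %*% B
  rss <- colSums((t(Y) - fitted)^2)
  sigma2 <- rss / (T_ - k_eff)
  xtx_inv_diag <- numeric(k_eff)
  xtx_inv_diag[qrX$pivot] <- diag(chol2inv(qr.R(qrX)))
  values <- matrix(0, V, K)
  svar <- matrix(Inf, V, K)
  values[, keep] <- t(B)
  svar[, keep] <- outer(sigma2, xtx_inv_diag)
  structure(list(values = values, sampling_var = svar), class = "engagement_map")
}

#' @export
print.engagement_map <- function(x, ...) {
  cat(sprintf("<engagement_map> %d vertices x %d networks\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Normalize engagement maps per network
#'
#' Dual-regression engagement is only defined up to a per-network scale (the
#' seed time courses have arbitrary amplitude), so each network's column is
#' divided by its SD across vertices (sampling variances by the squared
#' factor) before maps from different sessions are combined.
#'
#' @param map An `engagement_map`.
#' @return The rescaled `engagement_map`.
#' @export
normalize_engagement <- function(map) {
  stopifnot(inherits(map, "engagement_map"))
  s <- apply(map$values, 2L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  map$values <- sweep(map$values, 2L, s, "/")
  map$sampling_var <- sweep(map$sampling_var, 2L, s^2, "/")
  map
}

#' Estimate population prior maps from pseudo test-retest pairs
#'
#' Given, for each session, the engagement maps of its two pseudo test-retest
#' halves `(a, b)`, decomposes the variance at each vertex and network by the
#' method of moments: the prior mean is the grand mean of the per-session
#' averages `(a + b) / 2`; the half-map noise variance is
#' `w = mean((a - b)^2 / 2)`; and the between-subject variance is the sample
#' variance of the per-session averages minus `w / 2`, floored at zero. The
#' fraction of floored entries is recorded.
#'
#' @param pairs List of sessions, each a list of two `engagement_map`s (the
#'   halves) or two bare `V x K` matrices.
#' @param normalize If TRUE, [normalize_engagement()] is applied to every half
#'   map before estimation.
#' @return A `prior_maps` object with `mean`, `between_var` (both `V x K`),
#'   `n_sessions_used` and attribute `floor_fraction`.
#' @export
estimate_prior <- function(pairs, normalize = FALSE) {
  n <- length(pairs)
  if (n < 2L) stop_config("need >= 2 sessions to estimate between-subject variance")
  get_values <- function(h) {
    if (inherits(h, "engagement_map")) {
      if (normalize) h <- normalize_engagement(h)
      h$values
    } else {
      as.matrix(h)
    }
  }
  a1 <- get_values(pairs[[1]][[1]])
  V <- nrow(a1); K <- ncol(a1)
  mean_sum <- matrix(0, V, K); w_sum <- matrix(0, V, K)
  for (p in pairs) {
    a <- get_values(p[[1]]); b <- get_values(p[[2]])
    if (!identical(dim(a), c(V, K)) || !identical(dim(b), c(V, K))) {
      stop_config("engagement maps are not dimension-consistent")
    }
    mean_sum <- mean_sum + (a + b) / 2
    w_sum <- w_sum + (a - b)^2 / 2
  }
  grand <- mean_sum / n
  # stable two-pass sample variance of the per-session averages
  ss <- matrix(0, V, K)
  for (p in pairs) {
    m <- (get_values(p[[1]]) + get_values(p[[2]])) / 2
    ss <- ss + (m - grand)^2
  }
  var_m <- ss / (n - 1)
  w <- w_sum / n
  between <- var_m - w / 2
  floored <- between < 0
  between[floored] <- 0
  structure(
    list(mean = grand, between_var = between, n_sessions_used = n),
    floor_fraction = mean(floored),
    class = "prior_maps"
  )
}

#' @export
print.prior_maps <- function(x, ...) {
  cat(sprintf(
    "<prior_maps> %d vertices x %d networks from %d sessions (%.1f%% variance-floored)\n",
    nrow(x$mean), ncol(x$mean), x$n_sessions_used,
    100 * attr(x, "floor_fraction")))
  invisible(x)
}
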