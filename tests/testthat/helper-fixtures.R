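# Shared fixture builders; everything is generated in code at test time.

tiny_atlas <- function(V = 60, K = 3, seed = 1) {
  make_parcel_atlas(V, K, seed = seed)
}

# Noiseless BOLD with block-diagonal engagement (each vertex drives only its
# own parcel's network) and exactly orthogonal network time courses.
orthogonal_construction <- function(V = 60, K = 3, n_time = 80, seed = 5) {
  atlas <- tiny_atlas(V, K, seed = seed)
  set.seed(seed)
  S <- matrix(0, V, K)
  S[cbind(seq_len(V), atlas$labels)] <- runif(V, 0.5, 2)
  A <- t(qr.Q(qr(matrix(rnorm(n_time * K), n_time, K)))) * sqrt(n_time)
  list(atlas = atlas, S = S, A = A, bold = bold_run(S %*% A, tr = 0.5))
}

# m time series (rows) whose sample correlation matrix equals R exactly:
# columns of an orthonormal mean-zero basis mixed by chol(R).
series_with_correlations <- function(R, n_time = 40, seed = 2) {
  m <- nrow(R)
  set.seed(seed)
  X <- scale(matrix(rnorm(n_time * m), n_time, m), scale = FALSE)
  E <- qr.Q(qr(X))                      # orthonormal, mean-zero columns
  t(E %*% chol(R))                      # crossprod = R exactly
}

# A phenotype table whose model-k equation holds exactly (zero noise).
exact_battery_table <- function(k, beta, n = 60, seed = 3) {
  set.seed(seed)
  tab <- simulate_phenotypes(n, noise_sd = 1, seed = seed)
  spec_lhs <- switch(as.character(k), "1" = "violence", "3" = "expansion",
                     "4" = "connectivity", "depression")
  metric <- switch(as.character(k), "5" = , "7" = "expansion",
                   "6" = , "8" = "connectivity", NULL)
  x <- with(tab, switch(as.character(k),
    "1" = cbind(1, sex),
    "2" = cbind(1, sex, violence, sex * violence),
    "3" = cbind(1, sex, violence, sex * violence),
    "4" = cbind(1, sex, violence, sex * violence),
    "5" = cbind(1, sex, expansion, sex * expansion),
    "6" = cbind(1, sex, connectivity, sex * connectivity),
    "7" = cbind(1, sex, violence, expansion, sex * expansion),
    "8" = cbind(1, sex, violence, connectivity, sex * connectivity)
  ))
  stopifnot(ncol(x) == length(beta))
  tab[[spec_lhs]] <- as.numeric(x %*% beta)
  list(table = tab, lhs = spec_lhs, metric = metric)
}

# Independent OLS oracle: plain normal-equations solve.
normal_equations_fit <- function(y, X) {
  solve(crossprod(X), crossprod(X, y))
}
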