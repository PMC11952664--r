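#' Default generating truth for network engagement maps
#'
#' Builds population-mean and between-subject-variance maps over an atlas:
#' each vertex engages its own parcel's network at level `within` (0 in all
#' other networks), with homogeneous between-subject standard deviation
#' `between_sd` everywhere. This is the latent structure the prior-estimation
#' and posterior-mapping stages try to recover.
#'
#' @param atlas An `atlas_spec`.
#' @param within Peak mean engagement of a vertex in its own network.
#' @param between_sd Between-subject SD of a vertex's engagement in its own
#'   network.
#' @param between_sd_out Between-subject SD of engagement outside the vertex's
#'   own network (defaults to `between_sd`; set 0 for maps whose true support
#'   is exactly the parcel).
#' @param edge Mean engagement at the parcel boundary relative to the peak
#'   (default 0.2): engagement tapers linearly from `within` at the parcel
#'   core to `within * edge` at its ends, the graded profile real network
#'   maps show. `edge = 1` gives a flat profile.
#' @return List with `mean` and `var`, both `V x K` matrices.
#' @export
default_prior_truth <- function(atlas, within = 1, between_sd = 0.1,
                                between_sd_out = between_sd, edge = 0.2) {
  check_atlas(atlas)
  m <- matrix(0, atlas$V, atlas$K)
  for (k in seq_len(atlas$K)) {
    idx <- which(atlas$labels == k)
    nk <- length(idx)
    centre <- (nk + 1) / 2
    taper <- if (nk == 1) 1 else {
      1 - (1 - edge) * abs(seq_len(nk) - centre) / (centre - 1)
    }
    m[idx, k] <- within * taper
  }
  own <- cbind(seq_len(atlas$V), atlas$labels)
  v <- matrix(between_sd_out^2, atlas$V, atlas$K)
  v[own] <- between_sd^2
  list(mean = m, var = v)
}

#' Simulate true subject-level engagement maps
#'
#' Draws each subject's true engagement at vertex `v` in network `k` from
#' Normal(`prior_mean_truth[v,k]`, `prior_var_truth[v,k]`), independently
#' across subjects. Within a subject, a fraction `shared_frac` of each
#' network's between-subject variance is carried by a single network-level
#' factor, so that one individual's network is coherently larger or smaller
#' than average — the spatially structured way real network topography varies
#' — while the per-vertex marginal distribution is unchanged.
#'
#' @param atlas An `atlas_spec`.
#' @param prior_mean_truth,prior_var_truth `V x K` matrices of the generating
#'   population mean and between-subject variance.
#' @param n_subjects Number of subjects.
#' @param shared_frac Fraction of between-subject variance shared across a
#'   network's vertices (0 = fully independent vertices; default 0.5).
#' @param seed Integer seed.
#' @return A list of `subject_truth` objects, each with a `V x K` `maps`
#'   matrix and the subject's own `seed`.
#' @export
simulate_subject_engagement <- function(atlas, prior_mean_truth, prior_var_truth,
                                        n_subjects, shared_frac = 0.5,
                                        seed = 1L) {
  check_atlas(atlas)
  prior_mean_truth <- as.matrix(prior_mean_truth)
  prior_var_truth <- as.matrix(prior_var_truth)
  if (!identical(dim(prior_mean_truth), c(atlas$V, atlas$K)) ||
      !identical(dim(prior_var_truth), c(atlas$V, atlas$K))) {
    stop_config("truth maps must be %d x %d", atlas$V, atlas$K)
  }
  if (any(prior_var_truth < 0)) stop_config("prior_var_truth must be nonnegative")
  if (shared_frac < 0 || shared_frac > 1) {
    stop_config("shared_frac must lie in [0, 1]")
  }
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      g <- stats::rnorm(atlas$K)               # network-level factors
      dev <- sqrt(shared_frac) * matrix(g, atlas$V, atlas$K, byrow = TRUE) +
        sqrt(1 - shared_frac) * matrix(stats::rnorm(atlas$V * atlas$K),
                                       atlas$V, atlas$K)
      maps <- prior_mean_truth + dev * sqrt(prior_var_truth)
      structure(list(maps = maps, subject = i, seed = seed),
                class = "subject_truth")
    })
  })
}

#' Simulate one surface-style BOLD session
#'
#' Generates `y_v(t) = sum_k s_k(v) a_k(t) + drift + motion-coupled artifact +
#' spikes + white noise`. Network time courses `a_k` are AR(1)-smoothed
#' Gaussian noise, mutually decorrelated by orthogonalization and scaled to
#' `signal_amplitude`. Motion is a 6-parameter random walk; the artifact adds
#' motion-coupled signal through random vertex loadings; spikes are rare
#' whole-brain deflections. With every magnitude and the noise at zero the
#' output is exactly the product of maps and time courses.
#'
#' @param subject A `subject_truth` (true `V x K` engagement maps).
#' @param atlas The matching `atlas_spec`.
#' @param n_time Number of frames (default 400; the full acquisition used 1110).
#' @param tr Repetition time in seconds (default 0.555).
#' @param nuisance_magnitudes List with elements `noise_sd`, `drift`, `motion`,
#'   `spike_amplitude`, `spike_rate` (all >= 0).
#' @param signal_amplitude SD of each network time course.
#' @param seed Integer seed.
#' @return List with `bold` (a [bold_run()]), `motion` (T x 6 matrix) and
#'   `timecourses` (`K x T`, the generating `a_k`).
#' @export
simulate_bold_session <- function(subject, atlas, n_time = 400L, tr = 0.555,
                                  nuisance_magnitudes = list(),
                                  signal_amplitude = 1, seed = 1L) {
  check_atlas(atlas)
  stopifnot(inherits(subject, "subject_truth"))
  n_time <- as.integer(n_time)
  if (n_time < 2L) stop_config("n_time must be >= 2")
  if (n_time < atlas$K) {
    stop_config("n_time (%d) must be at least K (%d) to decorrelate the drives",
                n_time, atlas$K)
  }
  mags <- utils::modifyList(
    list(noise_sd = 1, drift = 0, motion = 0, spike_amplitude = 0,
         spike_rate = 0.01),
    nuisance_magnitudes
  )
  if (any(unlist(mags) < 0)) stop_config("nuisance magnitudes must be >= 0")
  V <- atlas$V; K <- atlas$K
  with_seed(seed, {
    # AR(1)-smoothed Gaussian network drives, orthogonalized then rescaled
    raw <- vapply(seq_len(K), function(k) {
      as.numeric(stats::filter(stats::rnorm(n_time), 0.6, method = "recursive"))
    }, numeric(n_time))
    A <- t(qr.Q(qr(raw))) * sqrt(n_time) * signal_amplitude     # K x T
    Y <- subject$maps %*% A

    motion <- matrix(stats::rnorm(n_time * 6L, sd = 1), n_time, 6L)
    motion <- apply(motion, 2L, cumsum) * 0.01                  # slow random walk
    if (mags$motion > 0) {
      W <- matrix(stats::rnorm(V * 6L), V, 6L)
      Y <- Y + mags$motion * (W %*% t(scale(motion)))
    }
    if (mags$drift > 0) {
      tgrid <- seq_len(n_time) / n_time
      d1 <- cos(pi * tgrid * 0.5); d2 <- tgrid - mean(tgrid)
      Y <- Y + mags$drift * (stats::rnorm(V) %*% t(d1) + stats::rnorm(V) %*% t(d2))
    }
    if (mags$spike_amplitude > 0 && mags$spike_rate > 0) {
      spikes <- which(stats::runif(n_time) < mags$spike_rate)
      for (s in spikes) Y[, s] <- Y[, s] + mags$spike_amplitude
    }
    if (mags$noise_sd > 0) {
      Y <- Y + matrix(stats::rnorm(V * n_time, sd = mags$noise_sd), V, n_time)
    }
    list(bold = bold_run(Y, tr), motion = motion, timecourses = A)
  })
}

# method-of-moments negative-binomial size from a target mean and SD;
# Inf (Poisson limit) when the target shows no overdispersion
nb_size_from_moments <- function(mu, sd) {
  v <- sd^2
  if (v <= mu) return(Inf)
  mu^2 / (v - mu)
}

#' Simulate a phenotype table
#'
#' Generates the variables of the moderated regression battery with known
#' coefficients. `sex` is Bernoulli (1 = female); `violence` is a past-year
#' exposure count drawn negative-binomially with sex-specific means (and a
#' dispersion matched by method of moments to the sex-specific SDs);
#' `expansion`, `connectivity` and `depression` follow the battery's linear
#' model equations with Normal(0, `noise_sd`^2) errors, on the standardized
#' coefficient scale on which the battery's estimates are reported.
#' Demographic covariates are drawn around the study cohort's moments, with
#' time-1 (`*_t1`) variants two years earlier and correlated with time 2.
#'
#' @param n Number of subjects (>= 4).
#' @param phenotype_coeffs List with elements `depression`, `expansion`,
#'   `connectivity`, each a length-4 vector `(b0, b_sex, b_violence,
#'   b_sex_violence)` of generating coefficients.
#' @param violence_means_by_sex Length-2 vector `(female, male)` of mean
#'   past-year exposure counts.
#' @param violence_sds_by_sex Length-2 vector of the matching SDs (sets the
#'   negative-binomial dispersion).
#' @param sex_fraction_female Probability a subject is female.
#' @param noise_sd Error SD shared by the three model equations (0 makes
#'   depression an exact function of sex and violence).
#' @param missing_t1_frac Fraction of subjects whose time-1 network metrics are
#'   set missing (to be imputed downstream).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `sex`, `violence`, `depression`,
#'   `expansion`, `connectivity`, `age`, `black`, `white`, `hispanic`,
#'   `bmi_pct`, `puberty`, `ipr` and `*_t1` variants (including
#'   `violence_t1`, `depression_t1`, `expansion_t1`, `connectivity_t1`).
#' @export
simulate_phenotypes <- function(n,
                                phenotype_coeffs = list(
                                  depression   = c(0, 0.399, 0.10, 0.337),
                                  expansion    = c(0, 0, 0, 0),
                                  connectivity = c(0, -0.30, 0, 0)
                                ),
                                violence_means_by_sex = c(1.16, 2.95),
                                violence_sds_by_sex = c(2.37, 5.05),
                                sex_fraction_female = 141 / 220,
                                noise_sd = 1,
                                missing_t1_frac = 0,
                                seed = 1L) {
  if (n < 4L) stop_config("n must be >= 4")
  if (any(violence_means_by_sex < 0)) stop_config("violence means must be >= 0")
  if (sex_fraction_female < 0 || sex_fraction_female > 1) {
    stop_config("sex_fraction_female must lie in [0, 1]")
  }
  co <- phenotype_coeffs
  for (nm in c("depression", "expansion", "connectivity")) {
    if (length(co[[nm]]) != 4L) stop_config("phenotype_coeffs$%s needs 4 values", nm)
  }
  with_seed(seed, {
    sex <- stats::rbinom(n, 1L, sex_fraction_female)
    draw_violence <- function() {
      mu <- ifelse(sex == 1L, violence_means_by_sex[1], violence_means_by_sex[2])
      size <- ifelse(sex == 1L,
                     nb_size_from_moments(violence_means_by_sex[1], violence_sds_by_sex[1]),
                     nb_size_from_moments(violence_means_by_sex[2], violence_sds_by_sex[2]))
      ifelse(is.finite(size),
             stats::rnbinom(n, size = size, mu = mu),
             stats::rpois(n, lambda = mu))
    }
    violence <- draw_violence()
    lin <- function(b, e) b[1] + b[2] * sex + b[3] * violence +
      b[4] * sex * violence + e
    expansion    <- lin(co$expansion,    stats::rnorm(n, sd = noise_sd))
    connectivity <- lin(co$connectivity, stats::rnorm(n, sd = noise_sd))
    depression   <- lin(co$depression,   stats::rnorm(n, sd = noise_sd))

    age <- stats::rnorm(n, 16.1, 0.57)
    black <- stats::rbinom(n, 1L, 0.377)
    white <- stats::rbinom(n, 1L, 0.436)
    hispanic <- stats::rbinom(n, 1L, 0.295)
    bmi_pct <- pmin(99.9, pmax(1, stats::rnorm(n, 72, 24.9)))
    puberty <- pmin(5, pmax(2, round(stats::rnorm(n, ifelse(sex == 1L, 4.4, 3.7), 0.55))))
    ipr <- stats::rlnorm(n, meanlog = log(3), sdlog = 0.8)

    tab <- data.frame(
      sex = sex, violence = violence, depression = depression,
      expansion = expansion, connectivity = connectivity,
      age = age, black = black, white = white, hispanic = hispanic,
      bmi_pct = bmi_pct, puberty = puberty, ipr = ipr,
      age_t1 = age - 2,
      bmi_pct_t1 = pmin(99.9, pmax(1, bmi_pct + stats::rnorm(n, 0, 5))),
      puberty_t1 = pmax(1, puberty - 1L),
      ipr_t1 = ipr * exp(stats::rnorm(n, 0, 0.2)),
      violence_t1 = draw_violence(),
      depression_t1 = 0.5 * depression + stats::rnorm(n, sd = noise_sd * sqrt(0.75)),
      expansion_t1 = 0.6 * expansion + stats::rnorm(n, sd = noise_sd * 0.8),
      connectivity_t1 = 0.6 * connectivity + stats::rnorm(n, sd = noise_sd * 0.8)
    )
    if (missing_t1_frac > 0) {
      n_miss <- round(missing_t1_frac * n)
      if (n_miss > 0) {
        idx <- sample.int(n, n_miss)
        tab$expansion_t1[idx] <- NA_real_
        tab$connectivity_t1[idx] <- NA_real_
      }
    }
    tab
  })
}
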