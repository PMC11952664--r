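#' Assemble a pipeline configuration
#'
#' Collects every stage's parameters into one list that round-trips through
#' YAML unchanged. Defaults describe the desk-scale synthetic run (V = 2000
#' vertices, T = 400 frames, n = 40 subjects); the full acquisition scale
#' (V = 20484, T = 1110, n = 220) is reached by overriding `V`, `n_time`
#' and `n_subjects`.
#'
#' @param ... Overrides for any default field.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_subjects = 40L,
    V = 2000L,
    K = 17L,
    n_time = 400L,
    tr = 0.555,
    salience_index = 8L,
    atlas_seed = 11L,
    seed = 1L,
    prior_seed = 2L,
    engagement_within = 1,
    engagement_between_sd = 0.2,
    signal_amplitude = 2,
    nuisance_magnitudes = list(noise_sd = 1, drift = 0.2, motion = 0.1,
                               spike_amplitude = 2, spike_rate = 0.01),
    cutoff_hz = 0.01,
    dvars_practical_pct = 5,
    dvars_alpha = 0.05,
    alpha = 0.01,
    correction = "bonferroni",
    se_floor = 1e-3,
    low_variance_threshold = 1e-10,
    covariate_sets = c("none", "lagged", "demographic", "both"),
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_config("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  utils::modifyList(cfg, over, keep.null = TRUE)
}

#' Write / read a pipeline configuration
#'
#' @param config A [run_config()] list.
#' @param path YAML file path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  string_hash(yaml::as.yaml(config))
}

process_session <- function(session, config) {
  dct <- dct_highpass_bases(ncol(session$bold$data), session$bold$tr,
                            cutoff_hz = config$cutoff_hz)
  flags <- dvars_outliers(session$bold,
                          practical_cutoff_pct = config$dvars_practical_pct,
                          alpha = config$dvars_alpha)
  design <- suppressWarnings(
    build_nuisance_design(session$motion, session$bold, flags, dct)
  )
  regress_nuisance(session$bold, design)
}

subject_map_metrics <- function(clean, atlas, prior, config) {
  raw <- normalize_engagement(parcel_dual_regression(clean, atlas))
  post <- fit_posterior_map(raw, prior, se_floor = config$se_floor)
  invalid <- any(low_variance_vertices(clean, config$low_variance_threshold))
  network_metrics(post, clean, atlas$salience_index, alpha = config$alpha,
                  correction = config$correction, invalid = invalid)
}

#' Run the full synthetic pipeline
#'
#' Executes every stage end to end on a synthetic cohort: cohort generation
#' (two sessions per subject), nuisance regression, pseudo test-retest prior
#' estimation (one randomly selected session per subject), empirical-Bayes
#' individual maps for each timepoint, salience-network expansion and
#' connectivity, time-1 metric imputation, and the 32-fit moderated
#' regression battery. Identical configurations and seeds reproduce identical
#' outputs. When `config$out_dir` is set, artifacts (`metrics.tsv`,
#' `coefficients.tsv`, `report.json`, `provenance.json`) are written there
#' after all computation succeeds; nothing is written on a failure path.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list: `phenotypes` (with computed `expansion`,
#'   `connectivity`, `valid` columns), `report` (a `battery_report`), `prior`,
#'   `atlas`, `provenance`.
#' @export
run_pipeline <- function(config = run_config()) {
  atlas <- make_parcel_atlas(config$V, config$K, seed = config$atlas_seed,
                             salience_index = config$salience_index)
  truth <- default_prior_truth(atlas, within = config$engagement_within,
                               between_sd = config$engagement_between_sd)
  subjects <- simulate_subject_engagement(atlas, truth$mean, truth$var,
                                          config$n_subjects,
                                          seed = config$seed)
  phen <- simulate_phenotypes(config$n_subjects, seed = config$seed + 1L)
  phen$valid <- rep(NA, config$n_subjects)

  # which timepoint feeds the prior, one per subject
  prior_session <- with_seed(config$prior_seed,
                             sample(1:2, config$n_subjects, replace = TRUE))
  pairs <- vector("list", config$n_subjects)
  metrics_t2 <- vector("list", config$n_subjects)
  metrics_t1 <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    cleans <- lapply(1:2, function(s) {
      sess <- simulate_bold_session(
        subjects[[i]], atlas, n_time = config$n_time, tr = config$tr,
        nuisance_magnitudes = config$nuisance_magnitudes,
        signal_amplitude = config$signal_amplitude,
        seed = config$seed + 1000L * s + i
      )
      process_session(sess, config)
    })
    halves <- split_halves(cleans[[prior_session[i]]])
    pairs[[i]] <- lapply(halves, function(h) {
      normalize_engagement(parcel_dual_regression(h, atlas))
    })
    metrics_t1[[i]] <- cleans[[1]]
    metrics_t2[[i]] <- cleans[[2]]
  }
  prior <- estimate_prior(pairs)
  for (i in seq_len(config$n_subjects)) {
    m2 <- subject_map_metrics(metrics_t2[[i]], atlas, prior, config)
    m1 <- subject_map_metrics(metrics_t1[[i]], atlas, prior, config)
    phen$expansion[i] <- m2$expansion
    phen$connectivity[i] <- m2$connectivity
    phen$expansion_t1[i] <- m1$expansion
    phen$connectivity_t1[i] <- m1$connectivity
    # usable for analysis: no low-variance vertices and a defined
    # connectivity at both timepoints (mirrors the study's exclusions)
    phen$valid[i] <- m2$valid && m1$valid &&
      !is.na(m2$connectivity) && !is.na(m1$connectivity)
  }
  analysed <- phen[phen$valid, , drop = FALSE]
  report <- run_battery(analysed, covariate_sets = config$covariate_sets)
  provenance <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    prior_seed = config$prior_seed,
    n_sessions_prior = prior$n_sessions_used,
    prior_floor_fraction = attr(prior, "floor_fraction"),
    n_subjects_analysed = nrow(analysed),
    n_subjects_excluded = sum(!phen$valid),
    package_version = as.character(utils::packageVersion("salnet"))
  )
  result <- structure(
    list(phenotypes = phen, report = report, prior = prior, atlas = atlas,
         provenance = provenance),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_phenotype_tsv(phen, file.path(config$out_dir, "metrics.tsv"))
    write_phenotype_tsv(report$fits, file.path(config$out_dir, "coefficients.tsv"))
    jsonlite::write_json(
      list(group_means = as.list(report$group_means),
           violence_anova = report$violence_anova,
           correlations = report$correlations,
           n_fits = report$n_fits),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects analysed (%d excluded), prior from %d sessions\n",
              x$provenance$n_subjects_analysed, x$provenance$n_subjects_excluded,
              x$prior$n_sessions_used))
  print(x$report)
  invisible(x)
}
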