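#' Discrete cosine transform high-pass basis
#'
#' Builds the low-frequency DCT columns used to remove slow scanner drift.
#' Basis `j` (1-indexed) is `cos(pi * j * (t + 1/2) / T)` for `t = 0..T-1`,
#' unit-normalized, so the columns are mutually orthogonal. When `n_bases` is
#' `NULL` it is derived from the cutoff as `floor(2 * T * TR * cutoff_hz)`:
#' at T = 1110 frames and TR = 0.555 s a 0.01 Hz cutoff gives 12 bases.
#'
#' @param n_time Number of frames.
#' @param tr Repetition time in seconds.
#' @param cutoff_hz High-pass cutoff in Hz (default 0.01).
#' @param n_bases Number of DCT columns; default derived from the cutoff.
#' @return A `n_time x n_bases` matrix (0 columns allowed).
#' @export
dct_highpass_bases <- function(n_time, tr, cutoff_hz = 0.01, n_bases = NULL) {
  n_time <- as.integer(n_time)
  if (is.null(n_bases)) n_bases <- floor(2 * n_time * tr * cutoff_hz)
  n_bases <- as.integer(n_bases)
  if (n_bases < 0L) stop_config("n_bases must be >= 0")
  if (n_bases > n_time) {
    stop_config("n_bases = %d exceeds the %d available frames", n_bases, n_time)
  }
  t_ <- seq_len(n_time) - 1L
  X <- vapply(seq_len(n_bases), function(j) {
    b <- cos(pi * j * (t_ + 0.5) / n_time)
    b / sqrt(sum(b^2))
  }, numeric(n_time))
  if (n_bases == 0L) X <- matrix(numeric(0), n_time, 0L)
  X
}

#' Flag motion-contaminated frames with a DVARS dual cutoff
#'
#' Computes the frame-to-frame signal-change statistic
#' `Dvar_t = mean_v (y_v(t) - y_v(t-1))^2` and flags a frame only when BOTH
#' cutoffs are exceeded: the practical cutoff (percent excursion of `Dvar`
#' above its robust baseline, `100 * (Dvar - med) / med > practical_cutoff_pct`)
#' and the statistical cutoff (one-sided p-value from a moment-matched
#' chi-square reference below `alpha` after Bonferroni correction across the
#' `T - 1` frame differences). The first frame has no predecessor and is never
#' flagged; a constant-in-time run yields no flags.
#'
#' @param bold A [bold_run()].
#' @param practical_cutoff_pct Practical threshold in percent (default 5).
#' @param alpha Significance level before Bonferroni (default 0.05).
#' @return Logical vector of length `T`.
#' @export
dvars_outliers <- function(bold, practical_cutoff_pct = 5, alpha = 0.05) {
  stopifnot(inherits(bold, "bold_run"))
  Y <- bold$data
  T_ <- ncol(Y)
  if (T_ < 3L) stop_config("DVARS needs at least 3 frames")
  d <- Y[, -1L, drop = FALSE] - Y[, -T_, drop = FALSE]
  dvar <- colMeans(d^2)
  flags <- rep(FALSE, T_)
  mu0 <- stats::median(dvar)
  if (mu0 <= 0) return(flags)
  # practical cutoff: percent change in signal variability over baseline
  pct <- 100 * (dvar - mu0) / mu0
  # statistical cutoff: chi-square moment match with robust variance
  s2 <- (stats::IQR(dvar) / 1.349)^2
  if (s2 <= 0) s2 <- stats::var(dvar)
  nu <- max(1, 2 * mu0^2 / s2)
  pval <- stats::pchisq(nu * dvar / mu0, df = nu, lower.tail = FALSE)
  hit <- pct > practical_cutoff_pct & pval < alpha / (T_ - 1L)
  flags[-1L] <- hit
  flags
}

#' Assemble the nuisance design matrix
#'
#' Expands the 6 motion parameters and the global signal (mean over vertices
#' per frame) into raw, backward-difference derivative (leading 0), square and
#' squared-derivative columns (28 in all), then appends the DCT drift columns
#' and one one-hot spike column per flagged frame. All-zero and linearly
#' dependent columns are dropped with a warning. White-matter and CSF
#' regressors are deliberately absent (they duplicate the global signal).
#'
#' @param motion `T x 6` motion parameter matrix.
#' @param bold A [bold_run()] (source of the global signal).
#' @param flags Logical vector of length `T` from [dvars_outliers()] (or NULL).
#' @param dct DCT basis matrix from [dct_highpass_bases()] (or NULL).
#' @return A `nuisance_design` object with `columns` (`T x p`) and `roles`.
#' @export
build_nuisance_design <- function(motion, bold, flags = NULL, dct = NULL) {
  stopifnot(inherits(bold, "bold_run"))
  motion <- as.matrix(motion)
  T_ <- ncol(bold$data)
  if (nrow(motion) != T_ || ncol(motion) != 6L) {
    stop_config("motion must be %d x 6", T_)
  }
  if (!is.null(flags) && length(flags) != T_) stop_config("flags must have length %d", T_)
  if (!is.null(dct) && nrow(dct) != T_) stop_config("DCT basis must have %d rows", T_)

  backdiff <- function(x) c(0, diff(x))
  expand <- function(x, what) {
    d <- backdiff(x)
    m <- cbind(x, d, x^2, d^2)
    colnames(m) <- paste0(what, c("", "_deriv", "_sq", "_derivsq"))
    m
  }
  global <- colMeans(bold$data)
  cols <- cbind(
    do.call(cbind, lapply(1:6, function(j) expand(motion[, j], paste0("motion", j)))),
    expand(global, "global")
  )
  roles <- c(rep(c("motion", "motion-derivative", "motion-square",
                   "derivative-square"), 6),
             "global", "global-derivative", "global-square", "derivative-square")
  if (!is.null(dct) && ncol(dct) > 0L) {
    colnames(dct) <- paste0("dct", seq_len(ncol(dct)))
    cols <- cbind(cols, dct)
    roles <- c(roles, rep("dct", ncol(dct)))
  }
  if (!is.null(flags) && any(flags)) {
    sp <- vapply(which(flags), function(t0) {
      v <- numeric(T_); v[t0] <- 1; v
    }, numeric(T_))
    colnames(sp) <- paste0("spike", which(flags))
    cols <- cbind(cols, sp)
    roles <- c(roles, rep("spike", ncol(sp)))
  }

  zero <- apply(cols, 2L, function(x) all(x == 0))
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero nuisance column(s): %s",
                    sum(zero), paste(colnames(cols)[zero], collapse = ", ")),
            call. = FALSE)
    cols <- cols[, !zero, drop = FALSE]
    roles <- roles[!zero]
  }
  qrX <- qr(cols)
  if (qrX$rank < ncol(cols)) {
    drop_idx <- qrX$pivot[(qrX$rank + 1L):ncol(cols)]
    warning(sprintf("dropping %d collinear nuisance column(s): %s",
                    length(drop_idx),
                    paste(colnames(cols)[drop_idx], collapse = ", ")),
            call. = FALSE)
    cols <- cols[, -drop_idx, drop = FALSE]
    roles <- roles[-drop_idx]
  }
  structure(list(columns = cols, roles = roles), class = "nuisance_design")
}

#' @export
print.nuisance_design <- function(x, ...) {
  cat(sprintf("<nuisance_design> %d frames x %d columns (%s)\n",
              nrow(x$columns), ncol(x$columns),
              paste(sprintf("%s:%d", names(table(x$roles)), table(x$roles)),
                    collapse = ", ")))
  invisible(x)
}

#' Simultaneous nuisance regression
#'
#' Removes each vertex's temporal mean and projects the time series onto the
#' orthogonal complement of all nuisance columns in a single joint
#' least-squares fit, so residuals are orthogonal to every design column and
#' per-vertex variance never increases. All regressors (motion expansion,
#' global signal terms, DCT drift columns, spike indicators) are removed
#' simultaneously, not sequentially.
#'
#' @param bold A [bold_run()].
#' @param design A `nuisance_design` (or a plain `T x p` matrix).
#' @return A residual [bold_run()].
#' @export
regress_nuisance <- function(bold, design) {
  stopifnot(inherits(bold, "bold_run"))
  X <- if (inherits(design, "nuisance_design")) design$columns else as.matrix(design)
  T_ <- ncol(bold$data)
  if (nrow(X) != T_) stop_config("design rows (%d) must match frames (%d)", nrow(X), T_)
  if (ncol(X) >= T_) {
    stop_config("rank deficiency: %d regressors for %d frames", ncol(X), T_)
  }
  Yc <- bold$data - rowMeans(bold$data)
  if (ncol(X) == 0L) return(bold_run(Yc, bold$tr))
  resid <- t(qr.resid(qr(X), t(Yc)))
  bold_run(resid, bold$tr)
}

#' Flag vertices with vanishing residual variance
#'
#' Subjects whose nuisance-regressed runs contain a vertex with (numerically)
#' zero temporal variance cannot support correlation-based network metrics and
#' are marked metric-invalid downstream.
#'
#' @param bold A residual [bold_run()].
#' @param threshold Variance threshold (default 1e-10).
#' @return Logical vector over vertices (TRUE = low variance).
#' @export
low_variance_vertices <- function(bold, threshold = 1e-10) {
  stopifnot(inherits(bold, "bold_run"))
  v <- apply(bold$data, 1L, stats::var)
  v < threshold
}
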