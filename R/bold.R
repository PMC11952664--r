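#' BOLD run container
#'
#' A `bold_run` is a dense vertex-by-time real matrix with its repetition time
#' in seconds. All processing stages consume and return this container.
#'
#' @param data Numeric matrix, vertices in rows, timepoints in columns.
#' @param tr Repetition time in seconds.
#' @return A `bold_run` object.
#' @export
bold_run <- function(data, tr) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop_config("BOLD data must be a finite numeric matrix")
  }
  if (ncol(data) < 2L) stop_config("a BOLD run needs at least 2 timepoints")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) {
    stop_config("tr must be a positive scalar (seconds)")
  }
  structure(list(data = data, tr = as.numeric(tr)), class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %d vertices x %d timepoints, TR = %.3f s\n",
              nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Split a run into pseudo test-retest halves
#'
#' Splits a session down the middle: the first half holds frames
#' `1..floor(T/2)`, the second the remainder, so concatenating the halves
#' reproduces the input exactly. The halves serve as pseudo test-retest data
#' for separating within-subject measurement noise from between-subject map
#' variability.
#'
#' @param bold A [bold_run()].
#' @return A list of two `bold_run` halves.
#' @export
split_halves <- function(bold) {
  stopifnot(inherits(bold, "bold_run"))
  T_ <- ncol(bold$data)
  if (T_ < 4L) stop_config("run too short to split: %d frames (need >= 4)", T_)
  h <- floor(T_ / 2)
  list(
    bold_run(bold$data[, seq_len(h), drop = FALSE], bold$tr),
    bold_run(bold$data[, (h + 1L):T_, drop = FALSE], bold$tr)
  )
}
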