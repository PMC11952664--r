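#' Write a surface time series in the flat-binary dialect
#'
#' Writes the vertex-by-time matrix as little-endian 64-bit reals in row-major
#' order (vertex 1's full time series first), with a JSON sidecar
#' (`<path>.json`) recording `V`, `T` and the repetition time in milliseconds.
#'
#' @param bold A [bold_run()].
#' @param path Destination file (sidecar written next to it).
#' @param extra Named list merged into the sidecar (e.g. a seed).
#' @return `path`, invisibly.
#' @export
write_surface_timeseries <- function(bold, path, extra = list()) {
  stopifnot(inherits(bold, "bold_run"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(bold$data)), con, size = 8L, endian = "little")
  side <- c(list(V = nrow(bold$data), T = ncol(bold$data),
                 tr_ms = bold$tr * 1000), extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a surface time series
#'
#' Reads the flat-binary dialect written by [write_surface_timeseries()]; the
#' sidecar's repetition time (milliseconds) is converted to seconds. When an
#' atlas is supplied the vertex count is validated against it.
#'
#' @param path File written by [write_surface_timeseries()].
#' @param atlas Optional `atlas_spec` for vertex-count validation.
#' @return A [bold_run()].
#' @export
read_surface_timeseries <- function(path, atlas = NULL) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop_config("missing sidecar: %s", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  V <- as.integer(side$V); T_ <- as.integer(side$T)
  if (!is.null(atlas)) {
    check_atlas(atlas)
    if (V != atlas$V) {
      stop_config("file has %d vertices but the atlas expects %d", V, atlas$V)
    }
  }
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = V * T_, size = 8L, endian = "little")
  if (length(x) != V * T_) {
    stop_config("expected %d values, read %d", V * T_, length(x))
  }
  bold_run(matrix(x, nrow = V, byrow = TRUE), tr = side$tr_ms / 1000)
}

#' Write a table as TSV
#' @param table A `data.frame`.
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV
#' @param path TSV written by [write_phenotype_tsv()].
#' @return A `data.frame`.
#' @export
read_phenotype_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
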