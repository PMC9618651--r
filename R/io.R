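#' Write / read a windowed dataset as a binary container with JSON manifest
#'
#' The tensor values are stored as little-endian doubles (`<path>.bin`,
#' inputs then targets in column-major order) and everything needed to
#' reconstruct and validate the dataset — shapes, window length, channel
#' names, sampling rate, provenance and the normalization-statistics hash —
#' lives in a JSON manifest (`<path>.json`), so training is reproducible
#' from artifacts alone.
#'
#' @param data A `windowed_dataset`.
#' @param path Base path (without extension).
#' @return `write_windowed()` returns `path` invisibly; `read_windowed()`
#'   returns a `windowed_dataset`.
#' @export
write_windowed <- function(data, path) {
  manifest <- list(
    dim_x = dim(data$x),
    dim_y = dim(data$y),
    features = dimnames(data$x)[[3]],
    targets = colnames(data$y),
    fs = data$fs,
    stats_hash = attr(data, "stats_hash"),
    provenance = data$provenance
  )
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(data$x), con, size = 8, endian = "little")
  writeBin(as.numeric(data$y), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_windowed
#' @export
read_windowed <- function(path) {
  mpath <- paste0(path, ".json")
  if (!file.exists(mpath)) abort_provenance(paste0("manifest not found: ", mpath))
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  dim_x <- as.integer(m$dim_x)
  dim_y <- as.integer(m$dim_y)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  vals_x <- readBin(con, "numeric", n = prod(dim_x), size = 8, endian = "little")
  vals_y <- readBin(con, "numeric", n = prod(dim_y), size = 8, endian = "little")
  if (length(vals_x) != prod(dim_x) || length(vals_y) != prod(dim_y)) {
    abort_provenance("binary payload does not match the manifest shapes")
  }
  x <- array(vals_x, dim = dim_x, dimnames = list(NULL, NULL, m$features))
  y <- matrix(vals_y, dim_y[1], dim_y[2], dimnames = list(NULL, m$targets))
  out <- new_windowed_dataset(x, y, tibble::as_tibble(m$provenance),
                              fs = m$fs %||% NA_real_)
  if (!is.null(m$stats_hash)) attr(out, "stats_hash") <- m$stats_hash
  out
}
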