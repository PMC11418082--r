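#' Checkpoint container format
#'
#' Generators and flows are serialized to a single binary archive: a 4-byte
#' little-endian header length, a JSON header (fields `format_version`,
#' `kind`, scalar metadata, and per-array names/dims), then the named
#' parameter arrays as little-endian doubles in header order. The format is
#' self-describing, so any externally trained model matching the contract can
#' be packaged into it.
#'
#' @param meta named list of scalar metadata (must include `kind`).
#' @param arrays named list of numeric vectors/matrices/arrays.
#' @param path file path.
#' @return `read_checkpoint()` returns `list(meta = , arrays = )`.
#' @name latsr-checkpoint
NULL

#' @rdname latsr-checkpoint
#' @export
write_checkpoint <- function(meta, arrays, path) {
  stopifnot(is.list(meta), !is.null(meta$kind))
  stopifnot(is.list(arrays), length(names(arrays)) == length(arrays))
  meta$format_version <- 1L
  header <- list(
    meta = meta,
    arrays = lapply(arrays, function(a) {
      list(dim = if (is.null(dim(a))) length(a) else dim(a))
    })
  )
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  for (a in arrays)
    writeBin(as.numeric(a), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname latsr-checkpoint
#' @export
read_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)),
                               simplifyVector = TRUE)
  arrays <- list()
  for (nm in names(header$arrays)) {
    d <- as.integer(header$arrays[[nm]]$dim)
    v <- readBin(con, "double", n = prod(d), size = 8L, endian = "little")
    arrays[[nm]] <- if (length(d) > 1L) array(v, d) else v
  }
  list(meta = header$meta, arrays = arrays)
}
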