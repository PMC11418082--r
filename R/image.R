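#' Image containers and value-range conventions
#'
#' Images are plain numeric arrays with dimensions `c(C, H, W)` (channels
#' first). Two value ranges are used:
#' \itemize{
#'   \item internal range `[-1, 1]`: what generators emit and what the
#'     data-fidelity term and degradation operators consume (the usual GAN
#'     output convention);
#'   \item file range `[0, 1]`: what PNG/TIFF readers and writers and the
#'     feature extractors see.
#' }
#' `to_internal()` and `to_file_range()` convert between the two.
#'
#' @param x numeric array or matrix.
#' @param C,H,W integer dimensions.
#' @name latsr-images
NULL

#' Construct a channels-first image array
#'
#' @param x numeric vector, matrix (taken as 1 x H x W) or C x H x W array.
#' @param C,H,W dimensions, required when `x` is a vector.
#' @return numeric array with dim `c(C, H, W)`.
#' @export
as_image <- function(x, C = NULL, H = NULL, W = NULL) {
  if (is.matrix(x)) {
    x <- array(x, c(1L, nrow(x), ncol(x)))
  } else if (is.null(dim(x))) {
    stopifnot(!is.null(C), !is.null(H), !is.null(W))
    x <- array(as.numeric(x), c(C, H, W))
  }
  stopifnot(length(dim(x)) == 3L)
  storage.mode(x) <- "double"
  x
}

check_image <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L)
    stop(what, " must be a C x H x W array", call. = FALSE)
  if (!all(is.finite(img)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(img)
}

#' Map a file-range image ([0,1]) to the internal range ([-1,1])
#' @param img C x H x W array in `[0, 1]`.
#' @return array in `[-1, 1]`.
#' @export
to_internal <- function(img) 2 * img - 1

#' Map an internal-range image ([-1,1]) to the file range ([0,1])
#' @param img C x H x W array in `[-1, 1]`; values are clipped.
#' @return array in `[0, 1]`.
#' @export
to_file_range <- function(img) pmin(pmax((img + 1) / 2, 0), 1)

#' Read a multi-channel image file
#'
#' TIFF files may store channels either as samples-per-pixel or as separate
#' pages; both are accepted. PNG reads through [png::readPNG].
#'
#' @param path file path (.tif/.tiff/.png).
#' @return C x H x W array in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) > 1L) {
      # channels as pages
      a <- vapply(pages, function(p) {
        if (length(dim(p)) == 3L) p[, , 1L] else p
      }, matrix(0, nrow(pages[[1L]]), ncol(pages[[1L]])))
      img <- aperm(a, c(3L, 1L, 2L))
    } else {
      p <- pages[[1L]]
      img <- if (length(dim(p)) == 3L) aperm(p, c(3L, 1L, 2L)) else
        array(p, c(1L, dim(p)))
    }
  } else if (ext == "png") {
    p <- png::readPNG(path)
    img <- if (length(dim(p)) == 3L) aperm(p, c(3L, 1L, 2L)) else
      array(p, c(1L, dim(p)))
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  storage.mode(img) <- "double"
  img
}

#' Write a multi-channel image file
#'
#' Values are clipped to `[0, 1]`. Multi-channel TIFFs are written with
#' channels as samples-per-pixel.
#'
#' @param img C x H x W array in `[0, 1]`.
#' @param path output path (.tif/.tiff/.png).
#' @param bits bit depth for TIFF (8 or 16).
#' @export
write_image <- function(img, path, bits = 16L) {
  check_image(img)
  img <- pmin(pmax(img, 0), 1)
  hwc <- aperm(img, c(2L, 3L, 1L))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(hwc, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    if (dim(hwc)[3L] == 1L) hwc <- hwc[, , 1L]
    if (length(dim(hwc)) == 3L && dim(hwc)[3L] == 2L)
      stop("PNG does not support 2-channel images", call. = FALSE)
    png::writePNG(hwc, path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}
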