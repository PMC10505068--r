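# Loading, validating, mirroring and writing 16-bit grayscale array scans.

#' Load a macroarray scan
#'
#' Reads a single-channel grayscale TIFF (losslessly compressed or
#' uncompressed; 16-bit preferred, 8-bit promoted) into an
#' \code{\linkS4class{ArrayImage}} in native intensity units.  The image may
#' be mirrored (flipped left-right) depending on which side of the membrane
#' faced the scanner; mirroring, when requested, happens before any
#' processing.
#'
#' @param path path to the TIFF file.
#' @param mirror logical; flip the image left-right after loading.
#' @param format \code{"tiff"} (default) or \code{"png"} for other lossless
#'   grayscale sources.
#' @return An \code{\linkS4class{ArrayImage}}.
#' @seealso \code{\link{writeArrayImage}}, \code{\link{checkSaturation}}
#' @export
loadArrayImage <- function(path, mirror = FALSE, format = c("tiff", "png")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("image file not found: ", path)
  if (format == "tiff") {
    px <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  } else {
    px <- png::readPNG(path)
    # png values are fractional; promote to 16-bit units
    px <- round(px * 65535)
  }
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] == 1L) px <- px[, , 1L]
    else stop("multi-channel image: a single grayscale channel is required")
  }
  bits <- attr(px, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
  if (bits == 8L) px <- px * 257  # promote 0..255 to 0..65535
  if (max(px) > 65535 || min(px) < 0)
    stop("pixel values outside the 16-bit range 0..65535")
  img <- new("ArrayImage", pixels = matrix(as.numeric(px), nrow(px), ncol(px)),
             source = path, mirrored = FALSE, bitDepth = as.integer(bits))
  if (mirror) img <- mirrorImage(img) else img
}

#' Write an ArrayImage as a 16-bit uncompressed grayscale TIFF
#'
#' @param img an \code{\linkS4class{ArrayImage}} (or bare numeric matrix).
#' @param path output path.
#' @return The path, invisibly.  Round-trips every pixel value exactly.
#' @export
writeArrayImage <- function(img, path) {
  px <- if (is(img, "ArrayImage")) img@pixels else img
  tiff::writeTIFF(round(px) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Mirror an image left-right
#'
#' An involution: mirroring twice restores the original pixel grid.
#'
#' @param img an \code{\linkS4class{ArrayImage}}.
#' @return The mirrored \code{ArrayImage}, with the \code{mirrored} flag
#'   toggled.
#' @export
mirrorImage <- function(img) {
  new("ArrayImage", pixels = img@pixels[, ncol(img@pixels):1L, drop = FALSE],
      source = img@source, mirrored = !img@mirrored, bitDepth = img@bitDepth)
}

#' Accessors for ArrayImage
#'
#' \code{pixelData} returns the raw intensity matrix (indexed \code{[y, x]});
#' \code{imageSide} the dimensions.
#'
#' @param x an \code{ArrayImage}.
#' @return \code{pixelData}: numeric matrix; \code{imageSide}: integer
#'   vector \code{c(rows, cols)}.
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname pixelData
#' @export
setMethod("pixelData", "ArrayImage", function(x) x@pixels)

setMethod("show", "ArrayImage", function(object) {
  cat(sprintf("ArrayImage: %d x %d px, %d-bit source, range [%g, %g]\n",
              nrow(object@pixels), ncol(object@pixels), object@bitDepth,
              min(object@pixels), max(object@pixels)))
  cat(sprintf("  source: %s%s\n", object@source,
              if (object@mirrored) " (mirrored)" else ""))
})

#' Check an image for pixel saturation
#'
#' Scans are expected to stay within the linear dynamic range of the 16-bit
#' scanner; saturated pixels clip the signal and bias dot sums.  This is a
#' pre-check: a nonzero count is a warning condition (the CLI aborts only in
#' strict mode).
#'
#' @param img an \code{\linkS4class{ArrayImage}}.
#' @param limit saturation limit (default 65535); pixels \code{>= limit}
#'   count as saturated.
#' @return A list with \code{count}, \code{pass} (\code{count == 0}) and
#'   \code{coords}, a two-column matrix of (x, y) pixel coordinates of
#'   saturated pixels (capped at 1000 rows).
#' @export
checkSaturation <- function(img, limit = 65535) {
  if (limit > 65535) stop("limit must be <= 65535")
  px <- pixelData(img)
  w <- which(px >= limit, arr.ind = TRUE)
  list(count = nrow(w), pass = nrow(w) == 0L,
       coords = cbind(x = w[seq_len(min(nrow(w), 1000L)), 2L],
                      y = w[seq_len(min(nrow(w), 1000L)), 1L]))
}
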