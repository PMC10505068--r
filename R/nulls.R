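# Removal of null results: marker dots by known position, blank dots by the
# divergence of the pixel intensity field.  A dot carrying signal is a
# bright, centred blob; the gradient of the intensity field converges into
# it, i.e. the blob is a sink of the divergence field.  Blank dots have no
# such sink and are excluded from all subsequent statistics.

#' Sink score of one dot tile
#'
#' The divergence of the gradient of the (lightly smoothed) intensity field
#' is the Laplacian; a bright centred blob has a negative interior Laplacian
#' sum, so the score is defined as minus that sum: strongly positive for
#' signal blobs, near zero for flat (blank) tiles, negative and of equal
#' magnitude for an inverted (marker-like) dark blob.  The operator is
#' linear in the tile intensities.
#'
#' @param tile numeric dot tile (9 x 9 for the standard layout), normally
#'   from the background-subtracted mosaic.
#' @param smoothSd Gaussian pre-smoothing sd in px (default 1).
#' @return A single numeric score.
#' @export
sinkScore <- function(tile, smoothSd = 1) {
  m <- gaussSmooth(tile, smoothSd)
  n <- nrow(m); p <- ncol(m)
  i <- 2:(n - 1L); j <- 2:(p - 1L)
  lap <- m[i - 1L, j] + m[i + 1L, j] + m[i, j - 1L] + m[i, j + 1L] -
    4 * m[i, j]
  -sum(lap)
}

# vectorised sink scores for every dot of an ROI mosaic
allSinkScores <- function(mosaic, layout, smoothSd = 1) {
  d <- dotsPerSide(layout); p <- pxPerDot(layout)
  out <- matrix(0, d, d)
  for (r in seq_len(d)) {
    rows <- ((r - 1L) * p + 1L):(r * p)
    strip <- mosaic[rows, , drop = FALSE]
    for (c in seq_len(d))
      out[r, c] <- sinkScore(strip[, ((c - 1L) * p + 1L):(c * p)], smoothSd)
  }
  out
}

#' Classify null dots: markers and blanks
#'
#' Marker dots are classed by their known positions (the centre dot of every
#' cell).  Every remaining dot receives a sink score
#' (\code{\link{sinkScore}}) on its background-subtracted tile and is
#' classed \code{blank} when the score falls below a threshold \code{tau}:
#' either an absolute value, or (default) the automatic rule
#' \code{median - k * MAD} over all non-marker sink scores (raw MAD,
#' \code{k = 2}).  The automatic rule is invariant under affine intensity
#' changes of the image, since the sink score is linear in intensity.
#'
#' @param mosaic background-subtracted ROI mosaic
#'   (\code{\link{subtractAndSum}} returns it).
#' @param layout an \code{\linkS4class{ArrayLayout}}.
#' @param tau \code{"auto"} or a numeric absolute threshold.
#' @param k MAD multiplier for the automatic threshold (default 2).
#' @param smoothSd pre-smoothing sd passed to \code{\link{sinkScore}}.
#' @return list with \code{classes} (character dot matrix:
#'   \code{marker}/\code{blank}/\code{valid}), \code{sinkScores} (numeric
#'   dot matrix) and \code{tau} (the threshold used).
#' @export
classifyNulls <- function(mosaic, layout, tau = "auto", k = 2,
                          smoothSd = 1) {
  d <- dotsPerSide(layout); s <- cellSideDots(layout)
  ctr <- (s - 1L) %/% 2L
  sc <- allSinkScores(mosaic, layout, smoothSd)
  isMarker <- outer(seq_len(d) - 1L, seq_len(d) - 1L,
                    function(r, c) r %% s == ctr & c %% s == ctr)
  nonMarker <- sc[!isMarker]
  if (identical(tau, "auto")) {
    m <- stats::median(nonMarker); dev <- rawMad(nonMarker)
    if (dev == 0)
      stop(paste("automatic blank threshold is degenerate (zero MAD of",
                 "sink scores); supply an absolute tau"))
    tau <- m - k * dev
  } else {
    tau <- as.numeric(tau)
  }
  classes <- matrix("valid", d, d)
  classes[sc < tau & !isMarker] <- "blank"
  classes[isMarker] <- "marker"
  list(classes = classes, sinkScores = sc, tau = tau)
}

#' Blank/marker map as a plain matrix image
#'
#' Encodes the null-mask classes as an image-like numeric matrix (valid = 1,
#' blank = 0.5, marker = 0) at one pixel per dot, the array-wide blank map
#' used for visual QC of region-structured blank densities.
#'
#' @param classes character dot matrix from \code{\link{classifyNulls}}.
#' @return Numeric matrix.
#' @export
nullMaskImage <- function(classes) {
  m <- matrix(1, nrow(classes), ncol(classes))
  m[classes == "blank"] <- 0.5
  m[classes == "marker"] <- 0
  m
}
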