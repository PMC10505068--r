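#' @import methods
NULL

# ---------------------------------------------------------------------------
# ArrayLayout
# ---------------------------------------------------------------------------

#' ArrayLayout: geometric constants of one macroarray format
#'
#' An \code{ArrayLayout} holds the immutable geometry of a spotted macroarray:
#' the number of printed dots per side, the size of the marker-centred cell
#' (in dots), the pixel footprint of one dot, and the scanner characteristics.
#' The default geometry (see \code{\link{makeLayout}}) is the HexSelect-style
#' membrane: 240 x 240 dots grouped into 48 x 48 cells of 5 x 5 dots, each dot
#' imaged as a 9 x 9 pixel tile, scanned 16-bit at 10 px/mm into a
#' 2250 x 2250 image with a 2160 x 2160 region of interest.
#'
#' @slot dotsPerSide integer, printed dots per array side (default 240).
#' @slot cellSideDots integer, dots per cell side; odd, so the marker dot sits
#'   at the cell centre (default 5).
#' @slot pxPerDot integer, pixels per dot side in the scan (default 9).
#' @slot imageSidePx integer, nominal scan side length in pixels (default 2250).
#' @slot cellHalfwidthPx integer, half-width of a cell tile in pixels around
#'   the marker centre; \code{2*cellHalfwidthPx + 1 == cellSideDots*pxPerDot}
#'   (default 22).
#' @slot bitDepthMax integer, maximum representable intensity (default 65535).
#' @slot resolution numeric, scan resolution in px/mm (default 10).
#'
#' @seealso \code{\link{makeLayout}}, \code{\link{cellsPerSide}},
#'   \code{\link{roiSidePx}}, \code{\link{localityOffsets}}
#' @export
setClass("ArrayLayout",
  representation(
    dotsPerSide     = "integer",
    cellSideDots    = "integer",
    pxPerDot        = "integer",
    imageSidePx     = "integer",
    cellHalfwidthPx = "integer",
    bitDepthMax     = "integer",
    resolution      = "numeric"
  )
)

setValidity("ArrayLayout", function(object) {
  d <- object@dotsPerSide; c5 <- object@cellSideDots; p <- object@pxPerDot
  msgs <- character(0)
  if (d < 1L || c5 < 1L || p < 1L)
    msgs <- c(msgs, "dotsPerSide, cellSideDots and pxPerDot must be positive")
  if (c5 %% 2L != 1L)
    msgs <- c(msgs, "cellSideDots must be odd (marker dot is the cell centre)")
  if (d %% c5 != 0L)
    msgs <- c(msgs, "dotsPerSide must be divisible by cellSideDots")
  if (2L * object@cellHalfwidthPx + 1L != c5 * p)
    msgs <- c(msgs, sprintf(
      "2*cellHalfwidthPx + 1 (%d) must equal cellSideDots*pxPerDot (%d)",
      2L * object@cellHalfwidthPx + 1L, c5 * p))
  if (object@imageSidePx < d * p)
    msgs <- c(msgs, sprintf(
      "imageSidePx (%d) smaller than the region of interest (%d)",
      object@imageSidePx, d * p))
  if (object@bitDepthMax < 1L)
    msgs <- c(msgs, "bitDepthMax must be positive")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

# ---------------------------------------------------------------------------
# ArrayImage
# ---------------------------------------------------------------------------

#' ArrayImage: a single-channel macroarray scan
#'
#' Wraps the pixel matrix of one grayscale array scan together with its
#' provenance (source path, mirroring state, original bit depth).  Pixels are
#' stored in native intensity units, matrix-indexed as \code{[y, x]} (row =
#' vertical image coordinate), values in \code{0..65535}.
#'
#' @slot pixels numeric matrix of intensities, indexed \code{[y, x]}.
#' @slot source character, file path the image came from (or
#'   \code{"<synthetic>"}).
#' @slot mirrored logical, whether the image has been flipped left-right.
#' @slot bitDepth integer, bit depth of the source data (8 or 16).
#'
#' @seealso \code{\link{loadArrayImage}}, \code{\link{mirrorImage}},
#'   \code{\link{checkSaturation}}
#' @export
setClass("ArrayImage",
  representation(
    pixels   = "matrix",
    source   = "character",
    mirrored = "logical",
    bitDepth = "integer"
  )
)

setValidity("ArrayImage", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) return("pixels must be a numeric matrix")
  if (any(!is.finite(px))) return("pixels must be finite")
  if (min(px) < 0 || max(px) > 65535)
    return("pixel intensities must lie in [0, 65535]")
  TRUE
})

# ---------------------------------------------------------------------------
# MarkerGrid
# ---------------------------------------------------------------------------

#' MarkerGrid: refined marker-dot centres for every cell
#'
#' Pixel coordinates of the marker dot at the centre of each cell, after the
#' two-stage positioning (bilinear corner interpolation then per-marker
#' refinement).  Coordinate matrices are indexed \code{[cellRow, cellCol]}
#' (1-based) and hold 1-based integer pixel coordinates into the image.
#'
#' @slot cx integer matrix of marker x (column) pixel coordinates.
#' @slot cy integer matrix of marker y (row) pixel coordinates.
#' @slot status character matrix, \code{"refined"} or \code{"fallback"} (the
#'   interpolated position was kept because no plausible dark blob was found).
#' @slot layout the \code{\linkS4class{ArrayLayout}} the grid belongs to.
#'
#' @seealso \code{\link{buildMarkerGrid}}, \code{\link{extractCell}}
#' @export
setClass("MarkerGrid",
  representation(
    cx     = "matrix",
    cy     = "matrix",
    status = "matrix",
    layout = "ArrayLayout"
  )
)

setValidity("MarkerGrid", function(object) {
  n <- cellsPerSide(object@layout)
  if (!all(dim(object@cx) == c(n, n)) || !all(dim(object@cy) == c(n, n)))
    return("coordinate matrices must be cellsPerSide x cellsPerSide")
  if (!all(dim(object@status) == c(n, n)))
    return("status matrix must be cellsPerSide x cellsPerSide")
  TRUE
})

# ---------------------------------------------------------------------------
# GroundTruth
# ---------------------------------------------------------------------------

#' GroundTruth: everything the synthetic generator knows about an image
#'
#' Produced by \code{\link{simulateArray}} alongside the rendered image.  The
#' manifest is the dot-level truth table; the field matrices are the smooth
#' per-pixel background offset and gain surfaces; the marker coordinate
#' matrices hold the true (continuous, warped) marker centres.
#'
#' @slot layout the \code{\linkS4class{ArrayLayout}} used.
#' @slot manifest data.frame with one row per dot: \code{x}, \code{y} (1-based
#'   dot coordinates), \code{class} (\code{marker}/\code{blank}/\code{basal}/
#'   \code{signal}), \code{clone_id}, \code{replicate}, \code{amplitude}.
#' @slot markerX,markerY numeric matrices \code{[cellRow, cellCol]} of true
#'   marker centre pixel coordinates.
#' @slot offsetField,gainField numeric per-pixel background surfaces.
#' @slot params list, the fully resolved simulation specification.
#' @slot seed integer RNG seed used.
#'
#' @seealso \code{\link{simulateArray}}, \code{\link{writeManifest}}
#' @export
setClass("GroundTruth",
  representation(
    layout      = "ArrayLayout",
    manifest    = "data.frame",
    markerX     = "matrix",
    markerY     = "matrix",
    offsetField = "matrix",
    gainField   = "matrix",
    params      = "list",
    seed        = "integer"
  )
)

# ---------------------------------------------------------------------------
# MacroarrayRun
# ---------------------------------------------------------------------------

#' MacroarrayRun: the full result bundle of one pipeline run
#'
#' Holds every intermediate and final table of \code{\link{runPipeline}}.  All
#' dot-level matrices are \code{dotsPerSide x dotsPerSide}, indexed
#' \code{[dotRow, dotCol]} (1-based); the linearised \code{scoreTable} and the
#' clone-level \code{cloneCalls} use 1-based \code{x} (dot column) and
#' \code{y} (dot row) coordinates, matching bench annotation conventions.
#'
#' @slot layout the \code{\linkS4class{ArrayLayout}}.
#' @slot markers the refined \code{\linkS4class{MarkerGrid}}.
#' @slot nullClasses character matrix, per-dot class
#'   (\code{marker}/\code{blank}/\code{valid}).
#' @slot sinkScores numeric matrix of per-dot divergence (sink) scores.
#' @slot offsets numeric matrix of repaired per-dot background offsets.
#' @slot offsetFlags logical matrix, TRUE where the raw offset was an outlier
#'   replaced by its local median.
#' @slot sums numeric matrix of background-subtracted per-dot pixel sums.
#' @slot scores numeric matrix of MAD scores (number of local MADs from the
#'   local median); NA where not scored.
#' @slot scoreFlags character matrix: \code{ok}, \code{degenerate},
#'   \code{sparse}, \code{marker} or \code{blank}.
#' @slot scoreTable linearised data.frame (x, y, sum, score, flag) with one
#'   row per dot.
#' @slot cloneCalls data.frame of pair-validated clone calls.
#' @slot config list, the resolved run configuration.
#' @slot stageLog character vector of per-stage QC counts.
#'
#' @seealso \code{\link{runPipeline}}, \code{\link{scoreTable}},
#'   \code{\link{cloneCalls}}
#' @export
setClass("MacroarrayRun",
  representation(
    layout      = "ArrayLayout",
    markers     = "MarkerGrid",
    nullClasses = "matrix",
    sinkScores  = "matrix",
    offsets     = "matrix",
    offsetFlags = "matrix",
    sums        = "matrix",
    scores      = "matrix",
    scoreFlags  = "matrix",
    scoreTable  = "data.frame",
    cloneCalls  = "data.frame",
    config      = "list",
    stageLog    = "character"
  )
)
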