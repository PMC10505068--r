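# Array geometry: layout constructor, derived quantities, index conversions
# and the lattice-disc localities used by background repair and MAD scoring.

#' Construct an array layout
#'
#' Returns the default HexSelect-style macroarray geometry unless individual
#' constants are overridden: 240 dots per side grouped in 5 x 5 dot cells
#' (48 cells per side, one black marker dot at each cell centre), 9 x 9
#' pixels per dot (2160 px region of interest inside a nominal 2250 px scan),
#' 16-bit dynamic range, 10 px/mm.  Overrides must jointly satisfy the layout
#' invariants; smaller layouts are useful to exercise the identical code
#' paths on synthetic data.
#'
#' @param dotsPerSide dots per array side (default 240).
#' @param cellSideDots dots per cell side, odd (default 5).
#' @param pxPerDot pixels per dot side (default 9).
#' @param imageSidePx nominal scan side in px (default 2250 for the full
#'   layout; for overridden layouts it defaults to the region of interest
#'   plus the same 90 px margin).
#' @param cellHalfwidthPx cell tile half-width in px (default
#'   \code{(cellSideDots*pxPerDot - 1)/2}, i.e. 22).
#' @param bitDepthMax maximum intensity (default 65535).
#' @param resolution scan resolution in px/mm (default 10).
#' @return An \code{\linkS4class{ArrayLayout}}.
#' @examples
#' lay <- makeLayout()
#' nDots(lay)        # 57600
#' nCells(lay)       # 2304
#' roiSidePx(lay)    # 2160
#' small <- makeLayout(dotsPerSide = 30)
#' cellsPerSide(small)
#' @export
makeLayout <- function(dotsPerSide = 240L, cellSideDots = 5L, pxPerDot = 9L,
                       imageSidePx = NULL, cellHalfwidthPx = NULL,
                       bitDepthMax = 65535L, resolution = 10) {
  dotsPerSide <- as.integer(dotsPerSide)
  cellSideDots <- as.integer(cellSideDots)
  pxPerDot <- as.integer(pxPerDot)
  if (is.null(cellHalfwidthPx))
    cellHalfwidthPx <- (cellSideDots * pxPerDot - 1L) %/% 2L
  if (is.null(imageSidePx))
    imageSidePx <- dotsPerSide * pxPerDot + 90L
  new("ArrayLayout",
      dotsPerSide = dotsPerSide, cellSideDots = cellSideDots,
      pxPerDot = pxPerDot, imageSidePx = as.integer(imageSidePx),
      cellHalfwidthPx = as.integer(cellHalfwidthPx),
      bitDepthMax = as.integer(bitDepthMax), resolution = resolution)
}

#' Layout accessors
#'
#' Derived quantities of an \code{\linkS4class{ArrayLayout}}:
#' \code{cellsPerSide} = dots per side / cell side; \code{roiSidePx} = dots
#' per side x pixels per dot (the reconstructed region of interest);
#' \code{nDots} and \code{nCells} are the total dot and cell counts;
#' \code{dotsPerSide}, \code{pxPerDot}, \code{cellSideDots} return the raw
#' constants.
#'
#' @param x an \code{ArrayLayout}.
#' @return An integer scalar.
#' @name layout-accessors
#' @aliases cellsPerSide roiSidePx nDots nCells dotsPerSide pxPerDot
#'   cellSideDots
#' @examples
#' cellsPerSide(makeLayout())  # 48
NULL

#' @rdname layout-accessors
#' @export
setGeneric("cellsPerSide", function(x) standardGeneric("cellsPerSide"))
#' @rdname layout-accessors
#' @export
setMethod("cellsPerSide", "ArrayLayout",
          function(x) x@dotsPerSide %/% x@cellSideDots)

#' @rdname layout-accessors
#' @export
setGeneric("roiSidePx", function(x) standardGeneric("roiSidePx"))
#' @rdname layout-accessors
#' @export
setMethod("roiSidePx", "ArrayLayout", function(x) x@dotsPerSide * x@pxPerDot)

#' @rdname layout-accessors
#' @export
setGeneric("nDots", function(x) standardGeneric("nDots"))
#' @rdname layout-accessors
#' @export
setMethod("nDots", "ArrayLayout", function(x) x@dotsPerSide^2L)

#' @rdname layout-accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname layout-accessors
#' @export
setMethod("nCells", "ArrayLayout", function(x) cellsPerSide(x)^2L)

#' @rdname layout-accessors
#' @export
setGeneric("dotsPerSide", function(x) standardGeneric("dotsPerSide"))
#' @rdname layout-accessors
#' @export
setMethod("dotsPerSide", "ArrayLayout", function(x) x@dotsPerSide)

#' @rdname layout-accessors
#' @export
setGeneric("pxPerDot", function(x) standardGeneric("pxPerDot"))
#' @rdname layout-accessors
#' @export
setMethod("pxPerDot", "ArrayLayout", function(x) x@pxPerDot)

#' @rdname layout-accessors
#' @export
setGeneric("cellSideDots", function(x) standardGeneric("cellSideDots"))
#' @rdname layout-accessors
#' @export
setMethod("cellSideDots", "ArrayLayout", function(x) x@cellSideDots)

setMethod("show", "ArrayLayout", function(object) {
  cat(sprintf(
    "ArrayLayout: %d x %d dots (%d dots) in %d x %d cells of %d x %d\n",
    object@dotsPerSide, object@dotsPerSide, nDots(object),
    cellsPerSide(object), cellsPerSide(object),
    object@cellSideDots, object@cellSideDots))
  cat(sprintf("  dot tile %d x %d px, ROI %d x %d px in a %d px image\n",
              object@pxPerDot, object@pxPerDot, roiSidePx(object),
              roiSidePx(object), object@imageSidePx))
  cat(sprintf("  dynamic range 0..%d, %g px/mm\n",
              object@bitDepthMax, object@resolution))
})

#' Integer lattice offsets of a Euclidean disc ("locality")
#'
#' The locality of a dot is the set of dots within a fixed Euclidean radius
#' (in dot units) of it, a moving-window sample over which local medians and
#' MADs are computed.  This returns the canonical offset set: all integer
#' pairs \code{(dcol, drow)} with \code{dcol^2 + drow^2 <= radius^2},
#' boundary included, in row-major order (by \code{drow}, then \code{dcol}).
#' A radius of 3 gives 29 offsets; a radius of 4 gives 49.
#'
#' @param radius non-negative integer disc radius in dot units.
#' @return A data.frame with integer columns \code{dcol}, \code{drow} and
#'   attribute \code{radius}; the centre \code{(0,0)} is always a member.
#' @examples
#' nrow(localityOffsets(3))  # 29
#' nrow(localityOffsets(4))  # 49
#' @export
localityOffsets <- function(radius) {
  if (length(radius) != 1L || !is.finite(radius) || radius < 0 ||
      radius != round(radius))
    stop("radius must be a single non-negative integer")
  r <- as.integer(radius)
  g <- expand.grid(dcol = -r:r, drow = -r:r, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$dcol^2 + g$drow^2 <= r^2, , drop = FALSE]
  g <- g[order(g$drow, g$dcol), , drop = FALSE]
  rownames(g) <- NULL
  attr(g, "radius") <- r
  g
}

#' Locality members of a dot, clipped to the array
#'
#' Translates the disc offsets of \code{\link{localityOffsets}} to a centre
#' dot and silently clips members falling outside the array bounds, so
#' border localities are smaller than interior ones.
#'
#' @param col,row 0-based dot coordinates of the centre dot.
#' @param radius disc radius in dot units.
#' @param layout an \code{\linkS4class{ArrayLayout}}.
#' @return data.frame with 0-based integer columns \code{col}, \code{row}.
#' @examples
#' lay <- makeLayout()
#' nrow(localityMembers(100, 100, 4, lay))  # 49 (interior)
#' @export
localityMembers <- function(col, row, radius, layout) {
  d <- dotsPerSide(layout)
  if (col < 0 || col >= d || row < 0 || row >= d)
    stop("centre dot outside the layout")
  off <- localityOffsets(radius)
  m <- data.frame(col = off$dcol + as.integer(col),
                  row = off$drow + as.integer(row))
  m <- m[m$col >= 0 & m$col < d & m$row >= 0 & m$row < d, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Convert between dot indices and (cell, within-cell) indices
#'
#' Dots are indexed 0-based by \code{(col, row)}; each dot belongs to the
#' cell \code{(col \%/\% cellSideDots, row \%/\% cellSideDots)} at within-cell
#' offset \code{(col \%\% cellSideDots, row \%\% cellSideDots)}.  The marker
#' dot is the within-cell centre.  The mapping is a bijection; both functions
#' are vectorised.
#'
#' @param col,row 0-based dot coordinates.
#' @param cellCol,cellRow 0-based cell coordinates.
#' @param withinCol,withinRow 0-based within-cell dot offsets.
#' @param layout an \code{\linkS4class{ArrayLayout}}.
#' @return \code{dotToCell}: data.frame \code{cellCol}, \code{cellRow},
#'   \code{withinCol}, \code{withinRow}; \code{cellToDot}: data.frame
#'   \code{col}, \code{row}.
#' @examples
#' lay <- makeLayout()
#' dotToCell(12, 7, lay)
#' cellToDot(2, 1, 2, 2, lay)  # marker dot of cell (2, 1)
#' @export
dotToCell <- function(col, row, layout) {
  s <- cellSideDots(layout)
  data.frame(cellCol = col %/% s, cellRow = row %/% s,
             withinCol = col %% s, withinRow = row %% s)
}

#' @rdname dotToCell
#' @export
cellToDot <- function(cellCol, cellRow, withinCol, withinRow, layout) {
  s <- cellSideDots(layout)
  data.frame(col = cellCol * s + withinCol, row = cellRow * s + withinRow)
}

# Pixel coordinates (1-based, into the reconstructed ROI mosaic) of the 9x9
# tile of dot (col,row): columns tileCols(col), rows tileCols(row).
tilePx <- function(dotIndex, layout) {
  p <- pxPerDot(layout)
  (dotIndex * p + 1L):(dotIndex * p + p)
}
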