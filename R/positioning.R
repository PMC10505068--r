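# Two-stage dot positioning: bilinear four-corner interpolation gives an
# approximate marker grid; each marker is then refined by local intensity
# thresholding (markers are printed black, the darkest objects in their
# window).  The array is afterwards reconstructed cell by cell around the
# refined marker centres.

#' Validate an operator-supplied corner input
#'
#' The four marker-dot pixel coordinates at the array corners are the only
#' user input the positioning stage requires.  Accepts a 4 x 2 matrix (rows
#' top-left, top-right, bottom-left, bottom-right; columns x, y) or a list
#' of four \code{c(x, y)} vectors.
#'
#' @param corners corner coordinates (see above).
#' @return A validated 4 x 2 numeric matrix with rownames
#'   \code{tl, tr, bl, br}.
#' @export
asCorners <- function(corners) {
  if (is.list(corners)) corners <- do.call(rbind, corners)
  corners <- as.matrix(corners)
  if (!all(dim(corners) == c(4L, 2L)))
    stop("corners must be four (x, y) coordinates: tl, tr, bl, br")
  storage.mode(corners) <- "double"
  rownames(corners) <- c("tl", "tr", "bl", "br")
  colnames(corners) <- c("x", "y")
  # degenerate quadrilateral check via the two triangle areas
  area <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  a1 <- area(corners[1, ], corners[2, ], corners[3, ])
  a2 <- area(corners[2, ], corners[4, ], corners[3, ])
  if (a1 < 1 || a2 < 1)
    stop("degenerate corner quadrilateral (near-zero area)")
  corners
}

#' Bilinear interpolation of the marker grid from four corners
#'
#' First positioning stage: the corner quadrilateral is filled with evenly
#' interpolated marker positions at fractions \code{i/(cellsPerSide-1)}.
#' The four corners are reproduced exactly; for a parallelogram the result
#' is the affine image of the unit grid.
#'
#' @param corners corner input, see \code{\link{asCorners}}.
#' @param layout an \code{\linkS4class{ArrayLayout}}.
#' @return list of matrices \code{cx}, \code{cy} (\code{[cellRow, cellCol]})
#'   of approximate marker pixel coordinates.
#' @export
interpolateGrid <- function(corners, layout) {
  corners <- asCorners(corners)
  n <- cellsPerSide(layout)
  fr <- if (n > 1L) (seq_len(n) - 1) / (n - 1) else 0.5
  cx <- cy <- matrix(0, n, n)
  for (j in seq_len(n)) {    # cell column -> horizontal fraction
    u <- fr[j]
    for (i in seq_len(n)) {  # cell row -> vertical fraction
      v <- fr[i]
      w <- c((1 - u) * (1 - v), u * (1 - v), (1 - u) * v, u * v)
      cx[i, j] <- sum(w * corners[, "x"])
      cy[i, j] <- sum(w * corners[, "y"])
    }
  }
  list(cx = cx, cy = cy)
}

#' Refine one marker position by intensity thresholding
#'
#' Second positioning stage for a single marker: the window around the
#' approximate position is lightly smoothed (Gaussian, sd 1 px, which
#' suppresses single-pixel noise without moving a symmetric blob's
#' centroid), pixels below the midpoint of the smoothed window's dark tail
#' (1st percentile) and its median are selected -- the printed black marker
#' is the only small high-contrast dark object in the window -- and the
#' refined centre is the darkness-weighted centroid of the selected
#' pixels, rounded to the nearest integer pixel.  When no plausible dark
#' blob exists (uniform window, a "blob" covering less than 4 pixels or
#' more than a quarter of the window, or a selection scattered wider than a
#' marker can be) the approximate position is returned with
#' \code{status = "fallback"}.
#'
#' @param img an \code{\linkS4class{ArrayImage}} or pixel matrix.
#' @param approx numeric \code{c(x, y)} approximate centre.
#' @param window half-width of the search window in px (default: the
#'   layout's cell half-width, 22 for the standard layout).
#' @return list \code{x}, \code{y} (integer), \code{status}
#'   (\code{"refined"} or \code{"fallback"}).
#' @export
refineMarker <- function(img, approx, window = 22L) {
  px <- if (is(img, "ArrayImage")) pixelData(img) else img
  x0 <- round(approx[1L]); y0 <- round(approx[2L])
  xs <- (x0 - window):(x0 + window)
  ys <- (y0 - window):(y0 + window)
  if (min(xs) < 1L || min(ys) < 1L || max(xs) > ncol(px) || max(ys) > nrow(px))
    stop("marker search window falls outside the image")
  W <- gaussSmooth(px[ys, xs], 1)
  thr <- darkThreshold(as.vector(W))
  sel <- which(W < thr, arr.ind = TRUE)
  # the marker is the compact blob around the darkest pixel; drop stray
  # dark pixels elsewhere in the window (e.g. under a bright neighbour's
  # bloom the threshold turns permissive and selects plain background too)
  anchor <- which(W == min(W), arr.ind = TRUE)[1L, ]
  keep <- abs(sel[, 1L] - anchor[1L]) <= 9L & abs(sel[, 2L] - anchor[2L]) <= 9L
  sel <- sel[keep, , drop = FALSE]
  if (nrow(sel) < 4L)
    return(list(x = x0, y = y0, status = "fallback"))
  # squared darkness weights concentrate the centroid on the marker core,
  # halving the jitter from threshold-edge pixels
  wts <- (thr - W[sel])^2
  cx <- sum(wts * xs[sel[, 2L]]) / sum(wts)
  cy <- sum(wts * ys[sel[, 1L]]) / sum(wts)
  # a plausible marker blob is compact: scattered dark noise has a large
  # weighted spread around its centroid
  msd <- sum(wts * ((xs[sel[, 2L]] - cx)^2 + (ys[sel[, 1L]] - cy)^2)) /
    sum(wts)
  if (msd > 20)
    return(list(x = x0, y = y0, status = "fallback"))
  list(x = as.integer(round(cx)), y = as.integer(round(cy)),
       status = "refined")
}

#' Build the full refined marker grid
#'
#' Runs both positioning stages for every cell: bilinear interpolation from
#' the corner input, then per-marker refinement.  The refined grid must be
#' strictly increasing along rows and columns (a transposed or mis-ordered
#' corner input violates this and raises an error), and no more than
#' \code{maxFallbackFrac} of the markers may fall back to their interpolated
#' position.
#'
#' @param img an \code{\linkS4class{ArrayImage}}.
#' @param corners corner input, see \code{\link{asCorners}}.
#' @param layout an \code{\linkS4class{ArrayLayout}}.
#' @param window refinement window half-width, px.
#' @param maxFallbackFrac maximum tolerated fraction of fallback markers
#'   (default 0.05).
#' @return A \code{\linkS4class{MarkerGrid}}.
#' @export
buildMarkerGrid <- function(img, corners, layout,
                            window = layout@cellHalfwidthPx,
                            maxFallbackFrac = 0.05) {
  approx <- interpolateGrid(corners, layout)
  n <- cellsPerSide(layout)
  cx <- cy <- matrix(0L, n, n)
  status <- matrix("refined", n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- refineMarker(img, c(approx$cx[i, j], approx$cy[i, j]), window)
    cx[i, j] <- r$x; cy[i, j] <- r$y; status[i, j] <- r$status
  }
  nf <- sum(status == "fallback")
  if (nf > maxFallbackFrac * n * n)
    stop(sprintf(
      "positioning failure: %d of %d markers (%.1f%%) lack a dark blob",
      nf, n * n, 100 * nf / (n * n)))
  if (n > 1L) {
    if (any(apply(cx, 1L, diff) <= 0) || any(apply(t(cy), 1L, diff) <= 0))
      stop(paste("marker grid is not monotonic; check the corner order",
                 "(tl, tr, bl, br of the displayed image)"))
  }
  new("MarkerGrid", cx = cx, cy = cy, status = status, layout = layout)
}

#' MarkerGrid accessors
#'
#' \code{markerCoords} returns a data.frame of refined marker pixel
#' coordinates with cell indices; \code{fallbackCount} the number of markers
#' kept at their interpolated position.
#'
#' @param x a \code{MarkerGrid}.
#' @export
setGeneric("markerCoords", function(x) standardGeneric("markerCoords"))

#' @rdname markerCoords
#' @export
setMethod("markerCoords", "MarkerGrid", function(x) {
  n <- cellsPerSide(x@layout)
  g <- expand.grid(cellRow = seq_len(n), cellCol = seq_len(n))
  data.frame(cellCol = g$cellCol, cellRow = g$cellRow,
             x = x@cx[cbind(g$cellRow, g$cellCol)],
             y = x@cy[cbind(g$cellRow, g$cellCol)],
             status = x@status[cbind(g$cellRow, g$cellCol)],
             stringsAsFactors = FALSE)
})

#' @rdname markerCoords
#' @export
setGeneric("fallbackCount", function(x) standardGeneric("fallbackCount"))

#' @rdname markerCoords
#' @export
setMethod("fallbackCount", "MarkerGrid",
          function(x) sum(x@status == "fallback"))

setMethod("show", "MarkerGrid", function(object) {
  n <- cellsPerSide(object@layout)
  cat(sprintf("MarkerGrid: %d x %d refined marker centres (%d fallback)\n",
              n, n, fallbackCount(object)))
})

#' Extract one reconstructed cell tile
#'
#' Redefines a cell using its refined marker centre as datum: the tile is
#' the square of +/- \code{cellHalfwidthPx} pixels around the marker (45 x 45
#' for the standard layout).  Within the tile, the 5 x 5 dots occupy fixed
#' 9 x 9 blocks with the marker as the central block.
#'
#' @param img an \code{\linkS4class{ArrayImage}} or pixel matrix.
#' @param markers a \code{\linkS4class{MarkerGrid}}.
#' @param cellCol,cellRow 1-based cell indices.
#' @return Numeric tile matrix.
#' @export
extractCell <- function(img, markers, cellCol, cellRow) {
  px <- if (is(img, "ArrayImage")) pixelData(img) else img
  hw <- markers@layout@cellHalfwidthPx
  cx <- markers@cx[cellRow, cellCol]; cy <- markers@cy[cellRow, cellCol]
  if (cx - hw < 1L || cy - hw < 1L || cx + hw > ncol(px) || cy + hw > nrow(px))
    stop(sprintf("cell (%d, %d) tile exceeds the image bounds",
                 cellCol, cellRow))
  px[(cy - hw):(cy + hw), (cx - hw):(cx + hw)]
}

#' Reconstruct the region of interest as a cell mosaic
#'
#' Concatenates every reconstructed cell tile into one
#' \code{roiSidePx x roiSidePx} mosaic in which dot \code{(col, row)}
#' occupies the fixed 9 x 9 pixel block starting at
#' \code{(9*col + 1, 9*row + 1)} -- the fixed-grid image all downstream
#' quantification operates on.
#'
#' @param img an \code{\linkS4class{ArrayImage}}.
#' @param markers a \code{\linkS4class{MarkerGrid}}.
#' @return Numeric \code{roiSidePx x roiSidePx} matrix.
#' @export
reconstructArray <- function(img, markers) {
  lay <- markers@layout
  n <- cellsPerSide(lay)
  tile <- 2L * lay@cellHalfwidthPx + 1L
  mosaic <- matrix(0, roiSidePx(lay), roiSidePx(lay))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mosaic[((i - 1L) * tile + 1L):(i * tile),
           ((j - 1L) * tile + 1L):(j * tile)] <-
      extractCell(img, markers, j, i)
  }
  mosaic
}

#' QC sample of evenly spaced cells
#'
#' Samples \code{k x k} cells evenly spaced across the array (deterministic
#' indices \code{round(seq(1, cellsPerSide, length.out = k))}), extracts
#' their tiles, and checks that the central 9 x 9 block -- the marker dot --
#' has the lowest mean of the cell's dot blocks, the signature of a
#' correctly centred reconstruction.
#'
#' @param img an \code{\linkS4class{ArrayImage}}.
#' @param markers a \code{\linkS4class{MarkerGrid}}.
#' @param k cells per montage side (default 6).
#' @return list with \code{indices} (the sampled cell indices),
#'   \code{tiles} (list of tile matrices), \code{markerDarkest} (logical
#'   k x k matrix) and \code{montage} (one assembled matrix for plotting).
#' @export
qcSample <- function(img, markers, k = 6L) {
  lay <- markers@layout
  n <- cellsPerSide(lay)
  if (k > n) stop("k exceeds the number of cells per side")
  idx <- if (k == 1L) round((n + 1L) / 2) else
    unique(round(seq(1L, n, length.out = k)))
  k <- length(idx)
  tile <- 2L * lay@cellHalfwidthPx + 1L
  s <- cellSideDots(lay); p <- pxPerDot(lay)
  ctr <- (s - 1L) %/% 2L
  tiles <- vector("list", k * k)
  dark <- matrix(NA, k, k)
  montage <- matrix(0, k * tile, k * tile)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    tl <- extractCell(img, markers, idx[b], idx[a])
    tiles[[(a - 1L) * k + b]] <- tl
    blockMean <- matrix(0, s, s)
    for (wi in 0:(s - 1L)) for (wj in 0:(s - 1L))
      blockMean[wj + 1L, wi + 1L] <-
        mean(tl[(wj * p + 1L):(wj * p + p), (wi * p + 1L):(wi * p + p)])
    dark[a, b] <- which.min(blockMean) ==
      (ctr * s + ctr + 1L)  # central block index, column-major
    montage[((a - 1L) * tile + 1L):(a * tile),
            ((b - 1L) * tile + 1L):(b * tile)] <- tl
  }
  list(indices = idx, tiles = tiles, markerDarkest = dark, montage = montage)
}
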