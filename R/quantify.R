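# Per-dot background offset estimation, robust outlier repair, background
# subtraction and pixel summation.
#
# Background offsets are assumed homogeneous only at the dot level: each
# dot's offset is the intensity of its pixel(s) expressing no luminance,
# i.e. the tile minimum.  Dots whose signal fills the whole tile have an
# abnormally high minimum; those offsets are detected as robust outliers
# against their locality and replaced by the local median offset.

#' Per-dot background offsets (tile minima)
#'
#' @param mosaic reconstructed ROI mosaic (\code{\link{reconstructArray}}).
#' @param layout an \code{\linkS4class{ArrayLayout}}.
#' @return Numeric dot matrix \code{[dotRow, dotCol]} of tile minima.
#' @export
dotOffsets <- function(mosaic, layout) {
  blockReduce(mosaic, layout, "min")
}

#' Robust repair of outlier background offsets
#'
#' A dot's offset is an outlier when it deviates from the median offset of
#' its locality (radius 4 dots by default; markers and blanks are included
#' here, since offsets describe background, not signal) by more than
#' \code{k} local MADs, where the MAD carries the usual 1.4826 normal-
#' consistency factor -- this is a detection rule calibrated against the
#' noise (k = 3 keeps the false-flag rate of symmetric noise below 1
#' percent), not a reported unit.  Outliers are replaced by that local
#' median.  Detection and replacement both use the raw offsets (two-pass),
#' so replacements cannot cascade.  A locality with zero MAD and a nonzero
#' deviation flags the dot (documented convention: any deviation from an
#' otherwise constant neighbourhood is abnormal).
#'
#' @param raw numeric dot matrix of raw offsets (\code{\link{dotOffsets}}).
#' @param layout an \code{\linkS4class{ArrayLayout}}.
#' @param radius locality radius in dot units (default 4).
#' @param k MAD multiplier (default 3).
#' @return list with \code{offset} (repaired matrix), \code{flagged}
#'   (logical matrix), \code{raw}.
#' @export
repairOffsets <- function(raw, layout, radius = 4, k = 3) {
  st <- localityStats(raw, radius, layout)
  dev <- abs(raw - st$median)
  mad <- 1.4826 * st$mad
  flagged <- (mad > 0 & dev > k * mad) | (mad == 0 & dev > 0)
  repaired <- raw
  repaired[flagged] <- st$median[flagged]
  list(offset = repaired, flagged = flagged, raw = raw)
}

#' Background subtraction and per-dot pixel summation
#'
#' Subtracts each dot's (repaired) offset from every pixel of its tile,
#' clamping at zero (intensities are non-negative), and sums the entire
#' tile -- all 81 pixels for the standard layout, no shape mask -- into the
#' dot intensity table.
#'
#' @param mosaic reconstructed ROI mosaic.
#' @param offsets repaired offset dot matrix (or the list from
#'   \code{\link{repairOffsets}}).
#' @param layout an \code{\linkS4class{ArrayLayout}}.
#' @return list with \code{sums} (numeric dot matrix of background-
#'   subtracted pixel sums) and \code{subtracted} (the subtracted mosaic,
#'   used by blank classification).
#' @export
subtractAndSum <- function(mosaic, offsets, layout) {
  if (is.list(offsets)) offsets <- offsets$offset
  d <- dotsPerSide(layout)
  stopifnot(nrow(offsets) == d, ncol(offsets) == d)
  sub <- pmax(mosaic - blockExpand(offsets, layout), 0)
  list(sums = blockReduce(sub, layout, "sum"), subtracted = sub)
}
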