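# Synthetic macroarray image generator with full ground truth.
#
# Emulates the features of a real membrane scan that the pipeline has to
# cope with: a smooth heterogeneous background offset and a smooth
# multiplicative gain surface, a mild non-linear geometric warp of the print
# grid, dark high-contrast marker dots at cell centres, duplicate-pair clone
# dots at a basal expression level with bounded clone-to-clone variability,
# bright signal pairs (a few of them strong enough to fill their whole dot),
# blank (signal-free) dot pairs in region-structured densities, and
# Gaussian + shot noise.  Deterministic for a fixed seed.

# --- smooth scalar fields --------------------------------------------------
# A smooth pseudo-random surface over [-1,1]^2: low-order polynomial plus one
# separable sinusoid, normalised to max |value| = 1.  Returned as a closure
# so it can be evaluated on the pixel grid or at arbitrary dot centres.
smoothFieldFun <- function() {
  co <- stats::runif(6L, -1, 1)
  f <- stats::runif(2L, 0.5, 1.25)
  ph <- stats::runif(2L, 0, pi)
  raw <- function(u, v)
    co[1L] * u + co[2L] * v + co[3L] * u * v + co[4L] * u^2 + co[5L] * v^2 +
      co[6L] * sin(pi * f[1L] * u + ph[1L]) * sin(pi * f[2L] * v + ph[2L])
  g <- seq(-1, 1, length.out = 41L)
  sc <- max(abs(outer(g, g, raw)), .Machine$double.eps)
  function(u, v) raw(u, v) / sc
}

#' Simulation specification
#'
#' Builds the fully resolved parameter list consumed by
#' \code{\link{simulateArray}}.  Defaults describe the study conditions the
#' generator emulates on the full 240-dot layout: geometric warp up to 3 px,
#' Gaussian read noise of sd 50 (16-bit scale) plus mild shot noise, a
#' heterogeneous background offset of 400 +/- 150, a smooth gain surface of
#' 1 +/- 0.3, basal clone expression of amplitude 6000 varying
#' clone-to-clone within +/- 25\% (both replicate dots of a clone share the
#' same expression level; levels are stratified across each cell's pair
#' slots so that local background statistics are stationary, the synthetic
#' counterpart of the consistent bacterial expression background of real
#' membranes), 48 bright signal pairs plus 2 very strong dot-filling pairs,
#' and blank-pair rates of 0.05 / 0.15 in the left/right halves of the
#' array (at most two blank pairs per cell).
#'
#' @param layout an \code{\linkS4class{ArrayLayout}} (default full layout).
#' @param warpMaxPx maximum displacement of the smooth geometric warp, px.
#' @param noiseSd Gaussian read-noise sd in intensity units.
#' @param shotNoise logical, add signal-dependent shot noise.
#' @param shotFactor shot-noise variance per intensity unit.
#' @param offsetBase,offsetAmp background offset surface: base +/- amplitude.
#' @param gainAmp gain surface is 1 +/- \code{gainAmp}.
#' @param basalAmp peak amplitude of basal clone dots.
#' @param basalRel relative clone-to-clone basal variability (uniform,
#'   +/- \code{basalRel}).
#' @param psfSigma dot point-spread sd in px (truncated at
#'   \code{psfRadius}).
#' @param psfRadius truncation radius of the dot point spread, px; 4 keeps a
#'   dot's emission inside its own 9 x 9 tile.
#' @param markerAbsorption fractional absorption of the printed black marker
#'   (multiplicative dip, 0..1).
#' @param markerSigma marker dip sd in px.
#' @param nSignalPairs number of ordinary bright clone pairs.
#' @param signalAmpRange peak-amplitude range of ordinary signal pairs.
#' @param nStrongPairs number of very strong pairs whose signal fills the
#'   entire dot (detector blooming).
#' @param strongAmp peak amplitude of strong pairs (clipped at 65535 after
#'   gain).
#' @param bloomSigma,bloomRadius point spread of strong dots, px.
#' @param blankRates per-region probability that each of the two possible
#'   blank pairs of a cell is blank; one rate per vertical half of the array.
#' @return A named list with class attribute \code{"macrogridSimSpec"}.
#' @seealso \code{\link{simulateArray}}, \code{\link{demoSpec}}
#' @export
simSpec <- function(layout = makeLayout(), warpMaxPx = 3, noiseSd = 50,
                    shotNoise = TRUE, shotFactor = 0.5,
                    offsetBase = 400, offsetAmp = 150, gainAmp = 0.3,
                    basalAmp = 6000, basalRel = 0.25,
                    psfSigma = 1.6, psfRadius = 4,
                    markerAbsorption = 0.85, markerSigma = 2.0,
                    nSignalPairs = 48, signalAmpRange = c(8000, 20000),
                    nStrongPairs = 2, strongAmp = 120000,
                    bloomSigma = 3.5, bloomRadius = 8,
                    blankRates = c(0.05, 0.15)) {
  stopifnot(is(layout, "ArrayLayout"), warpMaxPx >= 0, noiseSd >= 0,
            markerAbsorption >= 0, markerAbsorption <= 1,
            basalRel >= 0, basalRel < 1, all(blankRates >= 0),
            all(blankRates <= 1))
  spec <- as.list(environment())
  class(spec) <- "macrogridSimSpec"
  spec
}

#' Default end-to-end demo specification
#'
#' The shipped demonstration: identical physics to \code{\link{simSpec}} on a
#' 24-cell-per-side layout (120 x 120 dots, 1080 px region of interest), a
#' size chosen so the complete pipeline runs in well under a minute while
#' every code path (warp, heterogeneous background, blank regions, strong
#' saturating dots, pair validation) is exercised.
#'
#' @param ... overrides passed to \code{\link{simSpec}}.
#' @return A simulation spec.
#' @export
demoSpec <- function(...) {
  simSpec(layout = makeLayout(dotsPerSide = 120L), ...)
}

#' Default duplicate-pair map
#'
#' The 24 non-marker positions of each 5 x 5 cell are paired point-
#' symmetrically about the central marker dot, giving 12 clone pairs per
#' cell.  This shipped configuration is a documented synthetic stand-in for
#' the manufacturer's clone-library pairing, which is external configuration;
#' any pair map with the same columns can be supplied instead.
#'
#' @param layout an \code{\linkS4class{ArrayLayout}}.
#' @return data.frame with columns \code{x}, \code{y} (1-based dot
#'   coordinates), \code{clone_id}, \code{replicate} (1 or 2).
#' @export
makePairMap <- function(layout = makeLayout()) {
  s <- cellSideDots(layout)
  cps <- cellsPerSide(layout)
  ctr <- (s - 1L) %/% 2L
  w <- expand.grid(wi = 0:(s - 1L), wj = 0:(s - 1L))
  w <- w[!(w$wi == ctr & w$wj == ctr), ]
  # keep one representative per point-symmetric pair
  first <- w[(w$wj < s - 1L - w$wj) |
               (w$wj == s - 1L - w$wj & w$wi < s - 1L - w$wi), ]
  first <- first[order(first$wj, first$wi), ]
  cells <- expand.grid(ci = 0:(cps - 1L), cj = 0:(cps - 1L))
  out <- vector("list", nrow(cells))
  for (n in seq_len(nrow(cells))) {
    ci <- cells$ci[n]; cj <- cells$cj[n]
    cellId <- cj * cps + ci + 1L
    p1 <- data.frame(col = ci * s + first$wi, row = cj * s + first$wj)
    p2 <- data.frame(col = ci * s + (s - 1L - first$wi),
                     row = cj * s + (s - 1L - first$wj))
    id <- sprintf("c%05d_p%02d", cellId, seq_len(nrow(first)))
    out[[n]] <- data.frame(
      x = c(p1$col, p2$col) + 1L, y = c(p1$row, p2$row) + 1L,
      clone_id = c(id, id), replicate = rep(1:2, each = nrow(first)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# add a (possibly gain-scaled) truncated-Gaussian spot to img in place-ish
renderSpot <- function(img, gainField, cx, cy, amp, sigma, rmax) {
  n <- nrow(img)
  xs <- max(1L, round(cx) - rmax):min(n, round(cx) + rmax)
  ys <- max(1L, round(cy) - rmax):min(n, round(cy) + rmax)
  dx2 <- (xs - cx)^2; dy2 <- (ys - cy)^2
  G <- outer(exp(-dy2 / (2 * sigma^2)), exp(-dx2 / (2 * sigma^2)))
  G[outer(dy2, dx2, `+`) > rmax^2] <- 0
  if (is.null(gainField))
    img[ys, xs] <- img[ys, xs] + amp * G
  else
    img[ys, xs] <- img[ys, xs] + amp * G * gainField[ys, xs]
  img
}

# Vectorised renderer for many small spots at once (windows may overlap:
# contributions are accumulated with rowsum over linear pixel indices).
# Assumes every window lies inside the image, which the layout margin
# guarantees for the truncation radii used.
renderSpotsVec <- function(img, gainField, cx, cy, amp, sigma, rmax) {
  if (!length(cx)) return(img)
  n <- nrow(img)
  offs <- -rmax:rmax
  w <- length(offs)
  xr <- round(cx); yr <- round(cy)
  dxm <- outer(xr, offs, `+`) - cx   # ndots x w, continuous x distances
  dym <- outer(yr, offs, `+`) - cy
  ex <- exp(-dxm^2 / (2 * sigma^2))
  ey <- exp(-dym^2 / (2 * sigma^2))
  idx <- val <- vector("list", w * w)
  r2 <- rmax^2
  for (j in seq_len(w)) {
    colIdx <- (xr + offs[j] - 1) * n
    for (i in seq_len(w)) {
      k <- (j - 1L) * w + i
      id <- colIdx + yr + offs[i]
      v <- amp * ey[, i] * ex[, j]
      v[dym[, i]^2 + dxm[, j]^2 > r2] <- 0
      idx[[k]] <- id
      val[[k]] <- v
    }
  }
  idx <- unlist(idx, use.names = FALSE)
  val <- unlist(val, use.names = FALSE)
  if (!is.null(gainField)) val <- val * gainField[idx]
  acc <- rowsum(val, idx)
  tgt <- as.numeric(rownames(acc))
  img[tgt] <- img[tgt] + acc[, 1L]
  img
}

#' Simulate a macroarray scan with known ground truth
#'
#' Renders one synthetic array image according to a specification from
#' \code{\link{simSpec}}: marker dips and clone spots are placed at the
#' smoothly warped grid positions, emissions are multiplied by the gain
#' surface and added to the offset surface, the printed black markers absorb
#' multiplicatively, and Gaussian + shot noise is added.  Pixel values are
#' clipped to [0, 65535] (with a warning when clipping occurs, as it does
#' for the deliberately dot-filling strong pairs).  Bit-identical for a
#' fixed seed.
#'
#' @param spec a \code{\link{simSpec}} list.
#' @param seed integer RNG seed (required: the truth must be reproducible).
#' @return A list with elements \code{image} (an
#'   \code{\linkS4class{ArrayImage}}) and \code{truth} (a
#'   \code{\linkS4class{GroundTruth}}).
#' @examples
#' sim <- suppressWarnings(simulateArray(demoSpec(), seed = 1))
#' sim$image
#' head(truthManifest(sim$truth))
#' @export
simulateArray <- function(spec = simSpec(), seed) {
  stopifnot(inherits(spec, "macrogridSimSpec"))
  if (missing(seed)) stop("a seed is required for a reproducible truth")
  set.seed(as.integer(seed))
  lay <- spec$layout
  d <- dotsPerSide(lay); s <- cellSideDots(lay); p <- pxPerDot(lay)
  cps <- cellsPerSide(lay)
  side <- lay@imageSidePx
  margin <- (side - roiSidePx(lay)) %/% 2L
  ctr <- (s - 1L) %/% 2L

  # smooth surfaces and warp (coefficient draws fixed in this order)
  fOffset <- smoothFieldFun()
  fGain <- smoothFieldFun()
  fWarpX <- smoothFieldFun()
  fWarpY <- smoothFieldFun()
  u <- (seq_len(side) - (side + 1) / 2) / (side / 2)
  offsetField <- spec$offsetBase + spec$offsetAmp * outer(u, u, function(v, w) fOffset(w, v))
  gainField <- 1 + spec$gainAmp * outer(u, u, function(v, w) fGain(w, v))

  # dot base centres (image px, 1-based) and warped true centres
  dotIdx <- expand.grid(col = 0:(d - 1L), row = 0:(d - 1L))
  baseX <- margin + dotIdx$col * p + (p + 1) / 2
  baseY <- margin + dotIdx$row * p + (p + 1) / 2
  uX <- (baseX - (side + 1) / 2) / (side / 2)
  uY <- (baseY - (side + 1) / 2) / (side / 2)
  wx <- fWarpX(uX, uY); wy <- fWarpY(uX, uY)
  if (spec$warpMaxPx > 0) {
    mag <- max(sqrt(wx^2 + wy^2))
    wx <- wx / mag * spec$warpMaxPx
    wy <- wy / mag * spec$warpMaxPx
  } else {
    wx <- wy <- rep(0, length(baseX))
  }
  trueX <- baseX + wx
  trueY <- baseY + wy

  # dot classes: markers by position; blanks and signals by clone pair
  pm <- makePairMap(lay)
  within <- dotToCell(dotIdx$col, dotIdx$row, lay)
  isMarker <- within$withinCol == ctr & within$withinRow == ctr

  cloneIds <- sort(unique(pm$clone_id))
  nPairsPerCell <- nrow(pm) / 2L / nCells(lay)
  # blank pairs: per cell, each of (at most) two candidate pairs is blank
  # with the rate of its vertical region
  cloneCell <- as.integer(sub("^c(\\d+)_p.*$", "\\1", cloneIds))
  cloneCi <- (cloneCell - 1L) %% cps
  rate <- spec$blankRates[1L + (cloneCi >= cps / 2)]
  clonePairNo <- as.integer(sub("^c\\d+_p(\\d+)$", "\\1", cloneIds))
  # candidate blank pairs are two fixed pair slots per cell; each goes blank
  # independently at the regional rate (never more than two per cell)
  blankCand <- clonePairNo %in% c(1L, nPairsPerCell)
  isBlankClone <- blankCand & stats::runif(length(cloneIds)) < rate

  nonBlank <- cloneIds[!isBlankClone]
  nSig <- min(spec$nSignalPairs, length(nonBlank))
  nStr <- min(spec$nStrongPairs, length(nonBlank) - nSig)
  sigClones <- sample(nonBlank, nSig + nStr)
  strongClones <- if (nStr > 0) sigClones[seq_len(nStr)] else character(0)
  regClones <- setdiff(sigClones, strongClones)

  # Basal expression levels are stratified across the pair slots of each
  # cell: the band [1-basalRel, 1+basalRel] is split into nPairsPerCell
  # equal strata, each cell draws one level per stratum (randomly assigned
  # to its pair slots, uniform within the stratum).  Every locality then
  # sees the same bounded level distribution, so local medians and MADs are
  # stationary across the array -- the synthetic counterpart of the
  # consistent bacterial expression background of the real membranes.
  npc <- as.integer(nPairsPerCell)
  strat <- unlist(lapply(seq_len(nCells(lay)), function(i) sample(npc)))
  su <- (strat - stats::runif(length(cloneIds))) / npc
  cloneAmp <- spec$basalAmp * (1 - spec$basalRel + 2 * spec$basalRel * su)
  names(cloneAmp) <- cloneIds
  cloneAmp[isBlankClone] <- 0
  extraAmp <- stats::setNames(rep(0, length(cloneIds)), cloneIds)
  extraAmp[regClones] <- stats::runif(length(regClones),
                                      spec$signalAmpRange[1L],
                                      spec$signalAmpRange[2L])
  extraAmp[strongClones] <- spec$strongAmp
  cloneClass <- ifelse(isBlankClone, "blank",
                       ifelse(cloneIds %in% sigClones, "signal", "basal"))
  names(cloneClass) <- cloneIds

  key <- paste(dotIdx$col + 1L, dotIdx$row + 1L)
  pmKey <- paste(pm$x, pm$y)
  mi <- match(key, pmKey)
  dotClone <- ifelse(is.na(mi), NA_character_, pm$clone_id[mi])
  dotRep <- ifelse(is.na(mi), NA_integer_, pm$replicate[mi])
  dotClass <- ifelse(isMarker, "marker", cloneClass[dotClone])
  dotAmp <- ifelse(isMarker, NA_real_,
                   cloneAmp[dotClone] + extraAmp[dotClone])
  dotStrong <- !isMarker & !is.na(dotClone) & dotClone %in% strongClones

  # ---- render ----
  img <- offsetField
  reg <- which(!isMarker & dotAmp > 0 & !dotStrong)
  img <- renderSpotsVec(img, gainField, trueX[reg], trueY[reg], dotAmp[reg],
                        spec$psfSigma, spec$psfRadius)
  for (i in which(dotStrong))
    img <- renderSpot(img, gainField, trueX[i], trueY[i], dotAmp[i],
                      spec$bloomSigma, spec$bloomRadius)
  # printed black markers absorb multiplicatively; marker windows are
  # mutually disjoint, so one indexed update suffices
  mk <- which(isMarker)
  {
    rmax <- spec$psfRadius
    offs <- -rmax:rmax
    xr <- round(trueX[mk]); yr <- round(trueY[mk])
    dxm <- outer(xr, offs, `+`) - trueX[mk]
    dym <- outer(yr, offs, `+`) - trueY[mk]
    ex <- exp(-dxm^2 / (2 * spec$markerSigma^2))
    ey <- exp(-dym^2 / (2 * spec$markerSigma^2))
    n <- nrow(img)
    for (j in seq_along(offs)) {
      colIdx <- (xr + offs[j] - 1) * n
      for (i in seq_along(offs)) {
        id <- colIdx + yr + offs[i]
        G <- ey[, i] * ex[, j]
        G[dym[, i]^2 + dxm[, j]^2 > rmax^2] <- 0
        img[id] <- img[id] * (1 - spec$markerAbsorption * G)
      }
    }
  }
  if (spec$noiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noiseSd)
  if (isTRUE(spec$shotNoise) && spec$shotFactor > 0)
    img <- img + stats::rnorm(length(img),
                              0, sqrt(pmax(img, 0) * spec$shotFactor))
  nClip <- sum(img > 65535)
  if (nClip > 0)
    warning(sprintf("%d pixels exceeded the 16-bit range and were clipped",
                    nClip))
  img <- pmin(pmax(img, 0), 65535)

  markerSel <- which(isMarker)
  mcell <- dotToCell(dotIdx$col[markerSel], dotIdx$row[markerSel], lay)
  markerX <- markerY <- matrix(NA_real_, cps, cps)
  markerX[cbind(mcell$cellRow + 1L, mcell$cellCol + 1L)] <- trueX[markerSel]
  markerY[cbind(mcell$cellRow + 1L, mcell$cellCol + 1L)] <- trueY[markerSel]

  manifest <- data.frame(
    x = dotIdx$col + 1L, y = dotIdx$row + 1L,
    class = dotClass,
    clone_id = ifelse(is.na(dotClone), "", dotClone),
    replicate = ifelse(is.na(dotRep), 0L, dotRep),
    amplitude = ifelse(is.na(dotAmp), 0, dotAmp),
    stringsAsFactors = FALSE)

  truth <- new("GroundTruth", layout = lay, manifest = manifest,
               markerX = markerX, markerY = markerY,
               offsetField = offsetField, gainField = gainField,
               params = unclass(spec)[setdiff(names(spec), "layout")],
               seed = as.integer(seed))
  image <- new("ArrayImage", pixels = img, source = "<synthetic>",
               mirrored = FALSE, bitDepth = 16L)
  list(image = image, truth = truth)
}

#' GroundTruth accessors
#'
#' \code{truthManifest} returns the dot-level truth table;
#' \code{cornerMarkers} the true marker centres of the four corner cells
#' (rounded to integer pixels), in the order top-left, top-right,
#' bottom-left, bottom-right -- the operator corner input the positioning
#' stage requires.
#'
#' @param x a \code{\linkS4class{GroundTruth}}.
#' @return \code{truthManifest}: data.frame; \code{cornerMarkers}: 4 x 2
#'   matrix with columns \code{x}, \code{y}.
#' @export
setGeneric("truthManifest", function(x) standardGeneric("truthManifest"))

#' @rdname truthManifest
#' @export
setMethod("truthManifest", "GroundTruth", function(x) x@manifest)

#' @rdname truthManifest
#' @export
setGeneric("cornerMarkers", function(x) standardGeneric("cornerMarkers"))

#' @rdname truthManifest
#' @export
setMethod("cornerMarkers", "GroundTruth", function(x) {
  n <- cellsPerSide(x@layout)
  m <- rbind(tl = c(x@markerX[1, 1], x@markerY[1, 1]),
             tr = c(x@markerX[1, n], x@markerY[1, n]),
             bl = c(x@markerX[n, 1], x@markerY[n, 1]),
             br = c(x@markerX[n, n], x@markerY[n, n]))
  colnames(m) <- c("x", "y")
  round(m)
})

setMethod("show", "GroundTruth", function(object) {
  tab <- table(object@manifest$class)
  cat(sprintf("GroundTruth: %d dots (seed %d)\n",
              nrow(object@manifest), object@seed))
  cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                  collapse = ", "), "\n")
})

#' Write / read the ground-truth manifest
#'
#' Tab-separated truth table (one row per dot: x, y, class, clone_id,
#' replicate, amplitude) suitable for joining against pipeline output on
#' (x, y).
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param path output (input) path.
#' @return \code{writeManifest}: the path, invisibly; \code{readManifest}:
#'   the manifest data.frame.
#' @export
writeManifest <- function(truth, path) {
  writeTSV(truthManifest(truth), path,
           comment = "synthetic ground truth manifest")
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) readTSV(path)

#' Compare clone calls against a ground-truth manifest
#'
#' Joins a \code{\link{validatePairs}} call table to the truth manifest by
#' clone id and computes clone-level precision and recall of the positive
#' calls against the true signal pairs.
#'
#' @param calls data.frame from \code{\link{validatePairs}} (or a
#'   \code{\linkS4class{MacroarrayRun}}).
#' @param truth a \code{\linkS4class{GroundTruth}} or its manifest.
#' @return list with \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}.
#' @export
scoreAgainstTruth <- function(calls, truth) {
  if (is(calls, "MacroarrayRun")) calls <- cloneCalls(calls)
  man <- if (is(truth, "GroundTruth")) truthManifest(truth) else truth
  trueClones <- unique(man$clone_id[man$class == "signal"])
  called <- calls$clone_id[calls$status == "positive"]
  tp <- length(intersect(called, trueClones))
  fp <- length(setdiff(called, trueClones))
  fn <- length(setdiff(trueClones, called))
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
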