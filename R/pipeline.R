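# End-to-end pipeline orchestration and result bundle output.

#' Run the full macroarray analysis pipeline
#'
#' Executes every stage in order on one scan: (optional) mirroring and the
#' saturation pre-check; two-stage marker positioning from the four
#' operator-supplied corner coordinates; cell-wise array reconstruction;
#' per-dot background offset estimation with robust outlier repair;
#' background subtraction and pixel summation; null-dot removal (markers by
#' position, blanks by the divergence of the intensity field); locality-MAD
#' scoring; positive calling; duplicate-pair validation.  Deterministic:
#' identical input and configuration give identical outputs.
#'
#' @param image an \code{\linkS4class{ArrayImage}}, or a TIFF path.
#' @param corners corner marker coordinates (see \code{\link{asCorners}});
#'   required before any pixel is touched.
#' @param layout an \code{\linkS4class{ArrayLayout}}.
#' @param mirror flip the image left-right before processing.
#' @param pairMap data.frame mapping dots to clone pairs (default
#'   \code{\link{makePairMap}} for the layout).
#' @param madThreshold MAD threshold for positive calls (default 3).
#' @param radius locality radius in dot units (default 4).
#' @param blankTau \code{"auto"} or an absolute sink-score threshold.
#' @param strictSaturation abort when saturated pixels are present.
#' @param saturationLimit saturation limit (default 65535).
#' @param outDir optional directory: when given, the result bundle (scores
#'   TSV, clone calls TSV, null mask TSV, QC montage PNG, overlay PNG,
#'   histogram TSV, resolved configuration, run log) is written there.
#' @return A \code{\linkS4class{MacroarrayRun}}.
#' @seealso \code{\link{scoreTable}}, \code{\link{cloneCalls}},
#'   \code{\link{stackResults}}
#' @export
runPipeline <- function(image, corners, layout = makeLayout(),
                        mirror = FALSE, pairMap = NULL, madThreshold = 3,
                        radius = 4, blankTau = "auto",
                        strictSaturation = FALSE, saturationLimit = 65535,
                        outDir = NULL) {
  if (missing(corners) || is.null(corners))
    stop("corner coordinates are required (tl, tr, bl, br)")
  corners <- asCorners(corners)  # validate before touching pixels
  cfg <- list(source = if (is.character(image)) image else "<in-memory>",
              mirror = mirror, corners = corners,
              dotsPerSide = dotsPerSide(layout),
              madThreshold = madThreshold, radius = radius,
              blankTau = blankTau, strictSaturation = strictSaturation,
              saturationLimit = saturationLimit)
  if (is.character(image)) image <- loadArrayImage(image)
  if (mirror) image <- mirrorImage(image)

  sat <- checkSaturation(image, saturationLimit)
  if (!sat$pass && strictSaturation)
    stop(sprintf("saturation check failed: %d pixels >= %g (strict mode)",
                 sat$count, saturationLimit))

  markers <- buildMarkerGrid(image, corners, layout)
  mosaic <- reconstructArray(image, markers)

  rawOff <- dotOffsets(mosaic, layout)
  off <- repairOffsets(rawOff, layout, radius = radius)
  qs <- subtractAndSum(mosaic, off$offset, layout)

  nulls <- classifyNulls(qs$subtracted, layout, tau = blankTau)
  sc <- madScores(qs$sums, nulls$classes, layout, radius = radius)
  tab <- linearizeScores(qs$sums, sc)
  if (is.null(pairMap)) pairMap <- makePairMap(layout)
  calls <- validatePairs(sc, pairMap, threshold = madThreshold)

  log <- c(
    sprintf("saturated pixels: %d", sat$count),
    sprintf("fallback markers: %d / %d", fallbackCount(markers),
            nCells(layout)),
    sprintf("repaired offsets: %d", sum(off$flagged)),
    sprintf("blank dots: %d (tau = %.4g)", sum(nulls$classes == "blank"),
            nulls$tau),
    sprintf("degenerate localities: %d", sum(sc$flags == "degenerate")),
    sprintf("sparse localities: %d", sum(sc$flags == "sparse")),
    sprintf("positive dots (> %g MADs): %d", madThreshold,
            sum(tab$flag == "ok" & !is.na(tab$score) &
                  tab$score > madThreshold)),
    sprintf("positive clone pairs: %d", sum(calls$status == "positive")))

  run <- new("MacroarrayRun", layout = layout, markers = markers,
             nullClasses = nulls$classes, sinkScores = nulls$sinkScores,
             offsets = off$offset, offsetFlags = off$flagged,
             sums = qs$sums, scores = sc$scores, scoreFlags = sc$flags,
             scoreTable = tab, cloneCalls = calls, config = cfg,
             stageLog = log)
  if (!is.null(outDir)) writeRunBundle(run, image, mosaic, outDir)
  run
}

#' MacroarrayRun accessors
#'
#' \code{scoreTable} returns the linearised per-dot table (x, y, sum, score,
#' flag); \code{cloneCalls} the pair-validated clone table;
#' \code{dotIntensities} the background-subtracted sum matrix;
#' \code{nullClasses} the per-dot class matrix; \code{runLog} the per-stage
#' QC counts.
#'
#' @param x a \code{MacroarrayRun}.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "MacroarrayRun", function(x) x@scoreTable)

#' @rdname scoreTable
#' @export
setGeneric("cloneCalls", function(x) standardGeneric("cloneCalls"))

#' @rdname scoreTable
#' @export
setMethod("cloneCalls", "MacroarrayRun", function(x) x@cloneCalls)

#' @rdname scoreTable
#' @export
setGeneric("dotIntensities", function(x) standardGeneric("dotIntensities"))

#' @rdname scoreTable
#' @export
setMethod("dotIntensities", "MacroarrayRun", function(x) x@sums)

#' @rdname scoreTable
#' @export
setGeneric("nullClasses", function(x) standardGeneric("nullClasses"))

#' @rdname scoreTable
#' @export
setMethod("nullClasses", "MacroarrayRun", function(x) x@nullClasses)

#' @rdname scoreTable
#' @export
setGeneric("runLog", function(x) standardGeneric("runLog"))

#' @rdname scoreTable
#' @export
setMethod("runLog", "MacroarrayRun", function(x) x@stageLog)

setMethod("show", "MacroarrayRun", function(object) {
  cat(sprintf("MacroarrayRun: %d x %d dots\n",
              dotsPerSide(object@layout), dotsPerSide(object@layout)))
  for (l in object@stageLog) cat(" ", l, "\n")
})

# write the full result bundle of one run
writeRunBundle <- function(run, image, mosaic, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  lay <- run@layout
  writeTSV(run@scoreTable, file.path(outDir, "scores.tsv"),
           comment = "per-dot background-subtracted sums and MAD scores")
  writeTSV(run@cloneCalls, file.path(outDir, "clone_calls.tsv"),
           comment = "duplicate-pair validated clone calls")
  d <- dotsPerSide(lay)
  g <- expand.grid(y = seq_len(d), x = seq_len(d))
  nm <- data.frame(x = g$x, y = g$y,
                   class = run@nullClasses[cbind(g$y, g$x)],
                   sink_score = run@sinkScores[cbind(g$y, g$x)])
  writeTSV(nm, file.path(outDir, "null_mask.tsv"),
           comment = "per-dot null classification and sink scores")
  hist <- scoreHistogram(list(scores = run@scores, flags = run@scoreFlags))
  writeTSV(hist, file.path(outDir, "score_histogram.tsv"),
           comment = "dot count vs number of MADs from median")
  # QC montage and blank map
  qc <- qcSample(image, run@markers, k = min(6L, cellsPerSide(lay)))
  writeGrayPNG(qc$montage, file.path(outDir, "qc_montage.png"))
  writeGrayPNG(nullMaskImage(run@nullClasses),
               file.path(outDir, "blank_map.png"))
  # overlay: reconstructed image with called dots marked in red
  gimg <- mosaic / max(mosaic, 1)
  rgb <- array(rep(gimg, 3L), dim = c(nrow(gimg), ncol(gimg), 3L))
  pos <- run@scoreTable[run@scoreTable$flag == "ok" &
                          !is.na(run@scoreTable$score) &
                          run@scoreTable$score > run@config$madThreshold, ]
  p <- pxPerDot(lay)
  for (i in seq_len(nrow(pos))) {
    rows <- ((pos$y[i] - 1L) * p + 1L):(pos$y[i] * p)
    cols <- ((pos$x[i] - 1L) * p + 1L):(pos$x[i] * p)
    rgb[rows, cols, 1L] <- 1
    rgb[rows, cols, 2L] <- rgb[rows, cols, 2L] * 0.4
    rgb[rows, cols, 3L] <- rgb[rows, cols, 3L] * 0.4
  }
  png::writePNG(rgb, file.path(outDir, "overlay.png"))
  # resolved configuration and stage log, for provenance
  cfg <- run@config
  cfg$corners <- paste(apply(cfg$corners, 1L, paste, collapse = ","),
                       collapse = "; ")
  writeLines(c(paste0(names(cfg), ": ", vapply(cfg, function(x)
    paste(format(x), collapse = " "), character(1L)))),
    file.path(outDir, "config.txt"))
  writeLines(run@stageLog, file.path(outDir, "run_log.txt"))
  invisible(outDir)
}

#' Stack score tables from several runs for comparative study
#'
#' Combines the per-dot score tables of multiple samples (runs of the same
#' layout) into one long-format table keyed by (sample, x, y) -- the format
#' for cross-sample or longitudinal comparison.  No imputation: every dot
#' of every sample appears exactly once, flags included.
#'
#' @param runs list of \code{\linkS4class{MacroarrayRun}} objects (or score
#'   table data.frames).
#' @param ids character sample identifiers (default: list names or
#'   \code{sample1..n}).
#' @return Long data.frame with columns \code{sample}, \code{x}, \code{y},
#'   \code{sum}, \code{score}, \code{flag}.
#' @export
stackResults <- function(runs, ids = NULL) {
  tabs <- lapply(runs, function(r)
    if (is(r, "MacroarrayRun")) scoreTable(r) else r)
  if (is.null(ids))
    ids <- if (!is.null(names(runs)) && all(nzchar(names(runs))))
      names(runs) else paste0("sample", seq_along(runs))
  n <- unique(vapply(tabs, nrow, integer(1L)))
  if (length(n) != 1L)
    stop("score tables disagree in size: runs use different layouts")
  do.call(rbind, Map(function(tab, id)
    cbind(sample = id, tab, stringsAsFactors = FALSE), tabs, ids))
}
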