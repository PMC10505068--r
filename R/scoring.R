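# Locality-MAD normalisation, positive calling and duplicate-pair (clone
# level) validation.
#
# With no absolute reference on the membrane, overexpression is defined
# relative to a dot's locality: the score is the dot sum's deviation from
# the local median, normalised by the local raw MAD -- "the number of MADs
# from median".  Because median and MAD are taken over the same locality,
# any locality-wise affine transform of the sums (local offset and gain)
# cancels exactly, which is what makes scores comparable across arrays,
# samples and time points.

#' Locality-MAD scores for every dot
#'
#' For each valid (non-marker, non-blank) dot, the sample is the set of
#' valid dots within the locality disc (radius 4 by default, clipped at the
#' array border); the score is \code{(sum - median(sample)) / MAD(sample)}
#' with the raw (unscaled) median of absolute deviations.  The score is
#' signed: only significantly HIGHER intensity constitutes overexpression.
#' Dots whose sample MAD is zero are flagged \code{degenerate}, dots with
#' fewer than \code{minSample} valid neighbours \code{sparse}; neither
#' receives a score nor can be called positive.  Marker and blank dots are
#' excluded both from the samples and from scoring.
#'
#' @param sums numeric dot matrix from \code{\link{subtractAndSum}}.
#' @param classes character dot matrix from \code{\link{classifyNulls}}
#'   (\code{marker}/\code{blank}/\code{valid}).
#' @param layout an \code{\linkS4class{ArrayLayout}}.
#' @param radius locality radius in dot units (default 4, i.e. 49 dots in
#'   the interior).
#' @param minSample minimum valid locality sample size (default 9).
#' @return list with \code{scores} (numeric dot matrix, NA where unscored),
#'   \code{flags} (character dot matrix: \code{ok}, \code{degenerate},
#'   \code{sparse}, \code{marker}, \code{blank}), \code{localitySize}
#'   (integer dot matrix of valid sample sizes).
#' @export
madScores <- function(sums, classes, layout, radius = 4, minSample = 9L) {
  d <- dotsPerSide(layout)
  stopifnot(all(dim(sums) == d), all(dim(classes) == d))
  V <- sums
  V[classes != "valid"] <- NA_real_
  st <- localityStats(V, radius, layout)
  scores <- (sums - st$median) / st$mad
  flags <- matrix("ok", d, d)
  flags[st$mad == 0] <- "degenerate"
  flags[st$n < minSample] <- "sparse"
  flags[classes == "marker"] <- "marker"
  flags[classes == "blank"] <- "blank"
  scores[flags != "ok"] <- NA_real_
  list(scores = scores, flags = flags, localitySize = st$n)
}

#' Linearise a score table
#'
#' One row per dot position -- markers, blanks and degenerate dots included
#' with their flags, never silently dropped -- with 1-based x (dot column)
#' and y (dot row) coordinates for matching against the protein library
#' annotation.
#'
#' @param sums,scoreObj results of \code{\link{subtractAndSum}} (matrix) and
#'   \code{\link{madScores}}.
#' @return data.frame with columns \code{x}, \code{y}, \code{sum},
#'   \code{score}, \code{flag}, covering all \code{dotsPerSide^2} positions.
#' @export
linearizeScores <- function(sums, scoreObj) {
  d <- nrow(sums)
  g <- expand.grid(y = seq_len(d), x = seq_len(d))  # row-major within x
  data.frame(x = g$x, y = g$y,
             sum = sums[cbind(g$y, g$x)],
             score = scoreObj$scores[cbind(g$y, g$x)],
             flag = scoreObj$flags[cbind(g$y, g$x)],
             stringsAsFactors = FALSE)
}

#' Call positive dots at a MAD threshold
#'
#' Positives are the valid, scored dots whose score STRICTLY exceeds the
#' threshold (default 3, the customary cutoff; a dot scoring exactly 3 is
#' not called).
#'
#' @param scoreObj result of \code{\link{madScores}}.
#' @param threshold MAD threshold (default 3).
#' @return data.frame of positive dots: \code{x}, \code{y}, \code{score}.
#' @export
callPositives <- function(scoreObj, threshold = 3) {
  sel <- which(scoreObj$flags == "ok" & scoreObj$scores > threshold,
               arr.ind = TRUE)
  out <- data.frame(x = as.integer(sel[, 2L]), y = as.integer(sel[, 1L]),
                    score = scoreObj$scores[sel])
  out[order(out$y, out$x), , drop = FALSE]
}

#' Score histogram data
#'
#' Binned counts of the valid dot scores (the familiar dot-count versus
#' number-of-MADs histogram; strong arrays show a long right tail).
#'
#' @param scoreObj result of \code{\link{madScores}}.
#' @param binWidth histogram bin width in MAD units (default 0.5).
#' @return data.frame with \code{mid} (bin midpoint) and \code{count}.
#' @export
scoreHistogram <- function(scoreObj, binWidth = 0.5) {
  v <- scoreObj$scores[scoreObj$flags == "ok"]
  if (!length(v)) return(data.frame(mid = numeric(0), count = integer(0)))
  br <- seq(floor(min(v) / binWidth) * binWidth,
            ceiling(max(v) / binWidth) * binWidth + binWidth, by = binWidth)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

#' Duplicate-pair (clone level) validation
#'
#' Every clone is printed as a duplicate dot pair; a clone is called
#' positive only when BOTH replicates are validly scored and both scores
#' strictly exceed the threshold.  Clones with a marker/blank/degenerate/
#' sparse replicate are \code{unevaluable} and never positive; clones with
#' exactly one replicate above threshold are \code{negative} (the singleton
#' is visible in the per-dot output for QC).
#'
#' @param scoreObj result of \code{\link{madScores}}.
#' @param pairMap data.frame with columns \code{x}, \code{y},
#'   \code{clone_id}, \code{replicate}; every clone id must map exactly two
#'   dots (see \code{\link{makePairMap}}).
#' @param threshold MAD threshold (default 3).
#' @return data.frame with one row per clone: \code{clone_id}, \code{x1},
#'   \code{y1}, \code{score1}, \code{x2}, \code{y2}, \code{score2},
#'   \code{minScore}, \code{status}
#'   (\code{positive}/\code{negative}/\code{unevaluable}).
#' @export
validatePairs <- function(scoreObj, pairMap, threshold = 3) {
  need <- c("x", "y", "clone_id", "replicate")
  if (!all(need %in% names(pairMap)))
    stop("pairMap must have columns x, y, clone_id, replicate")
  cnt <- table(pairMap$clone_id)
  if (any(cnt != 2L))
    stop("pair map clones without exactly 2 dots: ",
         paste(utils::head(names(cnt)[cnt != 2L], 5L), collapse = ", "))
  pm <- pairMap[order(pairMap$clone_id, pairMap$replicate), ]
  i1 <- seq(1L, nrow(pm), by = 2L)
  i2 <- i1 + 1L
  s1 <- scoreObj$scores[cbind(pm$y[i1], pm$x[i1])]
  s2 <- scoreObj$scores[cbind(pm$y[i2], pm$x[i2])]
  f1 <- scoreObj$flags[cbind(pm$y[i1], pm$x[i1])]
  f2 <- scoreObj$flags[cbind(pm$y[i2], pm$x[i2])]
  evaluable <- f1 == "ok" & f2 == "ok"
  positive <- evaluable & s1 > threshold & s2 > threshold
  status <- ifelse(!evaluable, "unevaluable",
                   ifelse(positive, "positive", "negative"))
  data.frame(clone_id = pm$clone_id[i1],
             x1 = pm$x[i1], y1 = pm$y[i1], score1 = s1,
             x2 = pm$x[i2], y2 = pm$y[i2], score2 = s2,
             minScore = pmin(s1, s2),
             status = status, stringsAsFactors = FALSE)
}
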