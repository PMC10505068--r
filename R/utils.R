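# Internal numeric helpers shared across modules.

# Raw median absolute deviation: median(|x - median(x)|), deliberately
# WITHOUT the 1.4826 normal-consistency factor.  The pipeline's scores are
# reported in "number of MADs from median" units, so the raw MAD is the unit
# itself; rescaling would silently change the meaning of the published
# threshold of 3.
rawMad <- function(x) {
  x <- x[!is.na(x)]
  stats::median(abs(x - stats::median(x)))
}

# Dark-blob threshold for marker refinement.  The marker is a small
# (< 1 percent of the window) high-contrast dark blob, so balanced
# bimodal splits (e.g. Otsu) latch onto the dominant background mode
# instead; the robust rule is the midpoint between the dark tail (1st
# percentile, a noise-proof stand-in for the minimum) and the window
# median (the background level).
# Weighted toward the dark tail (0.3) because the window median is itself
# elevated by the bright clone dots that cover much of a cell.
darkThreshold <- function(v) {
  q <- stats::quantile(v, c(0.01, 0.5), names = FALSE, type = 7)
  q[1L] + 0.3 * (q[2L] - q[1L])
}

# Separable Gaussian smoothing of a small matrix with replicated (clamped)
# borders; sd in pixels, kernel truncated at 2*sd.
gaussSmooth <- function(m, sd = 1) {
  r <- max(1L, ceiling(2 * sd))
  k <- exp(-(-r:r)^2 / (2 * sd^2))
  k <- k / sum(k)
  n <- nrow(m); p <- ncol(m)
  idx <- function(i, nmax) pmin(pmax(i, 1L), nmax)
  out <- matrix(0, n, p)
  for (o in -r:r) out <- out + k[o + r + 1L] * m[idx(seq_len(n) + o, n), , drop = FALSE]
  out2 <- matrix(0, n, p)
  for (o in -r:r) out2 <- out2 + k[o + r + 1L] * out[, idx(seq_len(p) + o, p), drop = FALSE]
  out2
}

# Per-dot block reduction of an ROI mosaic (roi x roi px) into a
# dotsPerSide x dotsPerSide matrix, using the strided-submatrix trick:
# the (pr, pc) strided view collects pixel (pr, pc) of every tile.
blockReduce <- function(mosaic, layout, op = c("sum", "min")) {
  op <- match.arg(op)
  p <- pxPerDot(layout); roi <- roiSidePx(layout)
  stopifnot(nrow(mosaic) == roi, ncol(mosaic) == roi)
  acc <- NULL
  f <- if (op == "sum") `+` else pmin
  for (pr in seq_len(p)) for (pc in seq_len(p)) {
    sub <- mosaic[seq(pr, roi, by = p), seq(pc, roi, by = p)]
    acc <- if (is.null(acc)) sub else f(acc, sub)
  }
  acc
}

# Expand a per-dot matrix to per-pixel resolution over the ROI mosaic.
blockExpand <- function(dotmat, layout) {
  p <- pxPerDot(layout)
  dotmat[rep(seq_len(nrow(dotmat)), each = p),
         rep(seq_len(ncol(dotmat)), each = p)]
}

# Per-dot locality statistics over a dot-level value matrix V [row, col].
# Returns list(median, mad, n): matrices of the same shape.  NA entries of V
# are excluded from samples (and get statistics from their neighbours all the
# same).  Implemented by stacking one shifted copy of V per disc offset.
localityStats <- function(V, radius, layout) {
  d <- dotsPerSide(layout)
  off <- localityOffsets(radius)
  K <- nrow(off)
  n <- d * d
  stack <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    dc <- off$dcol[k]; dr <- off$drow[k]
    sr <- seq_len(d) + dr        # source rows for each target row
    sc <- seq_len(d) + dc
    okr <- sr >= 1L & sr <= d
    okc <- sc >= 1L & sc <= d
    sh <- matrix(NA_real_, d, d)
    sh[okr, okc] <- V[sr[okr], sc[okc]]
    stack[, k] <- as.vector(sh)
  }
  med <- apply(stack, 1L, stats::median, na.rm = TRUE)
  madv <- apply(abs(stack - med), 1L, stats::median, na.rm = TRUE)
  nv <- rowSums(!is.na(stack))
  list(median = matrix(med, d, d), mad = matrix(madv, d, d),
       n = matrix(nv, d, d))
}

# Write a numeric matrix as an 8-bit grayscale PNG, linearly rescaled.
writeGrayPNG <- function(m, path, lo = min(m), hi = max(m)) {
  g <- (m - lo) / max(hi - lo, .Machine$double.eps)
  png::writePNG(pmin(pmax(g, 0), 1), path)
  invisible(path)
}

# Tab-separated output with a fixed comment header declaring the 1-based
# x/y coordinate convention used in all report files.
writeTSV <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: x = dot column (1-based), y = dot row (1-based)",
             con)
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTSV <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
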