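# Shared fixtures: small layouts and deterministic synthetic scenes.

# brute-force lattice-disc oracle: all integer (dcol, drow) with
# dcol^2 + drow^2 <= r^2, enumerated over the bounding square
bruteDiscOffsets <- function(r) {
  g <- expand.grid(dcol = -r:r, drow = -r:r)
  g[g$dcol^2 + g$drow^2 <= r^2, ]
}

# sort-based median oracle, independent of stats::median
oracleMedian <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

# brute-force raw MAD oracle
oracleRawMad <- function(x) oracleMedian(abs(x - oracleMedian(x)))

smallLayout <- function(dots = 30L) makeLayout(dotsPerSide = dots)

# a small quiet scene: 12 cells/side, flat fields unless overridden
quietSpec <- function(dots = 60L, ...) {
  over <- list(...)
  defaults <- list(layout = makeLayout(dotsPerSide = as.integer(dots)),
                   warpMaxPx = 0, noiseSd = 0, shotNoise = FALSE,
                   offsetAmp = 0, gainAmp = 0,
                   nSignalPairs = 6, nStrongPairs = 0, blankRates = c(0, 0))
  do.call(simSpec, utils::modifyList(defaults, over))
}

simQuiet <- function(seed = 11, ...) {
  suppressWarnings(simulateArray(quietSpec(...), seed = seed))
}

# independent per-tile pixel sums for the dots listed in a manifest-like
# data.frame with 1-based x, y columns
blockReduceOracle <- function(mosaic, dots) {
  vapply(seq_len(nrow(dots)), function(i)
    sum(mosaic[(dots$y[i] - 1) * 9 + 1:9, (dots$x[i] - 1) * 9 + 1:9]),
    numeric(1))
}
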