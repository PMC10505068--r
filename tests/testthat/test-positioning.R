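# Two-stage positioning: interpolation, refinement, reconstruction, QC.

test_that("bilinear interpolation reproduces corners and uniform grids", {
  lay <- makeLayout()  # 48 cells/side
  g <- interpolateGrid(rbind(c(0, 0), c(470, 0), c(0, 470), c(470, 470)),
                       lay)
  expect_equal(g$cx[1, ], seq(0, 470, by = 10))
  expect_equal(g$cy[, 1], seq(0, 470, by = 10))
  expect_equal(g$cx[48, 48], 470)

  # sheared parallelogram: bilinear reduces to the affine map
  A <- matrix(c(2, 0.3, 0.1, 1.7), 2, 2)
  uv <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  corners <- t(A %*% t(uv)) * 100 + 50
  g2 <- interpolateGrid(corners, lay)
  fr <- (0:47) / 47
  for (pick in list(c(5, 9), c(20, 33), c(48, 1))) {
    i <- pick[1]; j <- pick[2]
    exp_xy <- as.vector(A %*% c(fr[j], fr[i])) * 100 + 50
    expect_equal(c(g2$cx[i, j], g2$cy[i, j]), exp_xy, tolerance = 1e-9)
  }
  expect_error(interpolateGrid(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                               lay), "degenerate")
})

test_that("marker refinement recovers a dark blob centre exactly", {
  flat <- matrix(200, 100, 100)
  d <- as.matrix(expand.grid(y = 1:100, x = 1:100))
  blob <- 180 * exp(-((d[, "x"] - 50)^2 + (d[, "y"] - 47)^2) / 8)
  blob[(d[, "x"] - 50)^2 + (d[, "y"] - 47)^2 > 16] <- 0
  img <- flat - matrix(blob, 100, 100)

  r <- refineMarker(img, approx = c(53, 45), window = 10L)
  expect_equal(c(r$x, r$y), c(50, 47))
  expect_equal(r$status, "refined")

  # a nearby bright signal dot does not distract the low-intensity search
  bright <- 5000 * exp(-((d[, "x"] - 59)^2 + (d[, "y"] - 47)^2) / 8)
  r2 <- refineMarker(img + matrix(bright, 100, 100), c(53, 45), 10L)
  expect_equal(c(r2$x, r2$y), c(50, 47))

  # uniform window: no blob, fall back to the approximation
  r3 <- refineMarker(matrix(500, 100, 100), c(50, 50), 10L)
  expect_equal(r3$status, "fallback")
  expect_equal(c(r3$x, r3$y), c(50, 50))

  expect_error(refineMarker(img, c(5, 5), 10L), "outside")
})

test_that("zero-warp noiseless positioning recovers every marker exactly", {
  sim <- simQuiet(dots = 30L)
  mg <- buildMarkerGrid(sim$image, cornerMarkers(sim$truth),
                        sim$truth@layout)
  expect_equal(fallbackCount(mg), 0L)
  expect_equal(mg@cx, sim$truth@markerX)
  expect_equal(mg@cy, sim$truth@markerY)
})

test_that("warped noisy positioning stays within one pixel per axis", {
  # no dot-filling strong pairs here: positioning accuracy presumes the
  # printed marker is the darkest object in its window; a marker drowned
  # by an adjacent saturating bloom falls back to its interpolated
  # position by design (exercised in the pipeline tests)
  spec <- simSpec(layout = makeLayout(dotsPerSide = 60L), warpMaxPx = 3,
                  noiseSd = 50, nSignalPairs = 10, nStrongPairs = 0)
  sim <- suppressWarnings(simulateArray(spec, seed = 23))
  mg <- buildMarkerGrid(sim$image, cornerMarkers(sim$truth),
                        sim$truth@layout)
  expect_lte(max(abs(mg@cx - sim$truth@markerX)), 1)
  expect_lte(max(abs(mg@cy - sim$truth@markerY)), 1)
  expect_equal(mg@status[mg@status == "refined"],
               rep("refined", sum(mg@status == "refined")))
})

test_that("transposed corner input violates grid monotonicity", {
  sim <- simQuiet(dots = 30L)
  cm <- cornerMarkers(sim$truth)
  swapped <- cm[c(1, 3, 2, 4), ]  # tr <-> bl: transposed array
  expect_error(buildMarkerGrid(sim$image, swapped, sim$truth@layout),
               "monotonic|positioning failure")
})

test_that("cell tiles anchor on the marker and tile the reconstruction", {
  sim <- simQuiet(dots = 30L, offsetBase = 412)
  lay <- sim$truth@layout
  mg <- buildMarkerGrid(sim$image, cornerMarkers(sim$truth), lay)

  tile <- extractCell(sim$image, mg, 3, 2)
  expect_equal(dim(tile), c(45L, 45L))
  # marker block (central 9x9) has the lowest mean of the 25 dot blocks
  blocks <- sapply(0:4, function(wi) sapply(0:4, function(wj)
    mean(tile[wj * 9 + 1:9, wi * 9 + 1:9])))
  expect_equal(which.min(blocks), 13L)
  # corner pixel of a dot tile is pure flat background
  expect_equal(tile[1, 1], 412)

  mosaic <- reconstructArray(sim$image, mg)
  expect_equal(dim(mosaic), c(roiSidePx(lay), roiSidePx(lay)))
  # tile of cell (3, 2) appears verbatim in the mosaic
  expect_equal(mosaic[45 + 1:45, 2 * 45 + 1:45], tile)
})

test_that("QC sampling is deterministic and confirms marker-darkest tiles", {
  sim <- simQuiet(dots = 60L, noiseSd = 30)
  lay <- sim$truth@layout
  mg <- buildMarkerGrid(sim$image, cornerMarkers(sim$truth), lay)
  qc <- qcSample(sim$image, mg, k = 6L)
  expect_equal(qc$indices, round(seq(1, 12, length.out = 6)))
  expect_equal(length(qc$tiles), 36L)
  expect_true(all(qc$markerDarkest))
  expect_equal(dim(qc$montage), c(6L * 45L, 6L * 45L))

  q1 <- qcSample(sim$image, mg, k = 1L)
  expect_equal(q1$indices, 6)  # the central cell
  expect_error(qcSample(sim$image, mg, k = 40L), "exceeds")
})
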