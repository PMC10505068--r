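# Background offsets, robust repair, subtraction and summation.

test_that("dot offsets are tile minima", {
  lay <- makeLayout(dotsPerSide = 5L)  # one cell, 45 x 45 mosaic
  mosaic <- matrix(500, 45, 45)
  off <- dotOffsets(mosaic, lay)
  expect_equal(off, matrix(500, 5, 5))
  mosaic[12, 30] <- 120  # dot (col 4, row 2) in 1-based dot coordinates
  off2 <- dotOffsets(mosaic, lay)
  expect_equal(off2[2, 4], 120)
  expect_equal(sum(off2 == 500), 24L)

  # agreement with a direct per-tile minimum for random content
  set.seed(8)
  m <- matrix(runif(45 * 45, 0, 1000), 45, 45)
  off3 <- dotOffsets(m, lay)
  for (pick in list(c(1, 1), c(3, 4), c(5, 5))) {
    expect_equal(off3[pick[1], pick[2]],
                 min(m[(pick[1] - 1) * 9 + 1:9, (pick[2] - 1) * 9 + 1:9]))
  }
})

test_that("offset repair flags only genuine outliers and does not cascade", {
  lay <- makeLayout(dotsPerSide = 20L)
  eq <- matrix(300, 20, 20)
  r <- repairOffsets(eq, lay)
  expect_equal(sum(r$flagged), 0L)
  expect_equal(r$offset, eq)

  # one signal-filled dot: abnormally high offset, replaced by local median
  spiked <- eq
  spiked[10, 10] <- 5000
  r2 <- repairOffsets(spiked, lay)
  expect_true(r2$flagged[10, 10])
  expect_equal(r2$offset[10, 10], 300)
  expect_equal(sum(r2$flagged), 1L)

  # symmetric noise: false-flag rate below 1 percent at k = 3
  set.seed(21)
  lay60 <- makeLayout(dotsPerSide = 60L)
  noisy <- matrix(rnorm(3600, 300, 20), 60, 60)
  r3 <- repairOffsets(noisy, lay60)
  expect_lte(mean(r3$flagged), 0.01)
})

test_that("subtraction clamps at zero and sums recover spikes exactly", {
  lay <- makeLayout(dotsPerSide = 5L)
  mosaic <- matrix(400, 45, 45)
  mosaic[20, 20] <- 400 + 1234   # single-pixel spike on dot (3, 3)
  off <- matrix(400, 5, 5)
  qs <- subtractAndSum(mosaic, off, lay)
  expect_equal(qs$sums[3, 3], 1234)
  expect_equal(sum(qs$sums), 1234)  # all other dots sum to zero
  # minimum pixel of every dot tile is zero after subtraction
  expect_equal(dotOffsets(qs$subtracted, lay), matrix(0, 5, 5))
  # clamping: an offset above a pixel's value never produces negatives
  qs2 <- subtractAndSum(mosaic, off + 50, lay)
  expect_gte(min(qs2$subtracted), 0)
})

test_that("dot sums rank-match true amplitudes in a noiseless scene", {
  sim <- simQuiet(dots = 60L, nSignalPairs = 10, gainAmp = 0,
                  offsetAmp = 0)
  lay <- sim$truth@layout
  mg <- buildMarkerGrid(sim$image, cornerMarkers(sim$truth), lay)
  mosaic <- reconstructArray(sim$image, mg)
  off <- repairOffsets(dotOffsets(mosaic, lay), lay)
  sums <- subtractAndSum(mosaic, off, lay)$sums
  man <- truthManifest(sim$truth)
  keep <- man$class %in% c("basal", "signal")
  rho <- cor(sums[cbind(man$y, man$x)][keep], man$amplitude[keep],
             method = "spearman")
  expect_gte(rho, 0.99)
})

test_that("strong signals keep almost all their intensity through subtraction", {
  spec <- quietSpec(dots = 30L, offsetBase = 300, nSignalPairs = 0,
                    nStrongPairs = 2, strongAmp = 120000)
  sim <- suppressWarnings(simulateArray(spec, seed = 6))
  lay <- sim$truth@layout
  mg <- buildMarkerGrid(sim$image, cornerMarkers(sim$truth), lay)
  mosaic <- reconstructArray(sim$image, mg)
  raw <- dotOffsets(mosaic, lay)
  rep <- repairOffsets(raw, lay)
  sums <- subtractAndSum(mosaic, rep, lay)$sums
  man <- truthManifest(sim$truth)
  strong <- man[man$class == "signal", ]
  before <- blockReduceOracle(mosaic, strong)
  after <- sums[cbind(strong$y, strong$x)]
  # the dot-filling strong spots were flagged and repaired, not suppressed
  expect_true(all(rep$flagged[cbind(strong$y, strong$x)]))
  expect_true(all(after / before > 0.99))
  # and the change is bounded by 81 x the repaired offset
  expect_true(all(before - after <=
                    81 * rep$offset[cbind(strong$y, strong$x)] + 1e-6))
})
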