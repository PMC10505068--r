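# Synthetic generator: determinism, construction guarantees, manifest.

test_that("simulation is bit-identical for a fixed seed", {
  spec <- quietSpec(dots = 30L, noiseSd = 25, shotNoise = TRUE,
                    warpMaxPx = 2, offsetAmp = 100, gainAmp = 0.2)
  a <- simulateArray(spec, seed = 4)
  b <- simulateArray(spec, seed = 4)
  expect_identical(pixelData(a$image), pixelData(b$image))
  expect_identical(truthManifest(a$truth), truthManifest(b$truth))
  c <- simulateArray(spec, seed = 5)
  expect_false(identical(pixelData(a$image), pixelData(c$image)))
})

test_that("flat quiet scene renders exact backgrounds at tile corners", {
  # zero warp/noise, flat offset c, flat gain: the truncated point spread
  # leaves the corner pixels of every non-marker dot tile untouched, so the
  # tile minimum equals the offset exactly
  sim <- simQuiet(dots = 30L, offsetBase = 300)
  px <- pixelData(sim$image)
  lay <- sim$truth@layout
  man <- truthManifest(sim$truth)
  margin <- (lay@imageSidePx - roiSidePx(lay)) %/% 2L
  mins <- vapply(which(man$class != "marker"), function(i) {
    rows <- margin + (man$y[i] - 1L) * 9L + 1:9
    cols <- margin + (man$x[i] - 1L) * 9L + 1:9
    min(px[rows, cols])
  }, numeric(1))
  expect_equal(unique(mins), 300)
})

test_that("manifest structure matches the printed pair architecture", {
  spec <- quietSpec(dots = 60L, nSignalPairs = 5, nStrongPairs = 1,
                    blankRates = c(0.2, 0.4))
  sim <- suppressWarnings(simulateArray(spec, seed = 9))
  man <- truthManifest(sim$truth)
  lay <- sim$truth@layout
  expect_equal(nrow(man), nDots(lay))
  expect_equal(sum(man$class == "marker"), nCells(lay))
  expect_equal(sum(man$class == "signal"), 2L * 6L)

  # signal and blank dots come in clone pairs
  for (cl in c("signal", "blank")) {
    sub <- man[man$class == cl, ]
    expect_true(all(table(sub$clone_id) == 2L))
  }
  # at most two blank pairs (four blank dots) per cell
  blank <- man[man$class == "blank", ]
  cellIdx <- paste((blank$x - 1L) %/% 5L, (blank$y - 1L) %/% 5L)
  expect_true(all(table(cellIdx) <= 4L))
  # both replicates of a clone share the true amplitude
  amp <- tapply(man$amplitude[man$clone_id != ""],
                man$clone_id[man$clone_id != ""],
                function(a) diff(range(a)))
  expect_true(all(amp == 0))
})

test_that("manifest round-trips through its TSV form and joins completely", {
  sim <- simQuiet(dots = 30L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeManifest(sim$truth, tf)
  back <- readManifest(tf)
  man <- truthManifest(sim$truth)
  expect_equal(back$x, man$x)
  expect_equal(back$class, man$class)
  expect_equal(back$amplitude, man$amplitude, tolerance = 1e-12)
  # join against a pipeline-shaped (x, y) table leaves nothing unmatched
  grid <- expand.grid(y = 1:30, x = 1:30)
  j <- merge(grid, man, by = c("x", "y"))
  expect_equal(nrow(j), nrow(grid))
})

test_that("pair map pairs every clone point-symmetrically about the marker", {
  lay <- makeLayout(dotsPerSide = 20L)
  pm <- makePairMap(lay)
  expect_equal(nrow(pm), nDots(lay) - nCells(lay))
  expect_true(all(table(pm$clone_id) == 2L))
  expect_equal(length(unique(pm$clone_id)), 12L * nCells(lay))
  # replicate 2 is the point reflection of replicate 1 through the marker
  p1 <- pm[pm$replicate == 1L, ]
  p2 <- pm[pm$replicate == 2L, ]
  p2 <- p2[match(p1$clone_id, p2$clone_id), ]
  cellX <- ((p1$x - 1L) %/% 5L) * 5L + 3L  # marker column, 1-based
  cellY <- ((p1$y - 1L) %/% 5L) * 5L + 3L
  expect_equal(p2$x, 2L * cellX - p1$x)
  expect_equal(p2$y, 2L * cellY - p1$y)
})

test_that("amplitudes beyond the dynamic range are clipped with a warning", {
  spec <- quietSpec(dots = 30L, nSignalPairs = 0, nStrongPairs = 1,
                    strongAmp = 200000)
  expect_warning(sim <- simulateArray(spec, seed = 2), "clipped")
  expect_lte(max(pixelData(sim$image)), 65535)
  expect_gte(min(pixelData(sim$image)), 0)
})

test_that("raising one signal amplitude never lowers its dot sum (no noise)", {
  lows <- simQuiet(dots = 30L, nSignalPairs = 3,
                   signalAmpRange = c(8000, 8000))
  highs <- simQuiet(dots = 30L, nSignalPairs = 3,
                    signalAmpRange = c(16000, 16000))
  lay <- lows$truth@layout
  for (sim in list(lows, highs)) {
    # same seed => same clone selection
    expect_equal(truthManifest(sim$truth)$clone_id,
                 truthManifest(lows$truth)$clone_id)
  }
  man <- truthManifest(lows$truth)
  sig <- man[man$class == "signal", ]
  margin <- (lay@imageSidePx - roiSidePx(lay)) %/% 2L
  sumAt <- function(sim, x, y) {
    px <- pixelData(sim$image)
    sum(px[margin + (y - 1L) * 9L + 1:9, margin + (x - 1L) * 9L + 1:9])
  }
  for (i in seq_len(nrow(sig))) {
    expect_gt(sumAt(highs, sig$x[i], sig$y[i]),
              sumAt(lows, sig$x[i], sig$y[i]))
  }
})
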