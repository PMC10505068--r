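# MAD normalisation, positive calling and pair validation.

test_that("raw MAD matches the worked locality example and the brute force", {
  # locality sums 1..49, dot value 37: median 25, MAD 12, score 1
  expect_equal(stats::median(1:49), 25)
  expect_equal(macrogrid:::rawMad(1:49), 12)
  expect_equal((37 - 25) / macrogrid:::rawMad(1:49), 1)

  set.seed(77)
  for (i in 1:1000) {
    n <- sample(3:49, 1)
    x <- switch(sample(3, 1),
                rnorm(n, 100, 25),
                runif(n, 0, 1),
                sample(0:10, n, replace = TRUE))
    expect_equal(macrogrid:::rawMad(x), oracleRawMad(x))
  }
})

test_that("mad scores agree with a brute-force locality oracle", {
  set.seed(14)
  lay <- makeLayout(dotsPerSide = 15L)
  sums <- matrix(rgamma(225, 4, 0.01), 15, 15)
  classes <- matrix("valid", 15, 15)
  classes[cbind(sample(15, 20, TRUE), sample(15, 20, TRUE))] <- "blank"
  # markers at cell centres
  for (ci in 0:2) for (cj in 0:2) classes[cj * 5 + 3, ci * 5 + 3] <- "marker"

  sc <- madScores(sums, classes, lay, radius = 3)
  for (i in seq_len(80)) {
    x <- sample(0:14, 1); y <- sample(0:14, 1)
    if (classes[y + 1, x + 1] != "valid") next
    if (sc$flags[y + 1, x + 1] != "ok") next  # sparse border locality
    mem <- localityMembers(x, y, 3, lay)
    v <- sums[cbind(mem$row + 1, mem$col + 1)]
    v <- v[classes[cbind(mem$row + 1, mem$col + 1)] == "valid"]
    expected <- (sums[y + 1, x + 1] - oracleMedian(v)) / oracleRawMad(v)
    expect_equal(sc$scores[y + 1, x + 1], expected, tolerance = 1e-12)
  }
  # excluded dots carry flags, not scores
  expect_true(all(is.na(sc$scores[classes != "valid"])))
  expect_equal(sc$flags[classes == "marker"],
               rep("marker", sum(classes == "marker")))
})

test_that("equal sums are degenerate everywhere; sparse localities flagged", {
  lay <- makeLayout(dotsPerSide = 10L)
  classes <- matrix("valid", 10, 10)
  sc <- madScores(matrix(7, 10, 10), classes, lay)
  expect_true(all(sc$flags %in% c("degenerate")))
  expect_true(all(is.na(sc$scores)))

  # minSample larger than any locality: everything sparse
  sc2 <- madScores(matrix(rnorm(100), 10, 10), classes, lay,
                   minSample = 1000L)
  expect_true(all(sc2$flags == "sparse"))
})

test_that("scores are invariant under affine transforms of the sums", {
  set.seed(5)
  lay <- makeLayout(dotsPerSide = 20L)
  sums <- matrix(rgamma(400, 3, 1e-3), 20, 20)
  classes <- matrix("valid", 20, 20)
  a <- madScores(sums, classes, lay)
  b <- madScores(7.3 * sums + 1500, classes, lay)
  expect_lt(max(abs(a$scores - b$scores), na.rm = TRUE), 1e-9)
})

test_that("positive calls use a strict threshold", {
  scores <- matrix(NA_real_, 5, 5)
  flags <- matrix("marker", 5, 5)
  scores[2, 1:3] <- c(2.9, 3.0, 3.1)
  flags[2, 1:3] <- "ok"
  obj <- list(scores = scores, flags = flags)
  pos <- callPositives(obj, threshold = 3)
  expect_equal(nrow(pos), 1L)
  expect_equal(c(pos$x, pos$y), c(3L, 2L))
  expect_equal(nrow(callPositives(obj, threshold = Inf)), 0L)
})

test_that("score table covers every dot position exactly once", {
  lay <- makeLayout(dotsPerSide = 10L)
  sums <- matrix(rnorm(100, 1000, 10), 10, 10)
  classes <- matrix("valid", 10, 10)
  classes[3, 3] <- "marker"; classes[4, 7] <- "blank"
  sc <- madScores(sums, classes, lay)
  tab <- linearizeScores(sums, sc)
  expect_equal(nrow(tab), nDots(lay))
  expect_equal(anyDuplicated(paste(tab$x, tab$y)), 0L)
  expect_equal(sum(tab$flag == "marker"), 1L)
  expect_equal(sum(tab$flag == "blank"), 1L)
})

test_that("pair validation requires both replicates above threshold", {
  scores <- matrix(NA_real_, 5, 5)
  flags <- matrix("blank", 5, 5)
  put <- function(x, y, s, f = "ok") {
    scores[y, x] <<- s; flags[y, x] <<- f
  }
  put(1, 1, 5); put(2, 1, 6)        # cloneA: both high -> positive
  put(3, 1, 5); put(4, 1, 1)        # cloneB: singleton -> negative
  put(5, 1, 10); put(1, 2, NA, "degenerate")  # cloneC: unevaluable
  pm <- data.frame(
    x = c(1, 2, 3, 4, 5, 1), y = c(1, 1, 1, 1, 1, 2),
    clone_id = rep(c("cloneA", "cloneB", "cloneC"), each = 2),
    replicate = rep(1:2, 3))
  calls <- validatePairs(list(scores = scores, flags = flags), pm)
  expect_equal(calls$status[match(c("cloneA", "cloneB", "cloneC"),
                                  calls$clone_id)],
               c("positive", "negative", "unevaluable"))
  expect_equal(calls$minScore[calls$clone_id == "cloneA"], 5)

  bad <- rbind(pm, data.frame(x = 2, y = 2, clone_id = "cloneA",
                              replicate = 1))
  expect_error(validatePairs(list(scores = scores, flags = flags), bad),
               "exactly 2")
})

test_that("a regional gain block leaves locality-interior scores intact", {
  # scores are ratios of locality-relative deviations, so a regional
  # multiplicative gain change must cancel away from the block boundary
  set.seed(9)
  lay <- makeLayout(dotsPerSide = 30L)
  sums <- matrix(rgamma(900, 20, 1e-3), 30, 30)
  spikes <- rbind(c(8, 8), c(10, 9), c(22, 22), c(23, 20))
  sums[spikes] <- sums[spikes] + 2e5
  classes <- matrix("valid", 30, 30)
  gained <- sums
  gained[1:15, 1:15] <- gained[1:15, 1:15] * 5   # block covers two spikes
  a <- madScores(sums, classes, lay)
  b <- madScores(gained, classes, lay)
  for (r in seq_len(nrow(spikes))) {
    sa <- a$scores[spikes[r, 1], spikes[r, 2]]
    sb <- b$scores[spikes[r, 1], spikes[r, 2]]
    expect_lt(abs(sb - sa) / sa, 0.10)
  }
})
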