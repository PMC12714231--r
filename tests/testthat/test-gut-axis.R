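test_that("axial position is 0 at the start marker and 1 at the end", {
  fr <- gutFrame(c(10, 20), c(10, 220))
  expect_equal(normalizePosition(c(10, 20), fr), 0)
  expect_equal(normalizePosition(c(10, 220), fr), 1)
  expect_equal(normalizePosition(c(10, 120), fr), 0.5)
  # perpendicular displacement leaves s unchanged
  expect_equal(normalizePosition(c(45, 120), fr), 0.5)
  # beyond the markers clamps
  expect_equal(normalizePosition(c(10, 300), fr), 1)
  expect_equal(normalizePosition(c(10, -5), fr), 0)
  expect_error(gutFrame(c(1, 1), c(1, 1)), "differ")
})

test_that("axial position is invariant under rigid transformations", {
  set.seed(41)
  for (rep in 1:20) {
    start <- runif(2, 0, 100); end <- runif(2, 0, 100)
    pt <- runif(2, 0, 100)
    s0 <- normalizePosition(pt, gutFrame(start, end))
    theta <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    shift <- runif(2, -50, 50)
    s1 <- normalizePosition(as.numeric(R %*% pt + shift),
                            gutFrame(as.numeric(R %*% start + shift),
                                     as.numeric(R %*% end + shift)))
    expect_equal(s1, s0, tolerance = 1e-9)
  }
})

test_that("the x-projection option normalizes by column coordinate", {
  fr <- gutFrame(c(10, 20), c(60, 220))
  expect_equal(normalizePosition(c(99, 120), fr, method = "x"), 0.5)
  expect_error(normalizePosition(c(0, 0), gutFrame(c(0, 5), c(9, 5)),
                                 method = "x"), "column")
})

test_that("bins are half-open with a closed last edge", {
  expect_equal(assignBins(0.26, 4), 2L)
  expect_equal(assignBins(1, 100), 100L)
  expect_equal(assignBins(0, 4), 1L)
  expect_equal(assignBins(0.25, 4), 2L)    # left-closed edges
  expect_error(assignBins(1.2, 4), "outside")
})

test_that("bin counts conserve totals and respect weights", {
  set.seed(42)
  s <- runif(1000)
  expect_equal(sum(binPositions(s, 4)), 1000)
  expect_equal(sum(binPositions(s, 100)), 1000)
  w <- sample(1:3, 1000, TRUE)
  expect_equal(sum(binPositions(s, 4, w)), sum(w))
  expect_equal(binPositions(numeric(0), 4), rep(0L, 4))
})

test_that("density smoothing conserves mass and fixes uniform profiles", {
  spike <- rep(0, 100); spike[50] <- 10
  sm <- smoothDensity(spike)
  expect_equal(sum(sm), 10)
  # symmetric about bin 50
  expect_equal(sm[50 - (1:12)], sm[50 + (1:12)], tolerance = 1e-12)
  uniform <- rep(3, 100)
  expect_equal(smoothDensity(uniform), uniform, tolerance = 1e-9)
  set.seed(43)
  counts <- rpois(100, 4)
  expect_equal(sum(smoothDensity(counts)), sum(counts))
  expect_equal(smoothDensity(rep(0, 100)), rep(0, 100))
})

test_that("excluding a quarter partitions the records", {
  recs <- data.frame(id = 1:10, quarter = c(1, 2, 3, 4, 4, 1, 2, 4, 3, 2))
  kept <- excludeRegion(recs)
  expect_equal(nrow(kept) + sum(recs$quarter == 4), nrow(recs))
  expect_true(all(kept$quarter != 4))
  allQ4 <- data.frame(quarter = rep(4, 3))
  expect_equal(nrow(excludeRegion(allQ4)), 0)
  noQ4 <- data.frame(quarter = c(1, 2, 3))
  expect_identical(excludeRegion(noQ4), noQ4)
})

test_that("quarter and percentile counts both sum to the weighted total", {
  res <- renderImage(makeClusterSpec(seed = 5))
  obj <- detectAll(res)
  fr <- gutFrame(c(128, 0.08 * 256), c(128, 0.92 * 256))
  loc <- localizeCells(obj, fr)
  total <- weightedTotal(obj)
  expect_equal(sum(binPositions(loc$s, 4, loc$weight)), total)
  expect_equal(sum(binPositions(loc$s, 100, loc$weight)), total)
})

test_that("recovered positions match ground truth on a straight gut", {
  spec <- makeSeparatedSpec(n = 30, seed = 6, imageSide = 256L)
  # straight default gut: truth fractions from the cells' own columns
  res <- renderImage(spec)
  fr <- gutFrame(spec@gutStart, spec@gutEnd)
  obj <- detectAll(res)
  loc <- localizeCells(obj, fr)
  chord <- sqrt(sum((spec@gutEnd - spec@gutStart)^2))
  sTrue <- normalizePosition(res$truth[, c("row", "col")], fr)
  # match objects to truth by nearest center
  for (i in seq_len(nrow(loc))) {
    j <- which.min((res$truth$row - loc$row[i])^2 +
                     (res$truth$col - loc$col[i])^2)
    expect_lt(abs(loc$s[i] - sTrue[j]), 2 / chord)
  }
})
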