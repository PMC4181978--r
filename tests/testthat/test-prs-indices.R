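test_that("range increment follows the relative-change formula and sign semantics", {
  spec <- smallSpec(2L, 1L, 1)
  fp <- SuitabilityGrid(spec, matrix(c(1, 1), 1, 2))      # c = 2
  expect_equal(rangeIncrement(fp, fp), 0)
  ff3 <- SuitabilityGrid(smallSpec(3L, 1L, 1), matrix(1, 1, 3))
  # c(fp)=2, c(ff)=3 on a matching 3-cell grid
  fp3 <- SuitabilityGrid(smallSpec(3L, 1L, 1), matrix(c(1, 1, 0), 1, 3))
  expect_equal(rangeIncrement(fp3, ff3), 0.5)
  # contraction: c 2 -> 1 gives -0.5
  ff1 <- SuitabilityGrid(spec, matrix(c(1, 0), 1, 2))
  expect_equal(rangeIncrement(fp, ff1), -0.5)
  empty <- SuitabilityGrid(spec, matrix(0, 1, 2))
  expect_error(rangeIncrement(empty, fp), "degenerate")
})

test_that("range overlap hits its endpoints and the hand-computed Jaccard value", {
  spec <- smallSpec(2L, 1L, 1)
  set.seed(5)
  g <- randomSuitability()
  expect_equal(rangeOverlap(g, g), 1)
  left <- SuitabilityGrid(spec, matrix(c(0.8, 0), 1, 2))
  right <- SuitabilityGrid(spec, matrix(c(0, 0.6), 1, 2))
  expect_equal(rangeOverlap(left, right), 0)
  # hand evaluation: min = {0.5, 0}, max = {1, 0.5} -> 0.5 / 1.5
  fp <- SuitabilityGrid(spec, matrix(c(1, 0), 1, 2))
  ff <- SuitabilityGrid(spec, matrix(c(0.5, 0.5), 1, 2))
  expect_equal(rangeOverlap(fp, ff), 1 / 3)
  # independent cell-by-cell oracle on random pairs
  set.seed(6)
  for (rep in 1:25) {
    a <- randomSuitability()
    b <- randomSuitability()
    va <- gridValues(a); vb <- gridValues(b)
    expect_equal(rangeOverlap(a, b), sum(pmin(va, vb)) / sum(pmax(va, vb)))
  }
  empty <- SuitabilityGrid(spec, matrix(0, 1, 2))
  expect_error(rangeOverlap(empty, empty), "degenerate")
})

test_that("current-normalized overlap variant divides by the current cardinality", {
  spec <- smallSpec(2L, 1L, 1)
  fp <- SuitabilityGrid(spec, matrix(c(1, 0), 1, 2))
  ff <- SuitabilityGrid(spec, matrix(c(0.5, 0.5), 1, 2))
  expect_equal(rangeOverlap(fp, ff, "current_normalized"), 0.5)
  # reaches 1 when the future range covers the current one
  cover <- SuitabilityGrid(spec, matrix(c(1, 1), 1, 2))
  expect_equal(rangeOverlap(fp, cover, "current_normalized"), 1)
  expect_lt(rangeOverlap(fp, cover), 1)
})

test_that("fuzzy centroid is the membership-weighted mean of cell centers", {
  spec <- GridSpec(4L, 3L, 0, 0, 1)
  dem <- flatDem(spec, 500)
  # uniform membership: geometric grid center, flat elevation
  cen <- fuzzyCentroid(SuitabilityGrid(spec, matrix(0.4, 3, 4)), dem)
  expect_equal(cen@cx, 2)
  expect_equal(cen@cy, 1.5)
  expect_equal(cen@cz, 500)
  # point mass: that cell's center and elevation
  v <- matrix(0, 3, 4); v[2, 3] <- 0.7
  z <- matrix(100, 3, 4); z[2, 3] <- 1234
  cen <- fuzzyCentroid(SuitabilityGrid(spec, v), ElevationGrid(spec, z))
  expect_equal(cen@cx, 2.5)
  expect_equal(cen@cy, 1.5)
  expect_equal(cen@cz, 1234)
  # weighted mean: memberships in ratio 1 : 3 at x-centers 0.5 and 4.5
  spec5 <- GridSpec(5L, 1L, 0, 0, 1)
  v <- matrix(c(0.25, 0, 0, 0, 0.75), 1, 5)
  cen <- fuzzyCentroid(SuitabilityGrid(spec5, v), flatDem(spec5, 0))
  expect_equal(cen@cx, 3.5)
  expect_error(
    fuzzyCentroid(SuitabilityGrid(spec, matrix(0, 3, 4)), dem),
    "degenerate")
})

test_that("displacement is a plain coordinate difference and antisymmetric", {
  a <- Centroid3D(100, 30, 1000)
  b <- Centroid3D(99, 32, 1600)
  expect_equal(rangeDisplacement(a, a), c(dx = 0, dy = 0, dz = 0))
  expect_equal(rangeDisplacement(a, b), c(dx = -1, dy = 2, dz = 600))
  expect_equal(rangeDisplacement(b, a), -rangeDisplacement(a, b))
})

test_that("computePRS fields match the independently called single operations", {
  set.seed(7)
  spec <- smallSpec()
  dem <- flatDem(spec)
  for (rep in 1:10) {
    fp <- randomSuitability(spec)
    ff <- randomSuitability(spec)
    idx <- computePRS(fp, ff, dem)
    expect_identical(idx@iIndex, rangeIncrement(fp, ff))
    expect_identical(idx@oIndex, rangeOverlap(fp, ff))
    d <- rangeDisplacement(fuzzyCentroid(fp, dem), fuzzyCentroid(ff, dem))
    expect_identical(idx@dx, d[["dx"]])
    expect_identical(idx@dy, d[["dy"]])
    expect_identical(idx@dz, d[["dz"]])
    expect_identical(idx@cardCurrent, fuzzyCardinality(fp))
    expect_identical(idx@cardFuture, fuzzyCardinality(ff))
  }
})

test_that("identity scenario yields I = 0, O = 1 and zero displacement", {
  set.seed(8)
  spec <- smallSpec()
  g <- randomSuitability(spec)
  idx <- computePRS(g, g, flatDem(spec))
  expect_equal(idx@iIndex, 0)
  expect_equal(idx@oIndex, 1)
  expect_equal(c(idx@dx, idx@dy, idx@dz), c(0, 0, 0))
})

test_that("translating the future grid moves the centroid by whole cells", {
  spec <- GridSpec(12L, 10L, 0, 0, 0.5)
  set.seed(9)
  core <- matrix(runif(5 * 4), 5, 4)
  embed <- function(rowOff, colOff) {
    v <- matrix(0, 10, 12)
    v[rowOff + 1:5, colOff + 1:4] <- core
    SuitabilityGrid(spec, v)
  }
  fp <- embed(2, 2)
  dem <- flatDem(spec)
  for (shift in list(c(2, 0), c(0, 3), c(1, 2))) {
    ff <- embed(2 + shift[1], 2 + shift[2])
    idx <- computePRS(fp, ff, dem)
    expect_equal(idx@dx, shift[2] * 0.5, tolerance = 1e-12)
    expect_equal(idx@dy, shift[1] * 0.5, tolerance = 1e-12)
    expect_equal(idx@dz, 0)
    expect_equal(idx@iIndex, 0, tolerance = 1e-12)
  }
})

test_that("indices are invariant under common membership scaling", {
  set.seed(10)
  spec <- smallSpec()
  dem <- flatDem(spec)
  fp <- randomSuitability(spec)
  ff <- randomSuitability(spec)
  base <- computePRS(fp, ff, dem)
  for (lambda in c(0.2, 0.5, 0.9)) {
    fpS <- SuitabilityGrid(spec, gridValues(fp) * lambda)
    ffS <- SuitabilityGrid(spec, gridValues(ff) * lambda)
    scaled <- computePRS(fpS, ffS, dem)
    expect_equal(scaled@iIndex, base@iIndex, tolerance = 1e-12)
    expect_equal(scaled@oIndex, base@oIndex, tolerance = 1e-12)
    expect_equal(scaled@dx, base@dx, tolerance = 1e-12)
    expect_equal(scaled@dy, base@dy, tolerance = 1e-12)
    expect_equal(scaled@dz, base@dz, tolerance = 1e-12)
  }
})

test_that("crisp binary grids reduce O to classical Jaccard and I to relative area change", {
  set.seed(12)
  spec <- smallSpec(8L, 8L, 0.25)
  for (rep in 1:10) {
    a <- matrix(runif(64) < 0.4, 8, 8)
    b <- matrix(runif(64) < 0.4, 8, 8)
    if (!any(a) || !any(a | b)) next
    ga <- SuitabilityGrid(spec, a * 1)
    gb <- SuitabilityGrid(spec, b * 1)
    expect_equal(rangeOverlap(ga, gb), sum(a & b) / sum(a | b))
    expect_equal(rangeIncrement(ga, gb), (sum(b) - sum(a)) / sum(a))
  }
})

test_that("O and I obey symmetry and sign relations", {
  set.seed(13)
  spec <- smallSpec()
  for (rep in 1:20) {
    a <- randomSuitability(spec)
    b <- randomSuitability(spec)
    expect_equal(rangeOverlap(a, b), rangeOverlap(b, a))
    expect_equal(sign(rangeIncrement(a, b)),
                 sign(fuzzyCardinality(b) - fuzzyCardinality(a)))
  }
})

test_that("vertical displacement composes slope with northward shift", {
  spec <- GridSpec(240L, 180L, 95, 25, 1 / 12)
  slope <- 300
  dem <- makeDEM(spec, "north_slope", base = 400, slope = slope)
  deltaLat <- 1.5
  pair <- makeShiftPair(spec, center = c(105, 30), spread = c(0.6, 0.6),
                        dx = 0, dy = deltaLat, expansion = 1)
  idx <- computePRS(pair$fp, pair$ff, dem)
  expect_equal(idx@dz, slope * deltaLat, tolerance = 1e-6)
})
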