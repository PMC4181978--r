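mkIdx <- function(i = 0, o = 0.5, dx = 0, dy = 0, dz = 0, cc = 100,
                  cf = NULL) {
  if (is.null(cf)) cf <- cc * (1 + i)
  PRSIndices(i, o, dx, dy, dz, cc, cf)
}

test_that("arrow scaling matches the logarithmic anchors", {
  # a 10-degree movement is drawn 2 units long
  expect_equal(chartGeometry(mkIdx(dx = 10))@hArrowLength, 2)
  # a 1-degree movement is drawn 1 unit long
  expect_equal(chartGeometry(mkIdx(dy = 1))@hArrowLength, 1)
  # 100 m of vertical movement is one unit; 1000 m is two
  expect_equal(chartGeometry(mkIdx(dz = 100))@vArrowLength, 1)
  g <- chartGeometry(mkIdx(dz = 1000))
  expect_equal(g@vArrowLength, 2)
  expect_equal(g@vArrowSign, "up")
  expect_equal(chartGeometry(mkIdx(dz = -1000))@vArrowSign, "down")
})

test_that("sub-unit movements collapse to omitted zero-length arrows", {
  g <- chartGeometry(mkIdx(dx = 0.05, dz = 5))
  expect_equal(g@hArrowLength, 0)
  expect_equal(g@vArrowLength, 0)
  expect_equal(g@vArrowSign, "none")
})

test_that("horizontal arrow length is monotone in distance and 1 at one degree", {
  d <- c(0.2, 0.5, 1, 2, 5, 10, 20)
  len <- vapply(d, function(x) chartGeometry(mkIdx(dx = x))@hArrowLength,
                numeric(1))
  expect_true(all(diff(len) > 0))
  expect_equal(len[d == 1], 1)
})

test_that("sector area fraction equals O and circle areas track cardinalities", {
  for (o in c(0, 0.1, 0.25, 0.5, 0.99, 1)) {
    g <- chartGeometry(mkIdx(o = o))
    expect_equal(g@sectorAngle / (2 * pi), o, tolerance = 1e-12)
  }
  expect_equal(chartGeometry(mkIdx(o = 0.25))@sectorAngle, pi / 2)
  for (ratio in c(0.25, 1, 2, 4)) {
    g <- chartGeometry(mkIdx(cc = 100, cf = 100 * ratio))
    # drawn area ratio = radius^2 = cardinality ratio
    expect_equal(g@futureRadius^2, ratio, tolerance = 1e-12)
  }
  expect_equal(chartGeometry(mkIdx(cc = 100, cf = 400))@futureRadius, 2)
  # literal radius-proportional mode preserved behind the flag
  expect_equal(chartGeometry(mkIdx(cc = 100, cf = 400),
                             radiusMode = "radius")@futureRadius, 4)
})

test_that("chart geometry is a pure function of the index record", {
  idx <- mkIdx(i = 0.3, o = 0.4, dx = 1.2, dy = -0.7, dz = 320)
  g1 <- chartGeometry(idx)
  g2 <- chartGeometry(mkIdx(i = 0.3, o = 0.4, dx = 1.2, dy = -0.7,
                            dz = 320))
  expect_identical(g1, g2)
})

test_that("fixed geometry renders byte-identical SVG across runs", {
  idx <- mkIdx(i = 0.2, o = 0.35, dx = 2, dy = 1.5, dz = 500)
  geom <- chartGeometry(idx)
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  renderChart(geom, f1)
  renderChart(geom, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  svg <- readLines(f1)
  # draw order: sector path before the circles, circles before arrows
  expect_lt(grep("<path", svg)[1], grep("<circle", svg)[1])
  unlink(c(f1, f2))
})

test_that("identity indices render coincident circles, full disc and no arrows", {
  geom <- chartGeometry(mkIdx(i = 0, o = 1))
  f <- tempfile(fileext = ".svg")
  renderChart(geom, f)
  svg <- paste(readLines(f), collapse = "\n")
  expect_false(grepl("<line", svg))     # no arrows drawn
  expect_false(grepl("<path", svg))     # full disc drawn as a circle fill
  expect_equal(geom@futureRadius, 1)
  unlink(f)
})

test_that("unwritable chart paths error and png output is produced", {
  geom <- chartGeometry(mkIdx(dx = 1))
  expect_error(renderChart(geom, "/nonexistent-dir-xyz/c.svg"),
               "directory")
  f <- tempfile(fileext = ".png")
  renderChart(geom, f)
  expect_gt(file.size(f), 0)
  unlink(f)
})

test_that("panel rendering lays out species x scenario grids and checks keys", {
  recs <- list(); sp <- character(); sc <- character()
  for (s in c("sp1", "sp2")) for (z in c("A1B", "A2", "B1")) {
    recs[[length(recs) + 1L]] <- mkIdx(o = runif(1), dx = runif(1, 0, 3))
    sp <- c(sp, s); sc <- c(sc, z)
  }
  f <- tempfile(fileext = ".svg")
  renderPanel(recs, sp, sc, f)
  svg <- paste(readLines(f), collapse = "\n")
  # 2 x 3 panel: 12 circles (two per chart) plus labeled rows/columns
  expect_equal(lengths(regmatches(svg, gregexpr("<circle", svg))), 12)
  expect_true(grepl(">A1B<", svg) && grepl(">sp2<", svg))
  unlink(f)
  # single record renders a labeled 1 x 1 panel
  f1 <- tempfile(fileext = ".svg")
  renderPanel(recs[1], "solo", "A1B", f1)
  expect_gt(file.size(f1), 0)
  unlink(f1)
  # inconsistent scenario sets across species are an error
  expect_error(renderPanel(recs[1:5], sp[1:5], sc[1:5], f),
               "inconsistent scenario set")
})
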