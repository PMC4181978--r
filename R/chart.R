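#' @include prs-indices.R
NULL

#' Resolve PRS_Chart drawing geometry from an index record
#'
#' Translates the five indices into drawing primitives. The current range is
#' a unit circle. The future range is a concentric circle whose DRAWN AREA is
#' proportional to the cardinality ratio, i.e.
#' `futureRadius = sqrt(cardFuture / cardCurrent)` under the default
#' `radiusMode = "area"` (with `"radius"` the radius itself equals the
#' ratio). The overlap index O becomes a sector of the unit circle with area
#' fraction O. Horizontal movement of magnitude `d` degrees is drawn as an
#' arrow of length `1 + log10(d)` chart units — so 1 degree maps to 1 unit
#' and 10 degrees to 2 units — pointing in the actual movement direction;
#' vertical movement is an up/down arrow of `1 + log10(|Dz| / 100)` units,
#' one unit representing 100 m. Movements of at most 0.1 degree
#' (horizontal) or 10 m (vertical) get zero length and are omitted from the
#' rendering.
#'
#' @param idx a [PRSIndices-class].
#' @param radiusMode `"area"` (default; drawn area proportional to the
#'   cardinality ratio) or `"radius"` (radius proportional).
#' @return A [ChartGeometry-class].
#' @examples
#' idx <- PRSIndices(iIndex = 0, oIndex = 0.25, dx = 10, dy = 0, dz = 1000,
#'                   cardCurrent = 100, cardFuture = 100)
#' g <- chartGeometry(idx)
#' g@hArrowLength   # 2: a 10-degree movement is drawn 2 units long
#' g@vArrowLength   # 2: 1000 m at 100 m per unit on the log scale
#' @export
setMethod("chartGeometry", "PRSIndices",
  function(idx, radiusMode = c("area", "radius")) {
    radiusMode <- match.arg(radiusMode)
    ratio <- idx@cardFuture / idx@cardCurrent
    futureRadius <- if (radiusMode == "area") sqrt(ratio) else ratio
    d <- sqrt(idx@dx^2 + idx@dy^2)
    hLen <- if (d <= 0.1) 0 else 1 + log10(d)
    hDir <- if (d == 0) 0 else atan2(idx@dy, idx@dx)
    vLen <- if (abs(idx@dz) <= 10) 0 else 1 + log10(abs(idx@dz) / 100)
    vSign <- if (vLen == 0) "none" else if (idx@dz > 0) "up" else "down"
    new("ChartGeometry",
        currentRadius = 1, futureRadius = futureRadius,
        sectorFraction = idx@oIndex, sectorAngle = 2 * pi * idx@oIndex,
        hArrowDirection = hDir, hArrowLength = hLen,
        vArrowSign = vSign, vArrowLength = vLen)
  })

setMethod("show", "ChartGeometry", function(object) {
  cat("PRS_Chart geometry\n")
  cat(sprintf("  circles: current r = 1, future r = %.4f\n",
              object@futureRadius))
  cat(sprintf("  overlap sector: %.4f of the unit disc (%.4f rad)\n",
              object@sectorFraction, object@sectorAngle))
  cat(sprintf("  horizontal arrow: length %.4f, direction %.4f rad\n",
              object@hArrowLength, object@hArrowDirection))
  cat(sprintf("  vertical arrow: %s, length %.4f\n", object@vArrowSign,
              object@vArrowLength))
})

.chartStyle <- function(style = list()) {
  default <- list(
    currentColor = "#000000", currentWidth = 1,
    futureColor = "#1f4fd8", futureWidth = 3, futureDash = "8,6",
    sectorColor = "#d82020", sectorOpacity = 0.85,
    hArrowColor = "#1f4fd8", vArrowColor = "#000000",
    arrowWidth = 2, unitPx = 40, marginPx = 14
  )
  utils::modifyList(default, style)
}

.fmt <- function(x) sprintf("%.4f", x)

# One chart as a vector of SVG element strings, centered at (cx, cy),
# `unit` pixels per chart unit. Draw order: sector, current circle, future
# circle, arrows; zero-length arrows are omitted.
.chartElements <- function(geom, cx, cy, unit, st) {
  el <- character()
  r <- unit  # unit circle radius in px
  if (geom@sectorFraction >= 1 - 1e-12) {
    el <- c(el, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="%s" stroke="none"/>',
      .fmt(cx), .fmt(cy), .fmt(r), st$sectorColor, .fmt(st$sectorOpacity)))
  } else if (geom@sectorFraction > 1e-12) {
    # sector starts at 12 o'clock, sweeps clockwise (screen y points down)
    ang <- geom@sectorAngle
    x0 <- cx; y0 <- cy - r
    x1 <- cx + r * sin(ang); y1 <- cy - r * cos(ang)
    largeArc <- if (ang > pi) 1L else 0L
    el <- c(el, sprintf(
      '<path d="M %s %s L %s %s A %s %s 0 %d 1 %s %s Z" fill="%s" fill-opacity="%s" stroke="none"/>',
      .fmt(cx), .fmt(cy), .fmt(x0), .fmt(y0), .fmt(r), .fmt(r), largeArc,
      .fmt(x1), .fmt(y1), st$sectorColor, .fmt(st$sectorOpacity)))
  }
  el <- c(el, sprintf(
    '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="%s" stroke-width="%s"/>',
    .fmt(cx), .fmt(cy), .fmt(r), st$currentColor, .fmt(st$currentWidth)))
  el <- c(el, sprintf(
    '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="%s" stroke-width="%s" stroke-dasharray="%s"/>',
    .fmt(cx), .fmt(cy), .fmt(geom@futureRadius * unit), st$futureColor,
    .fmt(st$futureWidth), st$futureDash))
  if (geom@hArrowLength > 0) {
    x1 <- cx + geom@hArrowLength * unit * cos(geom@hArrowDirection)
    y1 <- cy - geom@hArrowLength * unit * sin(geom@hArrowDirection)
    el <- c(el, .svgArrow(cx, cy, x1, y1, st$hArrowColor, st$arrowWidth))
  }
  if (geom@vArrowLength > 0) {
    sgn <- if (geom@vArrowSign == "up") -1 else 1
    y1 <- cy + sgn * geom@vArrowLength * unit
    el <- c(el, .svgArrow(cx, cy, cx, y1, st$vArrowColor, st$arrowWidth))
  }
  el
}

.svgArrow <- function(x0, y0, x1, y1, color, width) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  ux <- (x1 - x0) / len; uy <- (y1 - y0) / len
  hs <- min(9, len / 3)  # arrowhead size in px
  bx <- x1 - hs * ux; by <- y1 - hs * uy
  px <- -uy; py <- ux
  c(sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
      .fmt(x0), .fmt(y0), .fmt(bx), .fmt(by), color, .fmt(width)),
    sprintf(
      '<polygon points="%s,%s %s,%s %s,%s" fill="%s" stroke="none"/>',
      .fmt(x1), .fmt(y1),
      .fmt(bx + hs * 0.5 * px), .fmt(by + hs * 0.5 * py),
      .fmt(bx - hs * 0.5 * px), .fmt(by - hs * 0.5 * py), color))
}

.chartExtentUnits <- function(geom) {
  max(1, geom@futureRadius, geom@hArrowLength, geom@vArrowLength) + 0.15
}

# deterministic standalone SVG document for one chart
.chartSVG <- function(geom, style = list()) {
  st <- .chartStyle(style)
  ext <- .chartExtentUnits(geom)
  half <- ext * st$unitPx + st$marginPx
  side <- 2 * half
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            .fmt(side), .fmt(side), .fmt(side), .fmt(side)),
    '<rect width="100%" height="100%" fill="#ffffff"/>',
    .chartElements(geom, half, half, st$unitPx, st),
    '</svg>')
}

.drawChartBase <- function(geom, st, label = NULL) {
  ext <- .chartExtentUnits(geom)
  graphics::plot.new()
  graphics::plot.window(xlim = c(-ext, ext), ylim = c(-ext, ext), asp = 1)
  th <- seq(0, 2 * pi, length.out = 256)
  if (geom@sectorFraction > 1e-12) {
    a <- seq(pi / 2, pi / 2 - geom@sectorAngle,
             length.out = max(8, ceiling(128 * geom@sectorFraction)))
    graphics::polygon(c(0, cos(a)), c(0, sin(a)), col = st$sectorColor,
                      border = NA)
  }
  graphics::lines(cos(th), sin(th), col = st$currentColor,
                  lwd = st$currentWidth)
  graphics::lines(geom@futureRadius * cos(th), geom@futureRadius * sin(th),
                  col = st$futureColor, lwd = st$futureWidth, lty = 2)
  if (geom@hArrowLength > 0)
    graphics::arrows(0, 0, geom@hArrowLength * cos(geom@hArrowDirection),
                     geom@hArrowLength * sin(geom@hArrowDirection),
                     col = st$hArrowColor, lwd = st$arrowWidth,
                     length = 0.08)
  if (geom@vArrowLength > 0)
    graphics::arrows(0, 0, 0,
                     ifelse(geom@vArrowSign == "up", 1, -1) *
                       geom@vArrowLength,
                     col = st$vArrowColor, lwd = st$arrowWidth,
                     length = 0.08)
  if (!is.null(label)) graphics::title(main = label, cex.main = 0.9)
}

#' Render one PRS_Chart to an image file
#'
#' Draws the chart described by a [ChartGeometry-class]: overlap sector
#' first, then the current (thin solid black) and future (broad dashed blue)
#' circles, then the horizontal (blue) and vertical (black) displacement
#' arrows. Zero-length arrows are omitted rather than drawn as dots. The
#' output format follows the file extension: `.svg` (written by the
#' package's deterministic SVG emitter — identical geometry yields
#' byte-identical files), `.png`, or `.pdf`.
#'
#' @param geom a [ChartGeometry-class].
#' @param outPath output file path ending in `.svg`, `.png` or `.pdf`.
#' @param style named list overriding colors, line widths, `unitPx` (pixels
#'   per chart unit) or `marginPx`.
#' @return Invisibly, `outPath`.
#' @examples
#' idx <- PRSIndices(0.2, 0.4, dx = 1.5, dy = 0.8, dz = 250,
#'                   cardCurrent = 100, cardFuture = 120)
#' out <- file.path(tempdir(), "chart.svg")
#' renderChart(chartGeometry(idx), out)
#' @export
renderChart <- function(geom, outPath, style = list()) {
  ext <- tolower(tools::file_ext(outPath))
  dir <- dirname(outPath)
  if (!dir.exists(dir))
    stop("cannot write chart: directory does not exist: ", dir,
         call. = FALSE)
  st <- .chartStyle(style)
  if (ext == "svg") {
    con <- file(outPath, open = "wb")
    on.exit(close(con))
    writeLines(.chartSVG(geom, style), con, sep = "\n")
  } else if (ext %in% c("png", "pdf")) {
    if (ext == "png") grDevices::png(outPath, width = 480, height = 480)
    else grDevices::pdf(outPath, width = 5, height = 5)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(1, 1, 1, 1))
    .drawChartBase(geom, st)
  } else {
    stop("unsupported chart format: .", ext, call. = FALSE)
  }
  invisible(outPath)
}

#' Render a species x scenario panel of PRS_Charts
#'
#' Draws one chart per (species, scenario) combination in a grid with
#' species as rows (order preserved as given, no re-sorting) and scenarios
#' as columns, with row and column labels — the tabular layout used to
#' compare range-shift projections across a genus.
#'
#' @param records list of [PRSIndices-class] objects.
#' @param species character vector parallel to `records`.
#' @param scenarios character vector parallel to `records`.
#' @param outPath output file ending in `.svg`, `.png` or `.pdf`.
#' @param style see [renderChart()].
#' @return Invisibly, `outPath`.
#' @export
renderPanel <- function(records, species, scenarios, outPath,
                        style = list()) {
  if (length(records) == 0L) stop("empty record table", call. = FALSE)
  if (length(species) != length(records) ||
      length(scenarios) != length(records))
    stop("species and scenarios must parallel records", call. = FALSE)
  spOrder <- unique(species)
  scOrder <- unique(scenarios)
  key <- paste(species, scenarios, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate species x scenario combination", call. = FALSE)
  for (sp in spOrder) {
    have <- sort(scenarios[species == sp])
    if (!identical(have, sort(scOrder)))
      stop("inconsistent scenario set for species '", sp, "'",
           call. = FALSE)
  }
  st <- .chartStyle(style)
  geoms <- lapply(records, chartGeometry)
  lookup <- function(sp, sc) geoms[[which(species == sp & scenarios == sc)]]
  ext <- tolower(tools::file_ext(outPath))
  nR <- length(spOrder); nC <- length(scOrder)
  if (ext == "svg") {
    cellPx <- 2 * (1.2 * st$unitPx + st$marginPx)
    labelPx <- 26
    wide <- labelPx + nC * cellPx
    high <- labelPx + nR * cellPx
    lines <- c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
      .fmt(wide), .fmt(high), .fmt(wide), .fmt(high)),
      '<rect width="100%" height="100%" fill="#ffffff"/>')
    for (jc in seq_len(nC))
      lines <- c(lines, sprintf(
        '<text x="%s" y="%s" text-anchor="middle" font-size="12" font-family="sans-serif">%s</text>',
        .fmt(labelPx + (jc - 0.5) * cellPx), .fmt(labelPx * 0.7),
        scOrder[jc]))
    for (ir in seq_len(nR))
      lines <- c(lines, sprintf(
        '<text x="%s" y="%s" text-anchor="middle" font-size="12" font-family="sans-serif" transform="rotate(-90 %s %s)">%s</text>',
        .fmt(labelPx * 0.7), .fmt(labelPx + (ir - 0.5) * cellPx),
        .fmt(labelPx * 0.7), .fmt(labelPx + (ir - 0.5) * cellPx),
        spOrder[ir]))
    for (ir in seq_len(nR)) for (jc in seq_len(nC)) {
      g <- lookup(spOrder[ir], scOrder[jc])
      sc <- st
      sc$unitPx <- st$unitPx * 1.2 / .chartExtentUnits(g)
      lines <- c(lines, .chartElements(
        g, labelPx + (jc - 0.5) * cellPx, labelPx + (ir - 0.5) * cellPx,
        sc$unitPx, sc))
    }
    lines <- c(lines, '</svg>')
    con <- file(outPath, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  } else if (ext %in% c("png", "pdf")) {
    if (ext == "png")
      grDevices::png(outPath, width = 220 * nC, height = 220 * nR)
    else grDevices::pdf(outPath, width = 2.2 * nC, height = 2.2 * nR)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(nR, nC), mar = c(0.5, 0.5, 1.5, 0.5))
    for (sp in spOrder) for (sc in scOrder)
      .drawChartBase(lookup(sp, sc), st, label = paste(sp, sc))
  } else {
    stop("unsupported chart format: .", ext, call. = FALSE)
  }
  invisible(outPath)
}
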