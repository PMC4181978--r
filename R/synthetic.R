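#' @include grid-core.R
NULL

#' Generate a synthetic digital elevation model
#'
#' Deterministic DEM surfaces for virtual-species experiments:
#' * `"flat"` — constant elevation `base`;
#' * `"north_slope"` — `base + slope * (lat - yOrigin)`, a plane rising
#'   northward at `slope` meters per degree of latitude;
#' * `"ridge"` — a Gaussian ridge `base + height * exp(-(lon - axisLon)^2 /
#'   (2 * width^2))` running south-north along `axisLon`.
#'
#' @param spec a [GridSpec-class].
#' @param kind `"flat"`, `"north_slope"` or `"ridge"`.
#' @param base base elevation in meters (default 500).
#' @param slope slope in meters per degree of latitude (north_slope).
#' @param axisLon ridge axis longitude in degrees (ridge).
#' @param height ridge height in meters (ridge).
#' @param width ridge Gaussian width in degrees (ridge).
#' @return An [ElevationGrid-class].
#' @examples
#' spec <- GridSpec(12L, 24L, 100, 30, 1 / 12)
#' dem <- makeDEM(spec, "north_slope", base = 400, slope = 300)
#' @export
makeDEM <- function(spec, kind = c("flat", "north_slope", "ridge"),
                    base = 500, slope = 300, axisLon = NULL, height = 1000,
                    width = 0.5) {
  kind <- match.arg(kind)
  xs <- xCoords(spec)
  ys <- yCoords(spec)
  v <- switch(kind,
    flat = matrix(base, spec@nRows, spec@nCols),
    north_slope = matrix(base + slope * (ys - spec@yOrigin),
                         spec@nRows, spec@nCols),
    ridge = {
      if (is.null(axisLon))
        axisLon <- spec@xOrigin + spec@nCols * spec@cellSize / 2
      row <- base + height * exp(-(xs - axisLon)^2 / (2 * width^2))
      matrix(row, spec@nRows, spec@nCols, byrow = TRUE)
    })
  ElevationGrid(spec, v)
}

#' Generate a virtual-species suitability surface
#'
#' A smooth unimodal (anisotropic Gaussian) membership surface standing in
#' for a distribution model's logistic output:
#' `mu(x, y) = peak * exp(-((x - cx)^2 / (2 sx^2) + (y - cy)^2 / (2 sy^2)))`
#' evaluated at cell centers. Its continuum fuzzy cardinality
#' (`peak * 2 * pi * sx * sy / cellSize^2` cells) and centroid (`center` on
#' a flat DEM) have closed forms, giving analytic ground truth for recovery
#' experiments. The construction is fully deterministic in its parameters.
#'
#' @param spec a [GridSpec-class].
#' @param center numeric length-2, `(lon, lat)` of the suitability peak.
#' @param spread numeric length-2, Gaussian sigmas `(sx, sy)` in degrees.
#' @param peak maximum membership, in `(0, 1]` (default 1).
#' @return A [SuitabilityGrid-class].
#' @examples
#' spec <- GridSpec(120L, 120L, 95, 25, 1 / 12)
#' g <- makeVirtualSuitability(spec, center = c(100, 30),
#'                             spread = c(0.6, 0.6))
#' @export
makeVirtualSuitability <- function(spec, center, spread, peak = 1) {
  if (any(spread <= 0)) stop("spread must be positive", call. = FALSE)
  if (peak <= 0 || peak > 1)
    stop("peak must lie in (0, 1]", call. = FALSE)
  xs <- xCoords(spec)
  ys <- yCoords(spec)
  gx <- exp(-(xs - center[1L])^2 / (2 * spread[1L]^2))
  gy <- exp(-(ys - center[2L])^2 / (2 * spread[2L]^2))
  SuitabilityGrid(spec, peak * outer(gy, gx))
}

#' Generate a current/future pair with known range-shift truth
#'
#' Builds a virtual species under the current climate as a Gaussian surface
#' at `center`, and its future counterpart translated by `(dx, dy)` degrees
#' with both sigmas scaled by `sqrt(expansion)` at equal peak, so the future
#' fuzzy cardinality is `expansion` times the current one. The returned
#' `truth` records the analytic continuum expectations the index pipeline
#' should recover: `I = expansion - 1`, `Dx = dx`, `Dy = dy` (and `Dz =
#' slope * dy` on a uniformly sloped DEM). Truncation by the grid boundary
#' is guarded: if either surface loses more than 0.1% of its continuum
#' cardinality off-grid, generation fails rather than silently biasing the
#' truth.
#'
#' @param spec a [GridSpec-class].
#' @param center,spread,peak base-surface parameters, as in
#'   [makeVirtualSuitability()].
#' @param dx,dy imposed centroid shift in degrees.
#' @param expansion future/current cardinality ratio (> 0); 1 = no area
#'   change.
#' @return List with elements `fp`, `ff` ([SuitabilityGrid-class]) and
#'   `truth` (list `iIndex`, `dx`, `dy`).
#' @examples
#' spec <- GridSpec(240L, 180L, 95, 25, 1 / 12)
#' pair <- makeShiftPair(spec, center = c(102, 31), spread = c(0.7, 0.7),
#'                       dx = 2, dy = 0, expansion = 1)
#' pair$truth$dx
#' @export
makeShiftPair <- function(spec, center, spread, dx = 0, dy = 0,
                          expansion = 1, peak = 1) {
  if (expansion <= 0) stop("expansion must be positive", call. = FALSE)
  fp <- makeVirtualSuitability(spec, center, spread, peak)
  spreadF <- spread * sqrt(expansion)
  ff <- makeVirtualSuitability(spec, center + c(dx, dy), spreadF, peak)
  cellArea <- spec@cellSize^2
  contP <- peak * 2 * pi * spread[1L] * spread[2L] / cellArea
  contF <- peak * 2 * pi * spreadF[1L] * spreadF[2L] / cellArea
  lossP <- 1 - fuzzyCardinality(fp) / contP
  lossF <- 1 - fuzzyCardinality(ff) / contF
  if (abs(lossP) > 0.001 || abs(lossF) > 0.001)
    stop("virtual-species support leaks off the grid (cardinality loss ",
         sprintf("%.3g%% / %.3g%%", 100 * lossP, 100 * lossF),
         "); enlarge the grid or shrink the spread", call. = FALSE)
  list(fp = fp, ff = ff,
       truth = list(iIndex = expansion - 1, dx = dx, dy = dy))
}

#' Generate a presence/absence evaluation sample
#'
#' Draws suitability scores for `nPres` presences and `nAbs` absences from
#' two Beta(2, 2)-shaped distributions rescaled so that the class means
#' differ by exactly `separation`: absences on `[0, 1 - separation]`,
#' presences on `[separation, 1]`. For `separation > 0.5` the supports are
#' disjoint and AUC is exactly 1; `separation = 0` makes the classes
#' exchangeable (AUC 0.5 in expectation). Deterministic per `seed`.
#'
#' @param nPres,nAbs class sizes, each `>= 1`.
#' @param separation difference of class means, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return List with `labels` (logical, presences first) and `scores`
#'   (numeric in `[0, 1]`).
#' @examples
#' s <- makeEvalSample(30, 30, separation = 0.6, seed = 7)
#' aucScore(s$labels, s$scores)  # 1: disjoint score supports
#' @export
makeEvalSample <- function(nPres, nAbs, separation, seed) {
  if (nPres < 1L || nAbs < 1L) stop("need nPres, nAbs >= 1", call. = FALSE)
  if (separation < 0 || separation > 1)
    stop("separation must lie in [0, 1]", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  w <- 1 - separation
  pres <- separation + w * stats::rbeta(nPres, 2, 2)
  abs_ <- w * stats::rbeta(nAbs, 2, 2)
  list(labels = rep(c(TRUE, FALSE), c(nPres, nAbs)),
       scores = c(pres, abs_))
}

#' Growing-season aridity from monthly climate
#'
#' Aridity is the natural logarithm of the ratio of total potential
#' evapotranspiration to total precipitation over the growing season, the
#' growing season being the months whose mean temperature is strictly above
#' 0 degrees C. Positive values indicate evaporative demand exceeding
#' precipitation. PET is an input; no evapotranspiration model is fitted
#' here.
#'
#' @param temp numeric length 12, monthly mean temperatures (degrees C).
#' @param precip numeric length 12, monthly precipitation totals (mm),
#'   `>= 0`.
#' @param pet numeric length 12, monthly potential evapotranspiration totals
#'   (mm), `>= 0`.
#' @return A single number, `log(sum(pet) / sum(precip))` over growing
#'   months.
#' @examples
#' growingSeasonAridity(temp = rep(10, 12), precip = rep(50, 12),
#'                      pet = rep(100, 12))  # log(2)
#' @export
growingSeasonAridity <- function(temp, precip, pet) {
  if (length(temp) != 12L || length(precip) != 12L || length(pet) != 12L)
    stop("temp, precip and pet must each have 12 monthly values",
         call. = FALSE)
  if (any(precip < 0) || any(pet < 0))
    stop("precip and pet must be non-negative", call. = FALSE)
  growing <- temp > 0
  if (!any(growing))
    stop("no growing season: no month has temperature above 0 C",
         call. = FALSE)
  totalP <- sum(precip[growing])
  if (totalP <= 0)
    stop("zero growing-season precipitation: aridity undefined",
         call. = FALSE)
  log(sum(pet[growing]) / totalP)
}
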