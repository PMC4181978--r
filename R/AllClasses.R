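#' @import methods
NULL

#' Grid geometry specification
#'
#' Describes the geometry of a regular geographic raster with square cells:
#' dimensions, the coordinates of the south-west corner (the outer edge, not a
#' cell center), the cell size in decimal degrees, and the NoData sentinel used
#' by file dialects. Throughout the package, cell `(i, j)` (column `i` counted
#' from the west, row `j` counted from the south, both 1-based) has its center
#' at `(xOrigin + (i - 0.5) * cellSize, yOrigin + (j - 0.5) * cellSize)`.
#'
#' @slot nCols integer, number of columns (west to east).
#' @slot nRows integer, number of rows (south to north).
#' @slot xOrigin numeric, longitude of the west edge in decimal degrees.
#' @slot yOrigin numeric, latitude of the south edge in decimal degrees.
#' @slot cellSize numeric, cell edge length in decimal degrees (square cells).
#' @slot nodata numeric, sentinel value written for NoData cells in ESRI
#'   ASCII files.
#'
#' @examples
#' GridSpec(nCols = 10L, nRows = 8L, xOrigin = 100, yOrigin = 30,
#'          cellSize = 1 / 12)
#' @name GridSpec-class
#' @aliases GridSpec-class
#' @exportClass GridSpec
setClass("GridSpec",
  representation(
    nCols = "integer",
    nRows = "integer",
    xOrigin = "numeric",
    yOrigin = "numeric",
    cellSize = "numeric",
    nodata = "numeric"
  ),
  prototype(nodata = -9999)
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single integer >= 1")
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single integer >= 1")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@xOrigin) != 1L || !is.finite(object@xOrigin))
    msg <- c(msg, "xOrigin must be a single finite number")
  if (length(object@yOrigin) != 1L || !is.finite(object@yOrigin))
    msg <- c(msg, "yOrigin must be a single finite number")
  if (length(object@nodata) != 1L || !is.finite(object@nodata))
    msg <- c(msg, "nodata must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @param nCols,nRows grid dimensions (coerced to integer).
#' @param xOrigin,yOrigin coordinates of the south-west grid corner (degrees).
#' @param cellSize cell edge length in degrees.
#' @param nodata NoData sentinel for file output.
#' @return `GridSpec()` returns a validated [GridSpec-class] object.
#' @rdname GridSpec-class
#' @export
GridSpec <- function(nCols, nRows, xOrigin, yOrigin, cellSize,
                     nodata = -9999) {
  new("GridSpec", nCols = as.integer(nCols), nRows = as.integer(nRows),
      xOrigin = as.numeric(xOrigin), yOrigin = as.numeric(yOrigin),
      cellSize = as.numeric(cellSize), nodata = as.numeric(nodata))
}

#' Virtual parent of gridded raster layers
#'
#' Shared representation of a georeferenced single-band raster: a
#' [GridSpec-class], a numeric value matrix, and a logical NoData mask. The
#' value matrix is stored with row 1 at the SOUTH edge and column 1 at the
#' west edge, so `values[j, i]` is the cell whose center is
#' `(xOrigin + (i - 0.5) * cellSize, yOrigin + (j - 0.5) * cellSize)`.
#' Masked (NoData) cells take part in no sum, centroid, or consensus.
#'
#' @slot spec a [GridSpec-class].
#' @slot values numeric matrix, `nRows x nCols`, south-up row order.
#' @slot mask logical matrix of the same shape; `TRUE` marks NoData.
#' @name GeoGrid-class
#' @aliases GeoGrid-class
#' @exportClass GeoGrid
setClass("GeoGrid",
  representation(spec = "GridSpec", values = "matrix", mask = "matrix",
                 "VIRTUAL"))

setValidity("GeoGrid", function(object) {
  s <- object@spec
  msg <- character()
  if (!identical(dim(object@values), c(s@nRows, s@nCols)))
    msg <- c(msg, sprintf("values must be a %d x %d matrix", s@nRows, s@nCols))
  if (!identical(dim(object@mask), dim(object@values)))
    msg <- c(msg, "mask must have the same dimensions as values")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (anyNA(object@mask))
    msg <- c(msg, "mask must not contain NA")
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be numeric")
  else if (any(!is.finite(object@values[!object@mask])))
    msg <- c(msg, "unmasked values must be finite")
  if (length(msg)) msg else TRUE
})

#' Fuzzy habitat-suitability raster
#'
#' A georeferenced raster of fuzzy memberships in `[0, 1]`: the concrete form
#' of a fuzzy range set. Each unmasked cell value is the degree to which the
#' cell belongs to the species' potential range, conventionally set equal to
#' the logistic output of the underlying distribution model.
#'
#' @slot spec,values,mask see [GeoGrid-class].
#' @seealso [fuzzyCardinality()], [fuzzyIntersection()], [computePRS()]
#' @examples
#' spec <- GridSpec(2L, 2L, 0, 0, 1)
#' g <- SuitabilityGrid(spec, matrix(c(0.2, 0.3, 0.5, 1), 2, 2))
#' fuzzyCardinality(g)
#' @name SuitabilityGrid-class
#' @aliases SuitabilityGrid-class
#' @exportClass SuitabilityGrid
setClass("SuitabilityGrid", contains = "GeoGrid")

setValidity("SuitabilityGrid", function(object) {
  v <- object@values[!object@mask]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    "unmasked membership values must lie in [0, 1]"
  else TRUE
})

#' Digital elevation raster
#'
#' Cell elevations in meters above sea level on the same grid geometry as the
#' suitability maps it is paired with. Supplies the vertical coordinate of the
#' membership-weighted range centroid.
#'
#' @slot spec,values,mask see [GeoGrid-class].
#' @name ElevationGrid-class
#' @aliases ElevationGrid-class
#' @exportClass ElevationGrid
setClass("ElevationGrid", contains = "GeoGrid")

.makeGrid <- function(class, spec, values, mask) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) {
    mask <- is.na(values)
  } else {
    mask <- as.matrix(mask) | is.na(values)
  }
  values[mask] <- 0
  new(class, spec = spec, values = values, mask = mask)
}

#' @param spec a [GridSpec-class].
#' @param values numeric matrix (`nRows x nCols`, row 1 = south edge); `NA`
#'   entries are masked.
#' @param mask optional logical matrix; `TRUE` marks NoData. Merged with the
#'   `NA` pattern of `values`.
#' @return `SuitabilityGrid()` returns a validated [SuitabilityGrid-class].
#' @rdname SuitabilityGrid-class
#' @export
SuitabilityGrid <- function(spec, values, mask = NULL) {
  .makeGrid("SuitabilityGrid", spec, values, mask)
}

#' @param spec,values,mask as for `SuitabilityGrid()`.
#' @return `ElevationGrid()` returns a validated [ElevationGrid-class].
#' @rdname ElevationGrid-class
#' @export
ElevationGrid <- function(spec, values, mask = NULL) {
  .makeGrid("ElevationGrid", spec, values, mask)
}

#' Membership-weighted 3-D range centroid
#'
#' The range center of a fuzzy range set: longitude and latitude in decimal
#' degrees and elevation in meters a.s.l., each a membership-weighted mean
#' over unmasked cells.
#'
#' @slot cx numeric, longitude (degrees).
#' @slot cy numeric, latitude (degrees).
#' @slot cz numeric, elevation (meters a.s.l.).
#' @seealso [fuzzyCentroid()]
#' @name Centroid3D-class
#' @aliases Centroid3D-class
#' @exportClass Centroid3D
setClass("Centroid3D",
  representation(cx = "numeric", cy = "numeric", cz = "numeric"))

setValidity("Centroid3D", function(object) {
  if (any(lengths(list(object@cx, object@cy, object@cz)) != 1L) ||
      !all(is.finite(c(object@cx, object@cy, object@cz))))
    "cx, cy, cz must each be a single finite number"
  else TRUE
})

#' @param cx,cy,cz centroid coordinates (degrees, degrees, meters).
#' @return `Centroid3D()` returns a [Centroid3D-class] object.
#' @rdname Centroid3D-class
#' @export
Centroid3D <- function(cx, cy, cz) {
  new("Centroid3D", cx = as.numeric(cx), cy = as.numeric(cy),
      cz = as.numeric(cz))
}

#' The five-index potential range shift record
#'
#' Holds the F-PRS index set for one current/future suitability pair: range
#' increment `I`, range overlap `O`, centroid displacements `Dx`, `Dy`
#' (degrees) and `Dz` (meters), plus the two fuzzy cardinalities they derive
#' from and the overlap normalization convention that produced `O`.
#'
#' @slot iIndex numeric, relative change in fuzzy range area; `>= -1`
#'   (negative = contraction, positive = expansion).
#' @slot oIndex numeric in `[0, 1]`; 0 = disjoint ranges, 1 = congruent.
#' @slot dx,dy numeric, east- and northward centroid displacement (degrees).
#' @slot dz numeric, vertical centroid displacement (meters).
#' @slot cardCurrent,cardFuture numeric, fuzzy cardinalities of the two
#'   range sets.
#' @slot overlapConvention `"jaccard"` or `"current_normalized"`.
#' @seealso [computePRS()], [chartGeometry()]
#' @name PRSIndices-class
#' @aliases PRSIndices-class
#' @exportClass PRSIndices
setClass("PRSIndices",
  representation(
    iIndex = "numeric", oIndex = "numeric",
    dx = "numeric", dy = "numeric", dz = "numeric",
    cardCurrent = "numeric", cardFuture = "numeric",
    overlapConvention = "character"
  ),
  prototype(overlapConvention = "jaccard")
)

setValidity("PRSIndices", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!all(vapply(list(object@iIndex, object@oIndex, object@dx, object@dy,
                       object@dz, object@cardCurrent, object@cardFuture),
                  num1, logical(1))))
    msg <- c(msg, "all index fields must be single finite numbers")
  else {
    if (object@oIndex < -1e-12 || object@oIndex > 1 + 1e-12)
      msg <- c(msg, "oIndex must lie in [0, 1]")
    if (object@iIndex < -1 - 1e-12)
      msg <- c(msg, "iIndex must be >= -1")
    if (object@cardCurrent < 0 || object@cardFuture < 0)
      msg <- c(msg, "cardinalities must be non-negative")
  }
  if (!object@overlapConvention %in% c("jaccard", "current_normalized"))
    msg <- c(msg, "overlapConvention must be 'jaccard' or 'current_normalized'")
  if (length(msg)) msg else TRUE
})

#' @param iIndex,oIndex,dx,dy,dz,cardCurrent,cardFuture index values; see the
#'   slot documentation.
#' @param overlapConvention which overlap normalization produced `oIndex`.
#' @return `PRSIndices()` returns a validated [PRSIndices-class] object.
#' @rdname PRSIndices-class
#' @export
PRSIndices <- function(iIndex, oIndex, dx, dy, dz, cardCurrent, cardFuture,
                       overlapConvention = "jaccard") {
  new("PRSIndices", iIndex = as.numeric(iIndex), oIndex = as.numeric(oIndex),
      dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz),
      cardCurrent = as.numeric(cardCurrent),
      cardFuture = as.numeric(cardFuture),
      overlapConvention = overlapConvention)
}

#' Ensemble of member suitability maps
#'
#' An ordered stack of mutually aligned suitability grids, one per
#' GCM x predictor-set combination, to be reduced to a consensus map by the
#' cell-wise median.
#'
#' @slot members list of [SuitabilityGrid-class] objects, all aligned.
#' @slot labels data.frame with columns `gcm` and `predictorSet`, one row per
#'   member; rows unique.
#' @seealso [consensusMedian()], [buildEnsembleIndex()]
#' @name EnsembleStack-class
#' @aliases EnsembleStack-class
#' @exportClass EnsembleStack
setClass("EnsembleStack",
  representation(members = "list", labels = "data.frame"))

setValidity("EnsembleStack", function(object) {
  msg <- character()
  n <- length(object@members)
  if (n < 1L)
    msg <- c(msg, "an ensemble needs at least one member")
  if (!all(vapply(object@members, is, logical(1), "SuitabilityGrid")))
    msg <- c(msg, "all members must be SuitabilityGrid objects")
  if (!all(c("gcm", "predictorSet") %in% names(object@labels)))
    msg <- c(msg, "labels must have columns 'gcm' and 'predictorSet'")
  else {
    if (nrow(object@labels) != n)
      msg <- c(msg, "labels must have one row per member")
    key <- paste(object@labels$gcm, object@labels$predictorSet, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "member labels must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' @param members list of aligned [SuitabilityGrid-class] objects.
#' @param labels data.frame with columns `gcm`, `predictorSet` (unique rows),
#'   or `NULL` to auto-number members.
#' @return `EnsembleStack()` returns a validated [EnsembleStack-class];
#'   member alignment is checked pairwise against the first member.
#' @rdname EnsembleStack-class
#' @export
EnsembleStack <- function(members, labels = NULL) {
  if (is.null(labels)) {
    labels <- data.frame(gcm = sprintf("m%02d", seq_along(members)),
                         predictorSet = "ps1",
                         stringsAsFactors = FALSE)
  }
  if (length(members) > 1L)
    for (k in seq_along(members)[-1L])
      assertAligned(members[[1L]], members[[k]])
  new("EnsembleStack", members = members, labels = labels)
}

#' Model-evaluation metrics with threshold curves
#'
#' AUC plus the maxima of Cohen's kappa and the true skill statistic over the
#' 19-point threshold grid `0.05, 0.10, ..., 0.95`, together with the full
#' per-threshold curve.
#'
#' @slot auc numeric in `[0, 1]`, rank-based (Mann-Whitney) AUC.
#' @slot maxKappa numeric in `[-1, 1]`.
#' @slot maxTSS numeric in `[-1, 1]`.
#' @slot curve data.frame with columns `threshold`, `kappa`, `tss`.
#' @seealso [maxOverThresholds()]
#' @name EvalMetrics-class
#' @aliases EvalMetrics-class
#' @exportClass EvalMetrics
setClass("EvalMetrics",
  representation(auc = "numeric", maxKappa = "numeric", maxTSS = "numeric",
                 curve = "data.frame"))

setValidity("EvalMetrics", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (!all(c("threshold", "kappa", "tss") %in% names(object@curve)))
    msg <- c(msg, "curve needs columns threshold, kappa, tss")
  else {
    if (abs(object@maxKappa - max(object@curve$kappa)) > 1e-12)
      msg <- c(msg, "maxKappa must equal the curve maximum")
    if (abs(object@maxTSS - max(object@curve$tss)) > 1e-12)
      msg <- c(msg, "maxTSS must equal the curve maximum")
  }
  if (length(msg)) msg else TRUE
})

#' Resolved PRS_Chart drawing geometry
#'
#' The drawing primitives of one potential-range-shift chart: the unit circle
#' for the current range, a concentric circle for the future range, a sector
#' whose area fraction equals the overlap index, and log-scaled horizontal and
#' vertical displacement arrows.
#'
#' @slot currentRadius numeric, always 1 (chart units).
#' @slot futureRadius numeric `>= 0`.
#' @slot sectorFraction numeric in `[0, 1]`, the overlap index.
#' @slot sectorAngle numeric, `2 * pi * sectorFraction` (radians).
#' @slot hArrowDirection numeric, radians counter-clockwise from east.
#' @slot hArrowLength numeric `>= 0`, chart units.
#' @slot vArrowSign `"up"`, `"down"`, or `"none"`.
#' @slot vArrowLength numeric `>= 0`, chart units.
#' @seealso [chartGeometry()], [renderChart()]
#' @name ChartGeometry-class
#' @aliases ChartGeometry-class
#' @exportClass ChartGeometry
setClass("ChartGeometry",
  representation(
    currentRadius = "numeric", futureRadius = "numeric",
    sectorFraction = "numeric", sectorAngle = "numeric",
    hArrowDirection = "numeric", hArrowLength = "numeric",
    vArrowSign = "character", vArrowLength = "numeric"
  ))

setValidity("ChartGeometry", function(object) {
  msg <- character()
  if (object@currentRadius != 1)
    msg <- c(msg, "currentRadius is fixed at 1")
  if (object@futureRadius < 0)
    msg <- c(msg, "futureRadius must be >= 0")
  if (object@sectorFraction < 0 || object@sectorFraction > 1)
    msg <- c(msg, "sectorFraction must lie in [0, 1]")
  if (abs(object@sectorAngle - 2 * pi * object@sectorFraction) > 1e-12)
    msg <- c(msg, "sectorAngle must equal 2*pi*sectorFraction")
  if (object@hArrowLength < 0 || object@vArrowLength < 0)
    msg <- c(msg, "arrow lengths must be >= 0")
  if (!object@vArrowSign %in% c("up", "down", "none"))
    msg <- c(msg, "vArrowSign must be 'up', 'down' or 'none'")
  if (length(msg)) msg else TRUE
})

#' A sample of index values for group statistics
#'
#' One value per species for a single index, genus (or pooled family) and
#' climate scenario; the unit on which the significance protocol operates.
#'
#' @slot values numeric vector, finite, one entry per species.
#' @slot groupLabel character, genus name or `"family"`.
#' @slot scenarioLabel character, climate-scenario identifier.
#' @slot indexName one of `"I"`, `"O"`, `"Dx"`, `"Dy"`, `"Dz"`.
#' @seealso [summarizeSample()], [tVsZero()], [anovaScenarios()]
#' @name IndexSample-class
#' @aliases IndexSample-class
#' @exportClass IndexSample
setClass("IndexSample",
  representation(values = "numeric", groupLabel = "character",
                 scenarioLabel = "character", indexName = "character"))

setValidity("IndexSample", function(object) {
  msg <- character()
  if (length(object@values) < 1L || any(!is.finite(object@values)))
    msg <- c(msg, "values must be a non-empty finite numeric vector")
  if (!object@indexName %in% c("I", "O", "Dx", "Dy", "Dz"))
    msg <- c(msg, "indexName must be one of I, O, Dx, Dy, Dz")
  if (length(msg)) msg else TRUE
})

#' @param values numeric vector of per-species index values.
#' @param groupLabel genus name or `"family"`.
#' @param scenarioLabel climate-scenario identifier.
#' @param indexName one of `"I"`, `"O"`, `"Dx"`, `"Dy"`, `"Dz"`.
#' @return `IndexSample()` returns a validated [IndexSample-class].
#' @rdname IndexSample-class
#' @export
IndexSample <- function(values, groupLabel = "family",
                        scenarioLabel = "scenario", indexName = "I") {
  new("IndexSample", values = as.numeric(values), groupLabel = groupLabel,
      scenarioLabel = scenarioLabel, indexName = indexName)
}
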