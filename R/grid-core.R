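#' @include AllGenerics.R
NULL

#' Accessors for gridded raster layers
#'
#' `gridSpec()`, `gridValues()` and `gridMask()` return the geometry, the
#' value matrix (south-up row order) and the NoData mask of a grid.
#' `cellSize()` returns the cell edge length in degrees; `xCoords()` and
#' `yCoords()` return the cell-center longitudes (one per column) and
#' latitudes (one per row).
#'
#' @param x a [SuitabilityGrid-class] or [ElevationGrid-class].
#' @return See the individual descriptions.
#' @examples
#' spec <- GridSpec(3L, 2L, 100, 30, 0.5)
#' g <- SuitabilityGrid(spec, matrix(0.5, 2, 3))
#' xCoords(g)   # 100.25 100.75 101.25
#' yCoords(g)   # 30.25 30.75
#' @name grid-accessors
#' @aliases gridSpec gridValues gridMask cellSize xCoords yCoords
NULL

#' @rdname grid-accessors
#' @export
setMethod("gridSpec", "GeoGrid", function(x) x@spec)

#' @rdname grid-accessors
#' @export
setMethod("gridValues", "GeoGrid", function(x) {
  v <- x@values
  v[x@mask] <- NA_real_
  v
})

#' @rdname grid-accessors
#' @export
setMethod("gridMask", "GeoGrid", function(x) x@mask)

#' @rdname grid-accessors
#' @export
setMethod("cellSize", "GridSpec", function(x) x@cellSize)

#' @rdname grid-accessors
#' @export
setMethod("cellSize", "GeoGrid", function(x) x@spec@cellSize)

#' @rdname grid-accessors
#' @export
setMethod("xCoords", "GridSpec", function(x)
  x@xOrigin + (seq_len(x@nCols) - 0.5) * x@cellSize)

#' @rdname grid-accessors
#' @export
setMethod("xCoords", "GeoGrid", function(x) xCoords(x@spec))

#' @rdname grid-accessors
#' @export
setMethod("yCoords", "GridSpec", function(x)
  x@yOrigin + (seq_len(x@nRows) - 0.5) * x@cellSize)

#' @rdname grid-accessors
#' @export
setMethod("yCoords", "GeoGrid", function(x) yCoords(x@spec))

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d cols x %d rows, cell %.6g deg, SW corner (%.6g, %.6g)\n",
              object@nCols, object@nRows, object@cellSize,
              object@xOrigin, object@yOrigin))
})

setMethod("show", "GeoGrid", function(object) {
  v <- object@values[!object@mask]
  cat(sprintf("%s: %d x %d cells (%d masked)\n", class(object),
              object@spec@nRows, object@spec@nCols, sum(object@mask)))
  cat(sprintf("  extent: lon [%.6g, %.6g], lat [%.6g, %.6g], cell %.6g deg\n",
              object@spec@xOrigin,
              object@spec@xOrigin + object@spec@nCols * object@spec@cellSize,
              object@spec@yOrigin,
              object@spec@yOrigin + object@spec@nRows * object@spec@cellSize,
              object@spec@cellSize))
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], mean %.4g\n",
                min(v), max(v), mean(v)))
})

#' Assert that two grids share geometry and mask
#'
#' Verifies that two raster layers are defined on the identical grid: same
#' dimensions, same origin and cell size (compared within 1e-9 degrees), and
#' the same NoData mask. Every multi-grid operation in the package requires
#' pre-aligned inputs; no reprojection or resampling is attempted.
#'
#' @param a,b [SuitabilityGrid-class] or [ElevationGrid-class] objects.
#' @return Invisibly `TRUE` when aligned; otherwise an error naming the first
#'   differing field (`nCols`, `nRows`, `xOrigin`, `yOrigin`, `cellSize`,
#'   `mask`).
#' @examples
#' spec <- GridSpec(2L, 2L, 0, 0, 1)
#' g1 <- SuitabilityGrid(spec, matrix(0.5, 2, 2))
#' g2 <- SuitabilityGrid(spec, matrix(0.9, 2, 2))
#' assertAligned(g1, g2)
#' @export
assertAligned <- function(a, b) {
  sa <- a@spec; sb <- b@spec
  if (sa@nCols != sb@nCols)
    stop("grids are not aligned: nCols differ (", sa@nCols, " vs ",
         sb@nCols, ")", call. = FALSE)
  if (sa@nRows != sb@nRows)
    stop("grids are not aligned: nRows differ (", sa@nRows, " vs ",
         sb@nRows, ")", call. = FALSE)
  tol <- 1e-9
  if (abs(sa@xOrigin - sb@xOrigin) > tol)
    stop("grids are not aligned: xOrigin differs", call. = FALSE)
  if (abs(sa@yOrigin - sb@yOrigin) > tol)
    stop("grids are not aligned: yOrigin differs", call. = FALSE)
  if (abs(sa@cellSize - sb@cellSize) > tol)
    stop("grids are not aligned: cellSize differs (", sa@cellSize, " vs ",
         sb@cellSize, ")", call. = FALSE)
  if (!identical(a@mask, b@mask))
    stop("grids are not aligned: mask differs", call. = FALSE)
  invisible(TRUE)
}

#' Fuzzy cardinality of a suitability grid
#'
#' The fuzzy-set analogue of range area: the sum of all unmasked membership
#' values. For a binary (crisp) map this reduces to the occupied cell count.
#' An optional `cos(latitude)` area weighting is available for callers who
#' want latitude-corrected areas; the default, used throughout the index
#' pipeline, is the plain unweighted sum.
#'
#' @param g a [SuitabilityGrid-class].
#' @param areaWeighted logical; if `TRUE`, each cell's membership is weighted
#'   by the cosine of its center latitude. Default `FALSE`.
#' @return A single non-negative number.
#' @examples
#' spec <- GridSpec(2L, 2L, 0, 0, 1)
#' fuzzyCardinality(SuitabilityGrid(spec, matrix(c(0.2, 0.3, 0.5, 1), 2, 2)))
#' @export
setMethod("fuzzyCardinality", "SuitabilityGrid",
  function(g, areaWeighted = FALSE) {
    v <- g@values
    v[g@mask] <- 0
    if (areaWeighted) {
      w <- cos(yCoords(g) * pi / 180)
      v <- v * w  # recycles down columns: rows share a latitude
    }
    sum(v)
  })

.binaryFuzzyOp <- function(a, b, op) {
  assertAligned(a, b)
  mask <- a@mask | b@mask
  v <- op(a@values, b@values)
  v[mask] <- 0
  new("SuitabilityGrid", spec = a@spec, values = v, mask = mask)
}

#' Fuzzy intersection and union of aligned suitability grids
#'
#' The standard (Zadeh) fuzzy-set operators: intersection is the cell-wise
#' minimum of memberships, union the cell-wise maximum. The output mask is
#' the union of the input masks. These satisfy the exact identity
#' `c(min(a,b)) + c(max(a,b)) = c(a) + c(b)` and reduce to set intersection
#' and union on binary maps.
#'
#' @param a,b aligned [SuitabilityGrid-class] objects.
#' @return A [SuitabilityGrid-class] on the shared grid.
#' @examples
#' spec <- GridSpec(2L, 1L, 0, 0, 1)
#' a <- SuitabilityGrid(spec, matrix(c(1, 0), 1, 2))
#' b <- SuitabilityGrid(spec, matrix(c(0.5, 0.5), 1, 2))
#' gridValues(fuzzyIntersection(a, b))  # 0.5 0
#' gridValues(fuzzyUnion(a, b))         # 1.0 0.5
#' @name fuzzy-ops
NULL

#' @rdname fuzzy-ops
#' @export
setMethod("fuzzyIntersection", signature("SuitabilityGrid", "SuitabilityGrid"),
  function(a, b) .binaryFuzzyOp(a, b, pmin))

#' @rdname fuzzy-ops
#' @export
setMethod("fuzzyUnion", signature("SuitabilityGrid", "SuitabilityGrid"),
  function(a, b) .binaryFuzzyOp(a, b, pmax))
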