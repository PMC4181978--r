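#' @include grid-core.R
NULL

#' Range increment index I
#'
#' Relative change in fuzzy range area between the current and future
#' potential range: `I = (c(Ff) - c(Fp)) / c(Fp)`, where `c` is the fuzzy
#' cardinality. A negative value indicates range contraction and a positive
#' value range expansion; `I = 0` means unchanged total area (though not
#' necessarily unchanged location).
#'
#' @param fp current-climate [SuitabilityGrid-class] (fuzzy set F_p).
#' @param ff future-climate [SuitabilityGrid-class] (fuzzy set F_f).
#' @return A single number `>= -1`.
#' @examples
#' spec <- GridSpec(2L, 1L, 0, 0, 1)
#' fp <- SuitabilityGrid(spec, matrix(c(1, 1), 1, 2))
#' ff <- SuitabilityGrid(spec, matrix(c(1, 0), 1, 2))
#' rangeIncrement(fp, ff)  # -0.5: contraction
#' @export
rangeIncrement <- function(fp, ff) {
  assertAligned(fp, ff)
  cp <- fuzzyCardinality(fp)
  if (cp <= 0)
    stop("degenerate current range: fuzzy cardinality of fp is zero",
         call. = FALSE)
  (fuzzyCardinality(ff) - cp) / cp
}

#' Range overlap index O
#'
#' Fuzzy overlap between the current and future potential range. Under the
#' default `"jaccard"` convention,
#' `O = c(intersection) / c(union)` with the Zadeh min/max operators: 0 means
#' the two ranges are disjoint, 1 that they are completely congruent. The
#' `"current_normalized"` convention instead divides the intersection
#' cardinality by the current-range cardinality `c(Fp)`; it reaches 1
#' whenever the future range covers the current one and is not symmetric.
#'
#' @param fp,ff aligned [SuitabilityGrid-class] objects (current, future).
#' @param convention `"jaccard"` (default) or `"current_normalized"`.
#' @return A single number in `[0, 1]`.
#' @examples
#' spec <- GridSpec(2L, 1L, 0, 0, 1)
#' fp <- SuitabilityGrid(spec, matrix(c(1, 0), 1, 2))
#' ff <- SuitabilityGrid(spec, matrix(c(0.5, 0.5), 1, 2))
#' rangeOverlap(fp, ff)  # 0.5 / 1.5 = 1/3
#' @export
rangeOverlap <- function(fp, ff, convention = c("jaccard",
                                                "current_normalized")) {
  convention <- match.arg(convention)
  assertAligned(fp, ff)
  cI <- fuzzyCardinality(fuzzyIntersection(fp, ff))
  if (convention == "jaccard") {
    cU <- fuzzyCardinality(fuzzyUnion(fp, ff))
    if (cU <= 0)
      stop("degenerate ranges: both cardinalities are zero", call. = FALSE)
    cI / cU
  } else {
    cp <- fuzzyCardinality(fp)
    if (cp <= 0)
      stop("degenerate current range: fuzzy cardinality of fp is zero",
           call. = FALSE)
    cI / cp
  }
}

#' Membership-weighted 3-D range centroid
#'
#' The fuzzy range center: every unmasked cell contributes its center
#' longitude, center latitude and DEM elevation, weighted by its membership.
#' `Cx = sum(mu * X) / sum(mu)` and likewise for `Cy` (latitude) and `Cz`
#' (elevation). Cells with zero membership contribute nothing; no
#' threshold-based presence/absence partition is involved.
#'
#' @param g a [SuitabilityGrid-class] with positive fuzzy cardinality.
#' @param dem an [ElevationGrid-class] aligned with `g`.
#' @return A [Centroid3D-class] (degrees, degrees, meters).
#' @examples
#' spec <- GridSpec(4L, 3L, 0, 0, 1)
#' g <- SuitabilityGrid(spec, matrix(0.6, 3, 4))
#' dem <- ElevationGrid(spec, matrix(500, 3, 4))
#' fuzzyCentroid(g, dem)  # grid center (2, 1.5), 500 m
#' @export
setMethod("fuzzyCentroid", signature("SuitabilityGrid", "ElevationGrid"),
  function(g, dem) {
    assertAligned(g, dem)
    w <- g@values
    w[g@mask] <- 0
    total <- sum(w)
    if (total <= 0)
      stop("degenerate range: fuzzy cardinality is zero, centroid undefined",
           call. = FALSE)
    xs <- xCoords(g)
    ys <- yCoords(g)
    # column sums weight longitudes, row sums weight latitudes
    cx <- sum(colSums(w) * xs) / total
    cy <- sum(rowSums(w) * ys) / total
    z <- dem@values
    cz <- sum(w * z) / total
    Centroid3D(cx, cy, cz)
  })

#' Displacement between two range centroids
#'
#' Component-wise difference `end - start`: `Dx` (east positive) and `Dy`
#' (north positive) in decimal degrees, `Dz` in meters. No great-circle or
#' cos-latitude correction is applied; the indices are plain coordinate
#' differences, matching their angular-degree units.
#'
#' @param cStart,cEnd [Centroid3D-class] objects for the start (current) and
#'   end (future) period.
#' @return Named numeric vector `c(dx, dy, dz)`.
#' @examples
#' rangeDisplacement(Centroid3D(100, 30, 1000), Centroid3D(99, 32, 1600))
#' # dx = -1, dy = 2, dz = 600
#' @export
rangeDisplacement <- function(cStart, cEnd) {
  c(dx = cEnd@cx - cStart@cx,
    dy = cEnd@cy - cStart@cy,
    dz = cEnd@cz - cStart@cz)
}

#' Compute the full F-PRS index set
#'
#' One-call evaluation of the five potential-range-shift indices for a
#' current/future suitability pair over a shared DEM: range increment `I`,
#' range overlap `O`, and the centroid displacements `Dx`, `Dy`, `Dz`. Each
#' field equals the corresponding single-operation result exactly. Both
#' periods' centroids use the SAME elevation model; vertical movement `Dz`
#' therefore expresses a shift of the weighted range center across the
#' terrain, not a change of the terrain itself.
#'
#' @param fp,ff aligned current/future [SuitabilityGrid-class] objects, each
#'   with positive fuzzy cardinality.
#' @param dem an [ElevationGrid-class] aligned with both.
#' @param overlapConvention passed to [rangeOverlap()].
#' @return A [PRSIndices-class] record.
#' @examples
#' spec <- GridSpec(40L, 40L, 95, 25, 0.25)
#' dem <- makeDEM(spec, "flat", base = 500)
#' pair <- makeShiftPair(spec, center = c(99, 29), spread = c(0.8, 0.8),
#'                       dx = 2, dy = 0, expansion = 1)
#' computePRS(pair$fp, pair$ff, dem)
#' @export
computePRS <- function(fp, ff, dem,
                       overlapConvention = c("jaccard",
                                             "current_normalized")) {
  overlapConvention <- match.arg(overlapConvention)
  assertAligned(fp, ff)
  assertAligned(fp, dem)
  cp <- fuzzyCardinality(fp)
  cf <- fuzzyCardinality(ff)
  if (cp <= 0 || cf <= 0)
    stop("degenerate range: both periods need positive fuzzy cardinality",
         call. = FALSE)
  d <- rangeDisplacement(fuzzyCentroid(fp, dem), fuzzyCentroid(ff, dem))
  PRSIndices(
    iIndex = rangeIncrement(fp, ff),
    oIndex = rangeOverlap(fp, ff, overlapConvention),
    dx = d[["dx"]], dy = d[["dy"]], dz = d[["dz"]],
    cardCurrent = cp, cardFuture = cf,
    overlapConvention = overlapConvention
  )
}

setMethod("show", "PRSIndices", function(object) {
  cat("F-PRS indices (overlap convention: ", object@overlapConvention, ")\n",
      sep = "")
  cat(sprintf("  I  = %+.4f  (%s)\n", object@iIndex,
              if (object@iIndex < 0) "contraction"
              else if (object@iIndex > 0) "expansion" else "no area change"))
  cat(sprintf("  O  = %.4f\n", object@oIndex))
  cat(sprintf("  Dx = %+.4f deg, Dy = %+.4f deg, Dz = %+.1f m\n",
              object@dx, object@dy, object@dz))
  cat(sprintf("  cardinalities: current %.4g, future %.4g\n",
              object@cardCurrent, object@cardFuture))
})

setMethod("show", "Centroid3D", function(object) {
  cat(sprintf("Centroid3D: lon %.4f deg, lat %.4f deg, %.1f m a.s.l.\n",
              object@cx, object@cy, object@cz))
})
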