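#' @include AllClasses.R
NULL

#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))

#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @export
setGeneric("xCoords", function(x) standardGeneric("xCoords"))

#' @export
setGeneric("yCoords", function(x) standardGeneric("yCoords"))

#' @export
setGeneric("fuzzyCardinality",
           function(g, areaWeighted = FALSE) standardGeneric("fuzzyCardinality"))

#' @export
setGeneric("fuzzyIntersection",
           function(a, b) standardGeneric("fuzzyIntersection"))

#' @export
setGeneric("fuzzyUnion", function(a, b) standardGeneric("fuzzyUnion"))

#' @export
setGeneric("fuzzyCentroid", function(g, dem) standardGeneric("fuzzyCentroid"))

#' @export
setGeneric("consensusMedian",
           function(stack) standardGeneric("consensusMedian"))

#' @export
setGeneric("chartGeometry", function(idx, radiusMode = c("area", "radius"))
  standardGeneric("chartGeometry"))
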