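#' @include grid-core.R
NULL

#' Enumerate the GCM x predictor-set ensemble design
#'
#' Full Cartesian product of circulation-model and predictor-set identifiers,
#' GCM outer and predictor set inner (row-major). With five GCMs and five
#' predictor sets this yields the 25 member models of the standard ensemble
#' design.
#'
#' @param gcmIds character vector of unique GCM identifiers.
#' @param predictorSetIds character vector of unique predictor-set
#'   identifiers.
#' @return data.frame with columns `gcm` and `predictorSet`, one row per
#'   member model.
#' @examples
#' nrow(buildEnsembleIndex(paste0("gcm", 1:5), paste0("ps", 1:5)))  # 25
#' @export
buildEnsembleIndex <- function(gcmIds, predictorSetIds) {
  if (length(gcmIds) < 1L || length(predictorSetIds) < 1L)
    stop("both identifier lists must be non-empty", call. = FALSE)
  if (anyDuplicated(gcmIds))
    stop("duplicate GCM identifier: ",
         gcmIds[duplicated(gcmIds)][1L], call. = FALSE)
  if (anyDuplicated(predictorSetIds))
    stop("duplicate predictor-set identifier: ",
         predictorSetIds[duplicated(predictorSetIds)][1L], call. = FALSE)
  data.frame(
    gcm = rep(gcmIds, each = length(predictorSetIds)),
    predictorSet = rep(predictorSetIds, times = length(gcmIds)),
    stringsAsFactors = FALSE
  )
}

#' Cell-wise median consensus of an ensemble
#'
#' Reduces a stack of member suitability maps to the consensus prediction by
#' taking, in every cell, the median of the member values. A cell masked in
#' any member is masked in the consensus. For an even member count the
#' median is the mean of the two central order statistics.
#'
#' @param stack an [EnsembleStack-class].
#' @return A [SuitabilityGrid-class] on the members' shared grid.
#' @examples
#' spec <- GridSpec(1L, 1L, 0, 0, 1)
#' members <- lapply(c(0.2, 0.4, 0.9), function(v)
#'   SuitabilityGrid(spec, matrix(v, 1, 1)))
#' gridValues(consensusMedian(EnsembleStack(members)))  # 0.4
#' @export
setMethod("consensusMedian", "EnsembleStack", function(stack) {
  members <- stack@members
  if (length(members) == 0L)
    stop("empty ensemble stack", call. = FALSE)
  spec <- members[[1L]]@spec
  mask <- Reduce(`|`, lapply(members, function(m) m@mask))
  arr <- vapply(members, function(m) m@values,
                matrix(0, spec@nRows, spec@nCols))
  dim(arr) <- c(spec@nRows * spec@nCols, length(members))
  med <- apply(arr, 1L, stats::median)
  v <- matrix(med, spec@nRows, spec@nCols)
  v[mask] <- 0
  new("SuitabilityGrid", spec = spec, values = v, mask = mask)
})

setMethod("show", "EnsembleStack", function(object) {
  cat(sprintf("EnsembleStack: %d member suitability maps\n",
              length(object@members)))
  cat(sprintf("  GCMs: %s\n",
              paste(unique(object@labels$gcm), collapse = ", ")))
  cat(sprintf("  predictor sets: %s\n",
              paste(unique(object@labels$predictorSet), collapse = ", ")))
  if (length(object@members)) show(object@members[[1L]]@spec)
})
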