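# Shared fixture builders. All randomness is drawn inside the calling
# test's set.seed() scope.

smallSpec <- function(nCols = 6L, nRows = 5L, cellSize = 0.5,
                      x0 = 100, y0 = 30) {
  GridSpec(nCols, nRows, x0, y0, cellSize)
}

randomSuitability <- function(spec = smallSpec(), maskFrac = 0) {
  v <- matrix(runif(spec@nRows * spec@nCols), spec@nRows, spec@nCols)
  mask <- matrix(runif(length(v)) < maskFrac, spec@nRows, spec@nCols)
  SuitabilityGrid(spec, v, mask)
}

flatDem <- function(spec, elevation = 500) {
  ElevationGrid(spec, matrix(elevation, spec@nRows, spec@nCols))
}

# independent brute-force AUC: count concordant presence-absence pairs,
# ties worth one half
pairCountAUC <- function(labels, scores) {
  pres <- scores[labels]
  abs_ <- scores[!labels]
  total <- 0
  for (p in pres) for (a in abs_)
    total <- total + if (p > a) 1 else if (p == a) 0.5 else 0
  total / (length(pres) * length(abs_))
}

# independent one-way ANOVA from explicit sums of squares
ssqAnovaF <- function(groups) {
  all_ <- unlist(groups)
  grand <- mean(all_)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_) - length(groups)
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, p = pf(Fv, dfb, dfw, lower.tail = FALSE))
}
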