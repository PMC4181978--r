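#' @include AllClasses.R
NULL

#' Group-level summary of an index sample
#'
#' @slot mean numeric, sample mean.
#' @slot sd numeric, sample standard deviation (n - 1 denominator); `NA` for
#'   a single observation.
#' @slot n integer, sample size.
#' @slot sigClass `"ns"`, `"*"` (p < 0.05), `"**"` (p < 0.01), or `NA` when
#'   no test against zero was run.
#' @seealso [summarizeSample()], [tVsZero()]
#' @name GroupSummary-class
#' @aliases GroupSummary-class
#' @exportClass GroupSummary
setClass("GroupSummary",
  representation(mean = "numeric", sd = "numeric", n = "integer",
                 sigClass = "character"),
  prototype(sigClass = NA_character_))

#' Scenario-to-scenario comparison result
#'
#' ANOVA across climate scenarios with (gated) LSD-t pairwise comparisons
#' and a compact letter display: scenarios sharing a letter do not differ
#' significantly at the pairwise alpha level.
#'
#' @slot anovaF,anovaP one-way ANOVA F statistic and p-value.
#' @slot performed logical; `FALSE` when the ANOVA gate blocked the pairwise
#'   tests (reported as "/" in tabular output).
#' @slot pairwise data.frame with columns `groupA`, `groupB`, `t`, `p`.
#' @slot letters named character vector, one letter string per scenario.
#' @seealso [anovaScenarios()], [lsdT()]
#' @name ScenarioComparison-class
#' @aliases ScenarioComparison-class
#' @exportClass ScenarioComparison
setClass("ScenarioComparison",
  representation(anovaF = "numeric", anovaP = "numeric",
                 performed = "logical", pairwise = "data.frame",
                 letters = "character"))

.sigClass <- function(p) {
  if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Mean, standard deviation and size of an index sample
#'
#' Summarizes the per-species index values of one genus (or the pooled
#' family) under one scenario. The standard deviation uses the `n - 1`
#' denominator and is `NA` for a single observation. When `testZero = TRUE`
#' the summary also carries the significance class of a two-sided one-sample
#' t test against zero (`**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise).
#'
#' @param sample an [IndexSample-class].
#' @param testZero logical; run [tVsZero()] and fill `sigClass`.
#' @return A [GroupSummary-class].
#' @examples
#' summarizeSample(IndexSample(c(1, 2, 3)))
#' @export
summarizeSample <- function(sample, testZero = FALSE) {
  v <- sample@values
  if (length(v) < 1L) stop("empty sample", call. = FALSE)
  s <- if (length(v) >= 2L) stats::sd(v) else NA_real_
  sig <- NA_character_
  if (testZero) sig <- tVsZero(sample)[["sigClass"]]
  new("GroupSummary", mean = mean(v), sd = s, n = length(v), sigClass = sig)
}

#' One-sample two-sided t test against zero
#'
#' Tests whether the mean of an index sample differs from zero, the
#' no-range-shift null: `t = mean / (sd / sqrt(n))` on `n - 1` degrees of
#' freedom, two-sided. Applied to I, Dx, Dy and Dz samples (an overlap O
#' sample is bounded in `[0, 1]` and is not tested against zero in the
#' standard protocol).
#'
#' @param sample an [IndexSample-class] with `n >= 2` and positive variance.
#' @return List with elements `t`, `df`, `p`, and `sigClass` (`"**"` if
#'   p < 0.01, `"*"` if p < 0.05, `"ns"` otherwise).
#' @examples
#' tVsZero(IndexSample(c(2.1, 1.9, 2.0, 2.2, 1.8)))
#' @export
tVsZero <- function(sample) {
  v <- sample@values
  n <- length(v)
  if (n < 2L) stop("t test needs n >= 2", call. = FALSE)
  s <- stats::sd(v)
  if (s <= 0)
    stop("zero variance: t statistic undefined", call. = FALSE)
  tStat <- mean(v) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tStat), df = n - 1)
  list(t = tStat, df = n - 1L, p = p, sigClass = .sigClass(p))
}

.checkGroups <- function(groups) {
  if (length(groups) < 2L)
    stop("need at least two scenario groups", call. = FALSE)
  if (!all(vapply(groups, is, logical(1), "IndexSample")))
    stop("groups must be IndexSample objects", call. = FALSE)
  if (any(vapply(groups, function(g) length(g@values), integer(1)) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  nms <- vapply(groups, function(g) g@scenarioLabel, character(1))
  if (anyDuplicated(nms)) nms <- make.unique(nms)
  nms
}

#' One-way ANOVA across climate scenarios
#'
#' Fixed-effects one-way analysis of variance testing whether an index
#' differs among scenarios, treating species as independent replicates
#' within each scenario group. Fitted with [stats::aov()].
#'
#' @param groups list of [IndexSample-class] objects, one per scenario, each
#'   with `n >= 2`.
#' @return List with elements `F`, `dfBetween`, `dfWithin`, `p`, and `mse`
#'   (the pooled within-group mean square, reused by [lsdT()]).
#' @examples
#' g <- lapply(list(c(1, 2, 3), c(1.2, 2.2, 3.1), c(5, 6, 7)), IndexSample)
#' anovaScenarios(g)
#' @export
anovaScenarios <- function(groups) {
  nms <- .checkGroups(groups)
  values <- unlist(lapply(groups, function(g) g@values))
  scen <- factor(rep(nms, vapply(groups, function(g) length(g@values),
                                 integer(1))), levels = nms)
  fit <- stats::aov(values ~ scen)
  tab <- summary(fit)[[1L]]
  list(F = tab[["F value"]][1L],
       dfBetween = tab[["Df"]][1L],
       dfWithin = tab[["Df"]][2L],
       p = tab[["Pr(>F)"]][1L],
       mse = tab[["Mean Sq"]][2L])
}

# Maximal cliques of the "not significantly different" relation, smallest
# group count first; k is tiny (scenario count), so subset enumeration is fine.
.letterDisplay <- function(nms, notDiff) {
  k <- length(nms)
  subsets <- list()
  for (code in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0L)
    ok <- TRUE
    if (length(members) > 1L) {
      for (a in members) for (b in members)
        if (a < b && !notDiff[a, b]) { ok <- FALSE; break }
    }
    if (ok) subsets[[length(subsets) + 1L]] <- members
  }
  # keep maximal cliques only
  isMax <- vapply(subsets, function(s) {
    !any(vapply(subsets, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, logical(1))
  cliques <- subsets[isMax]
  cliques <- cliques[order(vapply(cliques, min, integer(1)))]
  letters_ <- letters[seq_along(cliques)]
  out <- vapply(seq_len(k), function(i) {
    paste(letters_[vapply(cliques, function(cl) i %in% cl, logical(1))],
          collapse = "")
  }, character(1))
  names(out) <- nms
  out
}

#' Gated LSD-t pairwise comparison of scenarios
#'
#' Fisher's least-significant-difference t tests between all scenario pairs,
#' using the pooled ANOVA mean-square error and its degrees of freedom, run
#' only when the preceding one-way ANOVA is significant (gate at
#' `gateAlpha = 0.05`). Pairwise decisions at `alpha = 0.10` are summarized
#' as a compact letter display: scenarios sharing a letter do not differ
#' significantly. When the gate blocks the comparison the result is flagged
#' `performed = FALSE` (the "/" entry of tabular reports); with
#' `strict = TRUE` a blocked gate is an error instead.
#'
#' @param groups list of [IndexSample-class] objects, one per scenario.
#' @param alpha pairwise significance level (default 0.10).
#' @param gateAlpha ANOVA gate level (default 0.05).
#' @param strict logical; error instead of returning a not-performed result
#'   when the ANOVA gate fails.
#' @return A [ScenarioComparison-class].
#' @examples
#' g <- lapply(list(c(1, 1.1, 0.9), c(1.05, 0.95, 1.0), c(4, 4.1, 3.9)),
#'             IndexSample)
#' g <- Map(function(s, n) { s@scenarioLabel <- n; s }, g,
#'          c("A1B", "A2", "B1"))
#' lsdT(g)
#' @export
lsdT <- function(groups, alpha = 0.10, gateAlpha = 0.05, strict = FALSE) {
  nms <- .checkGroups(groups)
  av <- anovaScenarios(groups)
  if (!is.finite(av$p) || av$p >= gateAlpha) {
    if (strict)
      stop("ANOVA gate not passed (p = ", format(av$p, digits = 4),
           "): LSD-t comparisons not performed", call. = FALSE)
    return(new("ScenarioComparison", anovaF = av$F, anovaP = av$p,
               performed = FALSE,
               pairwise = data.frame(groupA = character(), groupB = character(),
                                     t = numeric(), p = numeric()),
               letters = stats::setNames(rep(NA_character_, length(nms)),
                                         nms)))
  }
  k <- length(groups)
  means <- vapply(groups, function(g) mean(g@values), numeric(1))
  ns <- vapply(groups, function(g) length(g@values), numeric(1))
  pairs <- utils::combn(k, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(idx) {
    a <- pairs[1L, idx]; b <- pairs[2L, idx]
    se <- sqrt(av$mse * (1 / ns[a] + 1 / ns[b]))
    tStat <- (means[a] - means[b]) / se
    p <- 2 * stats::pt(-abs(tStat), df = av$dfWithin)
    data.frame(groupA = nms[a], groupB = nms[b], t = tStat, p = p,
               stringsAsFactors = FALSE)
  }))
  notDiff <- matrix(TRUE, k, k)
  for (idx in seq_len(ncol(pairs))) {
    a <- pairs[1L, idx]; b <- pairs[2L, idx]
    nd <- pw$p[idx] >= alpha
    notDiff[a, b] <- nd
    notDiff[b, a] <- nd
  }
  new("ScenarioComparison", anovaF = av$F, anovaP = av$p, performed = TRUE,
      pairwise = pw, letters = .letterDisplay(nms, notDiff))
}

#' Pool per-genus samples to the family level
#'
#' Concatenates index samples from several genera into one family-level
#' sample. All inputs must carry the same index name and scenario label.
#'
#' @param perGenus list of [IndexSample-class] objects.
#' @return An [IndexSample-class] with `groupLabel = "family"`.
#' @examples
#' a <- IndexSample(rnorm(12), "Abies", "A1B", "Dy")
#' b <- IndexSample(rnorm(16), "Pinus", "A1B", "Dy")
#' familyPool(list(a, b))
#' @export
familyPool <- function(perGenus) {
  if (length(perGenus) < 1L) stop("no samples to pool", call. = FALSE)
  idx <- unique(vapply(perGenus, function(g) g@indexName, character(1)))
  scen <- unique(vapply(perGenus, function(g) g@scenarioLabel, character(1)))
  if (length(idx) != 1L)
    stop("cannot pool samples of different indices: ",
         paste(idx, collapse = ", "), call. = FALSE)
  if (length(scen) != 1L)
    stop("cannot pool samples of different scenarios: ",
         paste(scen, collapse = ", "), call. = FALSE)
  IndexSample(unlist(lapply(perGenus, function(g) g@values)),
              groupLabel = "family", scenarioLabel = scen, indexName = idx)
}

setMethod("show", "GroupSummary", function(object) {
  sig <- if (is.na(object@sigClass)) "" else paste0(" ", object@sigClass)
  cat(sprintf("GroupSummary: mean %.4f%s, sd %s, n %d\n", object@mean, sig,
              if (is.na(object@sd)) "NA" else sprintf("%.4f", object@sd),
              object@n))
})

setMethod("show", "ScenarioComparison", function(object) {
  cat(sprintf("ANOVA: F = %.4f, p = %.4g\n", object@anovaF, object@anovaP))
  if (!object@performed) {
    cat("  LSD-t comparisons not performed (ANOVA gate)\n")
  } else {
    for (i in seq_len(nrow(object@pairwise)))
      cat(sprintf("  %s vs %s: t = %.4f, p = %.4g\n",
                  object@pairwise$groupA[i], object@pairwise$groupB[i],
                  object@pairwise$t[i], object@pairwise$p[i]))
    cat("  letters:",
        paste(names(object@letters), object@letters, sep = ":",
              collapse = "  "), "\n")
  }
})
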