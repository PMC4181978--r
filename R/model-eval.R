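#' @include AllClasses.R
NULL

.checkEvalSample <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length", call. = FALSE)
  if (!is.logical(labels))
    stop("labels must be logical (TRUE = presence)", call. = FALSE)
  if (anyNA(labels) || anyNA(scores))
    stop("labels and scores must not contain NA", call. = FALSE)
  if (any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed by the Mann-Whitney rank statistic: the
#' probability that a randomly drawn presence scores above a randomly drawn
#' absence, with tied scores counted one half. Requires at least one
#' presence and one absence.
#'
#' @param labels logical vector; `TRUE` = presence.
#' @param scores numeric vector of predicted suitabilities in `[0, 1]`.
#' @return A single number in `[0, 1]`.
#' @examples
#' aucScore(c(TRUE, TRUE, FALSE, FALSE), c(0.8, 0.4, 0.6, 0.2))  # 0.75
#' @export
aucScore <- function(labels, scores) {
  .checkEvalSample(labels, scores)
  nPres <- sum(labels)
  nAbs <- sum(!labels)
  if (nPres == 0L || nAbs == 0L)
    stop("AUC needs at least one presence and one absence", call. = FALSE)
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels]) - nPres * (nPres + 1) / 2) / (nPres * nAbs)
}

#' Confusion counts at a suitability threshold
#'
#' Dichotomizes scores at threshold `t` with the rule "predicted present iff
#' score >= t" (a cell exactly at the threshold stays inside the predicted
#' range) and cross-tabulates against the labels.
#'
#' @param labels logical vector; `TRUE` = presence.
#' @param scores numeric vector in `[0, 1]`.
#' @param t threshold in `[0, 1]`.
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusionAtThreshold <- function(labels, scores, t) {
  .checkEvalSample(labels, scores)
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]", call. = FALSE)
  pred <- scores >= t
  c(tp = sum(pred & labels), fp = sum(pred & !labels),
    fn = sum(!pred & labels), tn = sum(!pred & !labels))
}

#' Cohen's kappa from confusion counts
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between thresholded
#' predictions and observed labels. Returns 0 in the degenerate case
#' `p_e = 1` (all mass in one margin cell).
#'
#' @param counts named vector with `tp`, `fp`, `fn`, `tn` (as returned by
#'   [confusionAtThreshold()]).
#' @return A single number in `[-1, 1]`.
#' @examples
#' cohenKappa(c(tp = 40, fp = 10, fn = 10, tn = 40))  # 0.6
#' @export
cohenKappa <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  n <- tp + fp + fn + tn
  if (n <= 0) stop("empty confusion table", call. = FALSE)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) return(0)
  (po - pe) / (1 - pe)
}

#' True skill statistic from confusion counts
#'
#' `TSS = sensitivity + specificity - 1`. Unlike kappa it is insensitive to
#' prevalence. Both label margins must be non-empty.
#'
#' @param counts named vector with `tp`, `fp`, `fn`, `tn`.
#' @return A single number in `[-1, 1]`.
#' @examples
#' trueSkillStat(c(tp = 40, fp = 20, fn = 10, tn = 30))  # 0.4
#' @export
trueSkillStat <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  if (tp + fn == 0 || fp + tn == 0)
    stop("TSS undefined: a label class is empty", call. = FALSE)
  tp / (tp + fn) + tn / (fp + tn) - 1
}

#' Threshold-grid maxima of kappa and TSS, with AUC
#'
#' Evaluates Cohen's kappa and the true skill statistic at the 19 thresholds
#' `0.05, 0.10, ..., 0.95` (generated as exact multiples `k/20` to avoid
#' floating-point drift), selects the maxima (Max kappa, Max TSS), and
#' computes the rank-based AUC.
#'
#' @param labels logical vector; `TRUE` = presence.
#' @param scores numeric vector of predicted suitabilities in `[0, 1]`.
#' @return An [EvalMetrics-class] holding `auc`, `maxKappa`, `maxTSS` and the
#'   19-row per-threshold curve.
#' @examples
#' set.seed(1)
#' s <- makeEvalSample(nPres = 50, nAbs = 50, separation = 0.4, seed = 1)
#' maxOverThresholds(s$labels, s$scores)
#' @export
maxOverThresholds <- function(labels, scores) {
  .checkEvalSample(labels, scores)
  thresholds <- (1:19) / 20
  rows <- lapply(thresholds, function(t) {
    cc <- confusionAtThreshold(labels, scores, t)
    data.frame(threshold = t, kappa = cohenKappa(cc),
               tss = trueSkillStat(cc))
  })
  curve <- do.call(rbind, rows)
  new("EvalMetrics",
      auc = aucScore(labels, scores),
      maxKappa = max(curve$kappa),
      maxTSS = max(curve$tss),
      curve = curve)
}

setMethod("show", "EvalMetrics", function(object) {
  cat(sprintf("Model evaluation: AUC %.4f, Max kappa %.4f, Max TSS %.4f\n",
              object@auc, object@maxKappa, object@maxTSS))
  cat(sprintf("  threshold grid: %d points in [%.2f, %.2f]\n",
              nrow(object@curve), min(object@curve$threshold),
              max(object@curve$threshold)))
})
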