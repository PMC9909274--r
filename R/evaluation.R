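#' @include svm-ensemble.R
NULL

#' Confusion-matrix metrics
#'
#' Recall, specificity, precision, F1, Matthews correlation coefficient
#' and accuracy from the four confusion counts. A metric whose
#' denominator is zero is reported as `NaN` with a warning, never as a
#' silent 0.
#'
#' @param tp,fn,fp,tn non-negative confusion counts (at least one
#'   positive total).
#' @return Named numeric vector `recall, specificity, precision, f1,
#'   mcc, accuracy`.
#' @examples
#' confusionMetrics(3, 1, 2, 4)
#' @export
confusionMetrics <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("all confusion counts are zero")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting NaN")
      return(NaN)
    }
    num / den
  }
  mccDen <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(recall = safe(tp, tp + fn, "recall"),
    specificity = safe(tn, tn + fp, "specificity"),
    precision = safe(tp, tp + fp, "precision"),
    f1 = safe(2 * tp, 2 * tp + fp + fn, "F1"),
    mcc = safe(tp * tn - fp * fn, mccDen, "MCC"),
    accuracy = (tp + tn) / sum(counts))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midranks for tied scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores)   # midranks for ties
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' PT vector of a complex
#'
#' Per-complex chain-pair bookkeeping: `a` = number of correctly
#' predicted interactions, `b` = number of correctly predicted
#' non-interactions, and their sum, the L1 norm of the vector (a, b).
#'
#' @param predicted 0/1 predictions for the six chain pairs.
#' @param truth 0/1 true interactions for the six chain pairs.
#' @return Named numeric vector `c(a, b, norm)`.
#' @export
ptNorm <- function(predicted, truth) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != 6L || length(truth) != 6L)
    stop("a tetramer complex has exactly 6 chain pairs")
  a <- sum(predicted == 1L & truth == 1L)
  b <- sum(predicted == 0L & truth == 0L)
  c(a = a, b = b, norm = a + b)
}

#' NPIRP vector of a complex at depth t
#'
#' For each of the six possible chain-pair interfaces (fixed pair
#' order), counts the true interface pairs among the top-t ranked
#' predictions; returns the 6-vector with its L0 norm (interfaces hit)
#' and L1 norm (total true pairs retrieved).
#'
#' @param rankings list of six data.frames with columns `res1`, `res2`,
#'   `score` (candidate pairs of each chain pair; ranked internally
#'   with the deterministic tie-break of [rankInterface()]).
#' @param trueSets list of six two-column matrices of true interface
#'   pairs, e.g. from [interfacePairs()].
#' @param t ranking depth (>= 1).
#' @return List with `n` (the 6 counts), `l0` and `l1`.
#' @export
npirp <- function(rankings, trueSets, t) {
  stopifnot(length(rankings) == 6L, length(trueSets) == 6L, t >= 1L)
  n <- vapply(seq_len(6L), function(z) {
    rk <- rankings[[z]]
    truth <- trueSets[[z]]
    if (is.null(rk) || !nrow(rk)) return(0L)
    top <- suppressWarnings(
      rankInterface(cbind(rk$res1, rk$res2), rk$score, t))
    if (!nrow(truth)) return(0L)
    sum(paste(top$res1, top$res2) %in% paste(truth[, 1L], truth[, 2L]))
  }, integer(1))
  if (!is.null(names(rankings))) names(n) <- names(rankings)
  list(n = n, l0 = sum(n > 0L), l1 = sum(n))
}

#' Accuracy4t over a test set
#'
#' Percentage of complexes whose top-t predictions hit at least `z`
#' interfaces, among the complexes having at least `z` native
#' interfaces: `100 * NCTP / NTP`.
#'
#' @param l0 per-complex L0 norms (interfaces hit in the top t), from
#'   [npirp()].
#' @param nativeInterfaces per-complex counts of native interacting
#'   chain pairs.
#' @param z minimum number of correctly predicted interfaces required.
#' @return Percentage in [0, 100].
#' @examples
#' accuracy4t(c(2, 0, 6), c(5, 6, 6), z = 1)
#' @export
accuracy4t <- function(l0, nativeInterfaces, z) {
  stopifnot(length(l0) == length(nativeInterfaces), z >= 1L)
  ntp <- sum(nativeInterfaces >= z)
  if (ntp == 0L)
    stop("no complex has at least ", z, " native interfaces")
  100 * sum(l0 >= z) / ntp
}
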