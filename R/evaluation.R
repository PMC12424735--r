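#' Precision-recall and ROC curves with areas
#'
#' Sweeps every distinct score as a threshold (ties enter or leave the
#' predicted-positive set together). AUPRC is the step-wise average
#' precision (sum of precision times incremental recall); AUROC is the
#' trapezoid over the ROC curve, which equals the tie-corrected
#' Mann-Whitney statistic.
#'
#' @param scores predicted probabilities
#' @param labels binary labels; both classes must be present
#' @return list with `curve` (data.frame: threshold, tp, fp, tn, fn,
#'   precision, recall, fpr), `auprc`, `auroc`.
#' @examples
#' prRocCurves(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 1, 0, 0))$auroc
#' @export
prRocCurves <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  P <- sum(labels == 1L)
  Nn <- sum(labels == 0L)
  if (P == 0L || Nn == 0L)
    stop("both classes must be present to compute curves")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tpCum <- cumsum(y == 1L)
  fpCum <- cumsum(y == 0L)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- tpCum[last]
  fp <- fpCum[last]
  curve <- data.frame(threshold = s[last], tp = tp, fp = fp,
                      tn = Nn - fp, fn = P - tp,
                      precision = tp / (tp + fp), recall = tp / P,
                      fpr = fp / Nn)
  dTP <- diff(c(0L, tp))
  auprc <- sum(curve$precision * dTP) / P
  tpr <- c(0, curve$recall)
  fpr <- c(0, curve$fpr)
  auroc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  list(curve = curve, auprc = auprc, auroc = auroc)
}

#' Precision at a fixed recall level
#'
#' Precision of the highest-threshold curve point whose recall reaches the
#' requested level (the `Pr@0.5Re`-style metric).
#'
#' @param curve the `curve` data.frame from [prRocCurves()]
#' @param recallLevel target recall in (0, 1\]
#' @return Precision at that operating point.
#' @export
precisionAtRecall <- function(curve, recallLevel) {
  if (recallLevel <= 0 || recallLevel > 1)
    stop("recallLevel must lie in (0, 1]")
  hit <- which(curve$recall >= recallLevel)
  if (!length(hit))
    stop("recall level ", recallLevel, " not reached by any threshold")
  curve$precision[hit[1L]]
}

#' Prevalence correction for precision
#'
#' Describes re-weighting a test set's class imbalance (negatives per
#' positive, e.g. 6.5) to a target imbalance believed to hold at deployment
#' (e.g. 36). False positives are re-weighted by
#' `weight = targetRatio / testRatio`, equivalent to evaluating precision at
#' the target prevalence under unchanged class-conditional score
#' distributions; recall is unaffected.
#'
#' @param testRatio observed negative:positive ratio of the evaluation set
#' @param targetRatio assumed true negative:positive ratio
#' @return A `PrevalenceCorrection` list with `testRatio`, `targetRatio`,
#'   `weight`.
#' @export
prevalenceCorrection <- function(testRatio, targetRatio = 36) {
  if (testRatio <= 0 || targetRatio <= 0)
    stop("imbalance ratios must be positive")
  structure(list(testRatio = testRatio, targetRatio = targetRatio,
                 weight = targetRatio / testRatio),
            class = "PrevalenceCorrection")
}

#' Prevalence-corrected precision (PCPr)
#'
#' `PCPr = tp / (tp + weight * fp)` for a confusion count at one threshold.
#' With `weight = 1` this is raw precision; with weight above 1 it is
#' strictly smaller whenever any false positive exists.
#'
#' @param tp,fp true/false positive counts (tp + fp > 0; with zero
#'   predicted positives the value is undefined and `NA` is returned)
#' @param correction a [prevalenceCorrection()]
#' @return Corrected precision in \[0, 1\], or `NA` if tp + fp == 0.
#' @examples
#' prevalenceCorrectedPrecision(50, 50, prevalenceCorrection(6.5, 36))
#' @export
prevalenceCorrectedPrecision <- function(tp, fp, correction) {
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + correction$weight * fp)
}

#' Prevalence-corrected PR curve
#'
#' @param curve the `curve` data.frame from [prRocCurves()]
#' @param correction a [prevalenceCorrection()]
#' @return The curve with an added `pcpr` column.
#' @export
correctCurve <- function(curve, correction) {
  curve$pcpr <- mapply(prevalenceCorrectedPrecision, curve$tp, curve$fp,
                       MoreArgs = list(correction = correction))
  curve
}

#' Operating threshold for a target corrected precision
#'
#' The lowest threshold whose prevalence-corrected precision still meets
#' the target -- i.e. the recall-maximising threshold subject to the
#' precision constraint (the conservative deployment setting uses
#' `PCPr >= 0.75` at an assumed 1:36 imbalance).
#'
#' @param curve the `curve` data.frame from [prRocCurves()]
#' @param correction a [prevalenceCorrection()]
#' @param targetPCPr required corrected precision
#' @return list with `threshold`, `pcpr`, `recall` at the operating point.
#' @export
thresholdForTargetPCPr <- function(curve, correction, targetPCPr = 0.75) {
  cc <- correctCurve(curve, correction)
  ok <- which(!is.na(cc$pcpr) & cc$pcpr >= targetPCPr)
  if (!length(ok))
    stop(sprintf("target PCPr %.3f unattainable; maximum achievable is %.3f",
                 targetPCPr, max(cc$pcpr, na.rm = TRUE)))
  i <- ok[length(ok)]
  list(threshold = cc$threshold[i], pcpr = cc$pcpr[i],
       recall = cc$recall[i])
}

#' Full metric report for one score set
#'
#' @param scores predicted probabilities
#' @param labels binary labels
#' @param recallLevels recall levels for fixed-recall precision (default
#'   0.5)
#' @param correction optional [prevalenceCorrection()]; when supplied, the
#'   corrected curve and a `PCPr >= targetPCPr` operating threshold are
#'   included
#' @param targetPCPr target corrected precision (default 0.75)
#' @return list with `auprc`, `auroc`, `prAtRecall`, `imbalance`
#'   (negative:positive ratio of the labels), `curve`, and optionally
#'   `operating`.
#' @export
metricReport <- function(scores, labels, recallLevels = 0.5,
                         correction = NULL, targetPCPr = 0.75) {
  cv <- prRocCurves(scores, labels)
  rep <- list(auprc = cv$auprc, auroc = cv$auroc,
              prAtRecall = setNames(
                vapply(recallLevels, function(r)
                  precisionAtRecall(cv$curve, r), numeric(1)),
                paste0("Pr@", recallLevels, "Re")),
              imbalance = imbalanceRatio(labels),
              curve = cv$curve)
  if (!is.null(correction)) {
    rep$curve <- correctCurve(cv$curve, correction)
    rep$operating <- tryCatch(
      thresholdForTargetPCPr(cv$curve, correction, targetPCPr),
      error = function(e) NULL)
  }
  rep
}

#' Negative:positive imbalance ratio of a label set
#'
#' @param labels binary labels, or a two-element vector `c(pos, neg)` of
#'   counts when `counts = TRUE`
#' @param counts interpret `labels` as (positive, negative) counts
#' @return Ratio of negatives per positive.
#' @examples
#' imbalanceRatio(c(755, 4906), counts = TRUE)  # the 1:6.5 test imbalance
#' @export
imbalanceRatio <- function(labels, counts = FALSE) {
  if (counts) {
    pos <- labels[1L]; neg <- labels[2L]
  } else {
    pos <- sum(labels == 1L); neg <- sum(labels == 0L)
  }
  if (pos == 0) stop("no positives; imbalance ratio undefined")
  neg / pos
}
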