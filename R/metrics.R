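# Multiclass evaluation: accuracy, macro precision/recall/F1, averaged
# one-vs-rest AUC, confusion matrix.

#' MetricsReport: multiclass evaluation summary
#'
#' @slot accuracy Overall fraction correct.
#' @slot macroPrecision,macroRecall,macroF1 Macro averages over classes
#'   present in the truth vector (0/0 counted as 0).
#' @slot meanAuc One-vs-rest AUC (Mann-Whitney rank statistic with
#'   midranks) averaged over classes present in the truth vector.
#' @slot confusion 9x9 matrix, rows = truth, columns = prediction.
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric", macroPrecision = "numeric",
                 macroRecall = "numeric", macroF1 = "numeric",
                 meanAuc = "numeric", confusion = "matrix"),
  validity = function(object) {
    v <- c(object@accuracy, object@macroPrecision, object@macroRecall,
           object@macroF1, object@meanAuc)
    if (any(v < -1e-9 | v > 1 + 1e-9)) return("scalar metrics must lie in [0,1]")
    TRUE
  })

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport: accuracy %.3f | macro P %.3f R %.3f ",
                     "F1 %.3f | mean OvR AUC %.3f\n"),
              object@accuracy, object@macroPrecision, object@macroRecall,
              object@macroF1, object@meanAuc))
})

# Mann-Whitney AUC with midranks for ties: P(score_pos > score_neg) +
# 0.5 P(equal).
rankAuc <- function(scores, positive) {
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Evaluate multiclass predictions
#'
#' Macro-averaged precision/recall/F1 over the classes present in `yTrue`,
#' one-vs-rest AUC per present class averaged, and the 9x9 confusion
#' matrix (rows = truth). Classes absent from `yTrue` are excluded from the
#' AUC average with a warning.
#'
#' @param yTrue Integer labels in 0..8.
#' @param yProb Numeric matrix `n x 9` of class probabilities (rows sum
#'   to 1; column j is class j-1).
#' @return A [MetricsReport-class].
#' @export
evaluateMetrics <- function(yTrue, yProb) {
  yTrue <- as.integer(yTrue)
  yProb <- as.matrix(yProb)
  if (ncol(yProb) != 9L) stop("yProb must have 9 columns", call. = FALSE)
  if (length(yTrue) != nrow(yProb)) stop("length mismatch", call. = FALSE)
  if (any(abs(rowSums(yProb) - 1) > 1e-6)) stop("probability rows must sum to 1", call. = FALSE)
  if (length(unique(yTrue)) < 2L) stop("need at least 2 classes in yTrue", call. = FALSE)
  yPred <- max.col(yProb, ties.method = "first") - 1L
  conf <- matrix(0L, 9, 9, dimnames = list(truth = 0:8, predicted = 0:8))
  for (i in seq_along(yTrue)) conf[yTrue[i] + 1L, yPred[i] + 1L] <- conf[yTrue[i] + 1L, yPred[i] + 1L] + 1L
  present <- sort(unique(yTrue))
  absent <- setdiff(0:8, present)
  if (length(absent))
    warning(sprintf("classes absent from yTrue excluded from macro/AUC averages: %s",
                    paste(absent, collapse = ",")), call. = FALSE)
  prf <- vapply(present, function(k) {
    tp <- sum(yTrue == k & yPred == k)
    fp <- sum(yTrue != k & yPred == k)
    fn <- sum(yTrue == k & yPred != k)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f)
  }, numeric(3))
  aucs <- vapply(present, function(k) rankAuc(yProb[, k + 1L], yTrue == k), numeric(1))
  new("MetricsReport",
      accuracy = mean(yPred == yTrue),
      macroPrecision = mean(prf[1, ]), macroRecall = mean(prf[2, ]),
      macroF1 = mean(prf[3, ]), meanAuc = mean(aucs), confusion = conf)
}

#' Accessors for MetricsReport
#'
#' @param x A [MetricsReport-class].
#' @return `metricsTable`: one-row data.frame of the scalar metrics;
#'   `confusionMatrix`: the 9x9 count matrix.
#' @export
metricsTable <- function(x) {
  stopifnot(is(x, "MetricsReport"))
  data.frame(accuracy = x@accuracy, macro_precision = x@macroPrecision,
             macro_recall = x@macroRecall, macro_f1 = x@macroF1,
             mean_ovr_auc = x@meanAuc)
}

#' @rdname metricsTable
#' @export
confusionMatrix <- function(x) {
  stopifnot(is(x, "MetricsReport"))
  x@confusion
}
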