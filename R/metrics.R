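## Benchmark metrics: precision-recall, ROC, TPR at fixed FPR.

#' Classification metrics for benchmark scores
#'
#' Computes the step-interpolated precision-recall curve and its area
#' (AUPRC, the average-precision form), the empirical ROC curve and AUROC
#' (rank statistic with tie correction), and the true-positive rate at
#' requested empirical false-positive-rate cutoffs (largest TPR over
#' thresholds whose FPR does not exceed the cutoff).
#'
#' @param scores numeric scores, larger = more evidence for the positive
#'   class (e.g. logBF1).
#' @param labels logical or 0/1 vector of true classes.
#' @param fpr_cutoffs FPR levels for TPR\@FPR (default 0.01 and 0.05).
#' @return list with \code{auprc}, \code{auroc}, \code{tpr_at_fpr}
#'   (named numeric), \code{pr} and \code{roc} (data frames).
#' @export
benchmark_metrics <- function(scores, labels, fpr_cutoffs = c(0.01, 0.05)) {
  labels <- as.logical(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("need both classes")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  ## collapse tied thresholds
  last <- c(sc[-1L] != sc[-length(sc)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  fpr <- fp / n_neg
  ## AUPRC: sum over recall increments of the precision at that threshold
  auprc <- sum(diff(c(0, recall)) * precision)
  ## AUROC via Mann-Whitney with tie correction
  r <- rank(scores)
  auroc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  taf <- vapply(fpr_cutoffs, function(f) {
    ok <- fpr <= f + 1e-12
    if (any(ok)) max(recall[ok]) else 0
  }, 0)
  names(taf) <- paste0("fpr", fpr_cutoffs)
  list(auprc = auprc, auroc = auroc, tpr_at_fpr = taf,
       pr = data.frame(recall = recall, precision = precision),
       roc = data.frame(fpr = fpr, tpr = recall))
}
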