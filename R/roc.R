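#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (ties
#' grouped), accumulating true- and false-positive rates, and integrates
#' the curve by the trapezoid rule.  With tied scores this equals the
#' rank-average (Mann-Whitney) formulation of the AUC.
#'
#' @param scores numeric classifier scores (e.g. OOB vote shares).
#' @param y binary outcomes, both classes present.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, y) {
  y <- as.integer(y)
  .check_binary(y, "outcome y")
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present to compute a ROC curve")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y == 1), 0L)
  fp <- vapply(thr, function(t) sum(scores >= t & y == 0), 0L)
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}
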