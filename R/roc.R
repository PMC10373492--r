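#' ROC analysis of a score or feature panel
#'
#' AUC is computed from the empirical ROC curve (trapezoid over the unique
#' score thresholds; tied scores contribute half-concordance, so the value
#' equals the normalised Mann-Whitney U statistic). The 95 percent
#' confidence interval comes from a stratified bootstrap; misclassification
#' is evaluated at the Youden-optimal threshold (maximising TPR - FPR).
#' When a matrix of selected features is supplied, a logistic regression
#' combines them into one score per sample first.
#'
#' @param scores per-sample numeric score (higher = more likely positive),
#'   or a samples x features matrix of a selected-feature panel.
#' @param labels binary labels; the second factor level (or the larger of
#'   two values) is the positive class.
#' @param n_boot bootstrap resamples for the CI (default 2000).
#' @param seed RNG seed for the bootstrap (required).
#' @return object of class `roc_result`: `auc`, `ci_lo`, `ci_hi`,
#'   `misclassification` (percent), `threshold`, `curve` (FPR/TPR
#'   data.frame), `scores`.
#' @export
roc_analysis <- function(scores, labels, n_boot = 2000, seed) {
  if (missing(seed)) stop("a bootstrap seed is required")
  lf <- factor(labels)
  if (nlevels(lf) != 2) stop("labels must have exactly 2 classes")
  pos <- as.numeric(lf) == 2
  if (is.matrix(scores) || is.data.frame(scores)) {
    df <- data.frame(y = as.numeric(pos), as.data.frame(scores))
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    scores <- unname(fit$fitted.values)
  }
  stopifnot(length(scores) == length(lf))
  curve_auc <- function(s, p) {
    th <- sort(unique(s), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(s[p] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(s[!p] >= t), numeric(1))
    fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
    sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  }
  auc <- curve_auc(scores, pos)
  set.seed(seed)
  ip <- which(pos); inn <- which(!pos)
  bauc <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ip, replace = TRUE), sample(inn, replace = TRUE))
    curve_auc(scores[idx], pos[idx])
  }, numeric(1))
  ci <- stats::quantile(bauc, c(0.025, 0.975), names = FALSE, type = 7)
  ci <- c(min(ci[1], auc), max(ci[2], auc))
  th <- sort(unique(scores), decreasing = TRUE)
  youden <- vapply(th, function(t)
    mean(scores[pos] >= t) - mean(scores[!pos] >= t), numeric(1))
  t_star <- th[which.max(youden)]
  miscl <- 100 * mean((scores >= t_star) != pos)
  fpr <- c(0, vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
  tpr <- c(0, vapply(th, function(t) mean(scores[pos] >= t), numeric(1)), 1)
  structure(list(auc = auc, ci_lo = ci[1], ci_hi = ci[2],
                 misclassification = miscl, threshold = t_star,
                 curve = data.frame(fpr = fpr, tpr = tpr), scores = scores),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f), misclassification %.1f%% at Youden threshold\n",
              x$auc, x$ci_lo, x$ci_hi, x$misclassification))
  invisible(x)
}
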