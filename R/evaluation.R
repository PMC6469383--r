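#' Confusion counts at a score threshold
#'
#' A SNP is called positive iff its score is at or above `t`.
#'
#' @param scores per-SNP numeric scores (e.g. stability frequencies)
#' @param labels logical (or 0/1) causal indicators; must contain both
#'   classes
#' @param t threshold
#' @return one-row tibble with tp, fp, tn, fn, precision, recall,
#'   sensitivity, specificity.
#' @export
confusion_at_threshold <- function(scores, labels, t) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (all(labels) || !any(labels))
    stop("labels must contain both positives and negatives")
  pred <- scores >= t
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  tibble::tibble(threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = tp / (tp + fn),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp))
}

#' Precision-recall and ROC curve over all distinct-score thresholds
#'
#' Thresholds are the distinct scores in descending order (ties share a
#' threshold). The PR area is the trapezoidal rule over the recall-ordered
#' curve, anchored at recall 0 with the first point's precision; the ROC
#' area is the trapezoid over (FPR, TPR) with the (0,0) and (1,1) anchors.
#'
#' @inheritParams confusion_at_threshold
#' @return An object of class `ranking_eval`: tibble `curve` (one row per
#'   threshold), `pr_auc`, `roc_auc`, `n_pos`, `n_neg`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores (", length(scores), ") and labels (", length(labels),
         ") differ in length")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (all(labels) || !any(labels))
    stop("labels must contain both positives and negatives")
  P <- sum(labels); N <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- c(diff(s) != 0, TRUE)        # last index of each distinct score
  tp <- cumsum(l)[last]; fp <- cumsum(!l)[last]
  curve <- tibble::tibble(
    threshold = s[last], tp = tp, fp = fp, tn = N - fp, fn = P - tp,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    recall = tp / P, sensitivity = tp / P,
    specificity = (N - fp) / N)
  rec <- curve$recall; prec <- curve$precision
  # recall is non-decreasing along descending thresholds; anchor recall = 0
  pr_auc <- sum(diff(c(0, rec)) * (c(prec[1], utils::head(prec, -1)) + prec) / 2)
  fpr <- 1 - curve$specificity; tpr <- curve$sensitivity
  roc_auc <- sum(diff(c(0, fpr, 1)) * (c(0, tpr) + c(tpr, 1)) / 2)
  structure(list(curve = curve, pr_auc = pr_auc, roc_auc = roc_auc,
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "ranking_eval")
}

#' @export
print.ranking_eval <- function(x, ...) {
  cat(sprintf("<ranking_eval> %d+/%d- , PR-AUC = %.4f, ROC-AUC = %.4f\n",
              x$n_pos, x$n_neg, x$pr_auc, x$roc_auc))
  invisible(x)
}

#' Area under the precision-recall curve
#' @param x a `ranking_eval` from [pr_curve()], or a score vector (then
#'   `labels` is required)
#' @param labels causal indicators when `x` is a score vector
#' @return scalar in `[0, 1]`.
#' @export
pr_auc <- function(x, labels = NULL) {
  if (inherits(x, "ranking_eval")) return(x$pr_auc)
  pr_curve(x, labels)$pr_auc
}

#' Area under the ROC curve
#' @inheritParams pr_auc
#' @export
roc_auc <- function(x, labels = NULL) {
  if (inherits(x, "ranking_eval")) return(x$roc_auc)
  pr_curve(x, labels)$roc_auc
}

#' Summarize recovery performance over a simulation grid
#'
#' Expects one row per evaluated dataset with its PR-AUC (or computes it
#' from list-columns of scores and labels), and averages within
#' (sigma_sig, sigma_pop, method) cells.
#'
#' @param results tibble with columns `sigma_sig`, `sigma_pop`, `method`,
#'   and either `pr_auc` or list-columns `scores`, `labels`
#' @return tibble with per-cell n, mean_pr_auc, sd_pr_auc (sd is NA for
#'   singleton cells).
#' @export
evaluate_grid <- function(results) {
  stopifnot(nrow(results) >= 1)
  if (!"pr_auc" %in% names(results)) {
    results$pr_auc <- purrr::map2_dbl(results$scores, results$labels, pr_auc)
  }
  dplyr::summarise(
    dplyr::group_by(results, .data$sigma_sig, .data$sigma_pop, .data$method),
    n = dplyr::n(),
    mean_pr_auc = mean(.data$pr_auc),
    sd_pr_auc = stats::sd(.data$pr_auc),
    .groups = "drop")
}
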