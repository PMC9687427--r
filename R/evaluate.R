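# Evaluation: confusion metrics, ROC/AUC by the rank formulation,
# precision-recall points, and the accuracy-versus-number-of-features curve.

#' Confusion metrics from a prediction table
#'
#' Implantation success is the positive class: accuracy = (TP + TN)/n,
#' sensitivity = TP/(TP + FN), specificity = TN/(TN + FP),
#' F1 = 2TP/(2TP + FP + FN), MSE = mean squared difference between the
#' voting score and the 0/1 truth.
#'
#' @param predictions data.frame with \code{true_label},
#'   \code{predicted_label} and \code{score} columns.
#' @return List of class \code{"eval_report"} with \code{accuracy},
#'   \code{sensitivity}, \code{specificity}, \code{f1}, \code{mse},
#'   \code{n_errors}, \code{n}.
#' @export
confusion_metrics <- function(predictions) {
  stopifnot(nrow(predictions) >= 1)
  truth <- predictions$true_label == "success"
  pred <- predictions$predicted_label == "success"
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  n <- length(truth)
  sens <- if (tp + fn == 0) {
    warning("no positive-class samples; sensitivity undefined"); NaN
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no negative-class samples; specificity undefined"); NaN
  } else tn / (tn + fp)
  structure(list(
    accuracy = (tp + tn) / n,
    sensitivity = sens,
    specificity = spec,
    f1 = if (2 * tp + fp + fn == 0) NaN else 2 * tp / (2 * tp + fp + fn),
    mse = mean((predictions$score - as.numeric(truth))^2),
    n_errors = fp + fn,
    n = n
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "n = %d | accuracy %.3f | sensitivity %.3f | specificity %.3f | F1 %.3f | MSE %.3f | errors %d\n",
    x$n, x$accuracy, x$sensitivity, x$specificity, x$f1, x$mse, x$n_errors))
  invisible(x)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the probability that a random positive outscores a random
#' negative, ties counted one half; the curve is a threshold sweep over the
#' observed scores, anchored at (0,0) and (1,1).
#'
#' @param scores Numeric scores (higher = more success-like).
#' @param truth Labels (\code{"success"} positive) or logical/0-1 vector.
#' @return List with \code{auc} and \code{roc_points} (data.frame of
#'   \code{fpr}, \code{tpr}).
#' @export
roc_auc <- function(scores, truth) {
  pos <- truth_to_logical(truth)
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    call <- scores >= t
    c(fpr = sum(call & !pos) / nn, tpr = sum(call & pos) / np)
  }, numeric(2)))
  pts <- rbind(c(fpr = 0, tpr = 0), pts, c(fpr = 1, tpr = 1))
  pts <- unique(as.data.frame(pts))
  list(auc = auc, roc_points = pts[order(pts$fpr, pts$tpr), ])
}

truth_to_logical <- function(truth) {
  if (is.character(truth) || is.factor(truth))
    as.character(truth) == "success"
  else as.logical(truth)
}

#' Precision-recall points
#'
#' @inheritParams roc_auc
#' @return data.frame of \code{recall}, \code{precision} over the
#'   threshold sweep.
#' @export
pr_points <- function(scores, truth) {
  pos <- truth_to_logical(truth)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    call <- scores >= t
    c(recall = sum(call & pos) / sum(pos),
      precision = if (any(call)) sum(call & pos) / sum(call) else 1)
  }, numeric(2)))
  as.data.frame(pts)
}

#' Leave-one-out accuracy as a function of the number of features
#'
#' For each k, runs leave-one-out classification using the top-k features
#' of a fixed ranked list (non-nested) and records the accuracy; used to
#' confirm the plateau at the consensus size.
#'
#' @param mat Feature-by-sample log-CPM matrix.
#' @param labels Per-sample labels.
#' @param ranked_features Character vector of feature ids, best first.
#' @param ks Integer vector of feature counts to evaluate (k = 0 entries
#'   are skipped with a warning).
#' @param seed Integer seed.
#' @return data.frame with columns \code{k}, \code{accuracy}.
#' @export
accuracy_vs_k <- function(mat, labels, ranked_features, ks, seed = 1L) {
  if (any(ks == 0)) {
    warning("k = 0 entries skipped")
    ks <- ks[ks != 0]
  }
  stopifnot(all(ks <= length(ranked_features)), all(ks > 0))
  acc <- vapply(ks, function(k) {
    pt <- loo_predict(mat, labels,
                      features = utils::head(ranked_features, k),
                      nested = FALSE, seed = seed)
    mean(pt$correct)
  }, numeric(1))
  data.frame(k = ks, accuracy = acc)
}
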