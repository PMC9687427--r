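# Leave-one-out voting classification, holdout prediction, PCA/LDA
# projections, and hierarchical-clustering anomaly detection.

#' Leave-one-out prediction with the voting classifier
#'
#' For each sample, trains the hard-voting ensemble on the remaining n - 1
#' samples and predicts the held-out one. With \code{nested = TRUE} the
#' full feature-selection stage is re-run inside every fold (leakage-safe);
#' with \code{nested = FALSE} a fixed feature set (e.g. the global
#' consensus) is reused across folds. Folds whose training set degenerates
#' (a class absent or left with a single sample) fall back to the
#' majority-class prediction.
#'
#' @param mat Feature-by-sample log-CPM matrix (exploratory samples).
#' @param labels Per-sample labels, \code{"success"} / \code{"failure"}.
#' @param features Fixed feature set for \code{nested = FALSE}; ignored
#'   when nested.
#' @param nested Re-run feature selection inside each fold (default TRUE).
#' @param top_k,min_votes,var_quantile Passed to
#'   \code{\link{select_features}} when nested.
#' @param seed Integer seed (folds use seed + fold index).
#' @param max_features When a nested fold yields an empty consensus, fall
#'   back to the top \code{max_features} features by F statistic.
#' @return A prediction table (data.frame): \code{sample_id},
#'   \code{true_label}, \code{predicted_label}, the three per-model votes,
#'   \code{score}, \code{correct}.
#' @export
loo_predict <- function(mat, labels, features = NULL, nested = TRUE,
                        top_k = 15, min_votes = 3, var_quantile = 0.1,
                        seed = 1L, max_features = 7) {
  labels <- as.character(labels)
  n <- ncol(mat)
  stopifnot(n >= 4, length(labels) == n)
  if (!nested && is.null(features))
    stop("nested = FALSE requires a fixed feature set")

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- labels[tr]
    if (length(unique(ytr)) < 2 || min(table(ytr)) < 2) {
      maj <- names(which.max(table(ytr)))
      message("fold ", i, ": single-class training set; majority fallback")
      rows[[i]] <- data.frame(sample_id = colnames(mat)[i],
                              predicted_label = maj,
                              vote_svm = maj, vote_rf = maj, vote_sgd = maj,
                              score = as.numeric(maj == "success"),
                              stringsAsFactors = FALSE)
      next
    }
    feats <- if (nested) {
      sc <- select_features(mat[, tr, drop = FALSE], ytr, top_k = top_k,
                            min_votes = min_votes, seed = seed + i,
                            var_quantile = var_quantile)
      cons <- attr(sc, "consensus")
      if (length(cons)) cons
      else utils::head(sc$feature_id, max_features)
    } else features
    fit <- fit_voting_classifier(mat[feats, tr, drop = FALSE], ytr,
                                 seed = seed + i)
    rows[[i]] <- predict(fit, mat[, i, drop = FALSE])
  }
  out <- do.call(rbind, rows)
  out <- data.frame(sample_id = out$sample_id, true_label = labels,
                    predicted_label = out$predicted_label,
                    vote_svm = out$vote_svm, vote_rf = out$vote_rf,
                    vote_sgd = out$vote_sgd, score = out$score,
                    stringsAsFactors = FALSE)
  out$correct <- out$predicted_label == out$true_label
  out
}

#' Predict held-out validation samples with a frozen model
#'
#' Applies the exploratory-phase model (and its frozen feature set) to new
#' samples.
#'
#' @param model An \code{snc_voter} fit from the exploratory phase.
#' @param mat Feature-by-sample log-CPM matrix of validation samples; must
#'   contain every training feature.
#' @param labels Optional true labels for the validation samples.
#' @return Prediction table as in \code{\link{loo_predict}} (without
#'   \code{true_label}/\code{correct} when labels are not given).
#' @export
predict_holdout <- function(model, mat, labels = NULL) {
  out <- predict(model, mat)
  if (!is.null(labels)) {
    out$true_label <- as.character(labels)
    out$correct <- out$predicted_label == out$true_label
  }
  out
}

#' PCA projection of samples
#'
#' Mean-centered projection onto the leading principal axes, with
#' explained-variance fractions.
#'
#' @param mat Feature-by-sample matrix.
#' @param n_components Number of components (default 3).
#' @return List with \code{coords} (samples x components),
#'   \code{explained} (variance fractions, non-increasing) and
#'   \code{rotation} (feature loadings).
#' @export
pca_project <- function(mat, n_components = 3) {
  x <- t(mat)
  max_c <- min(ncol(x), nrow(x) - 1)
  if (n_components > max_c)
    stop("n_components exceeds min(features, samples - 1) = ", max_c)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)],
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE])
}

#' Fisher LDA projection for multifactor analysis
#'
#' Projects samples onto the <= (classes - 1) Fisher discriminant axes
#' maximizing the between-class to within-class scatter ratio. A singular
#' within-class scatter matrix is ridge-regularized (epsilon 1e-6 times the
#' mean diagonal) with a message.
#'
#' @param mat Feature-by-sample matrix.
#' @param groups Class labels per sample (e.g. interaction of outcome, day
#'   and storage); every class must have >= 2 samples.
#' @return List with \code{coords} (samples x axes) and \code{groups}.
#' @export
lda_project <- function(mat, groups) {
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2),
            length(groups) == ncol(mat))
  x <- t(mat)
  mu <- colMeans(x)
  sw <- matrix(0, ncol(x), ncol(x))
  sb <- matrix(0, ncol(x), ncol(x))
  for (g in levels(groups)) {
    xg <- x[groups == g, , drop = FALSE]
    mg <- colMeans(xg)
    sw <- sw + crossprod(sweep(xg, 2, mg))
    sb <- sb + nrow(xg) * tcrossprod(mg - mu)
  }
  if (rcond_sym(sw) < 1e-12) {
    message("singular within-class scatter; ridge-regularizing")
    sw <- sw + diag(1e-6 * mean(diag(sw)) + 1e-12, ncol(x))
  }
  eig <- eigen(solve(sw, sb))
  k <- min(nlevels(groups) - 1, ncol(x))
  axes <- Re(eig$vectors[, seq_len(k), drop = FALSE])
  coords <- sweep(x, 2, mu) %*% axes
  colnames(coords) <- paste0("LD", seq_len(k))
  list(coords = coords, groups = groups)
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Anomalous-sample detection by hierarchical clustering
#'
#' Clusters samples (Ward linkage on Euclidean distances of standardized
#' features) into two groups and flags every sample carrying the minority
#' label of its cluster. Run on training data restricted to the consensus
#' features.
#'
#' @param mat Feature-by-sample matrix (consensus features).
#' @param labels Per-sample labels.
#' @return Character vector of flagged sample ids (possibly empty), with
#'   the cluster assignment as attribute \code{"clusters"}.
#' @export
detect_anomalies <- function(mat, labels) {
  stopifnot(ncol(mat) >= 4, length(labels) == ncol(mat))
  xs <- standardize_features(t(mat))
  d <- stats::dist(xs)
  if (max(d) == 0) stop("all samples identical; clustering degenerate")
  cl <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = 2)
  labels <- as.character(labels)
  flagged <- character(0)
  for (k in 1:2) {
    idx <- which(cl == k)
    tab <- table(labels[idx])
    if (length(tab) < 2) next
    minority <- names(tab)[which.min(tab)]
    flagged <- c(flagged, colnames(mat)[idx][labels[idx] == minority])
  }
  structure(flagged, clusters = cl)
}
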