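# Ensemble feature selection: pre-filtering, normality gate, three
# importance rankers, top-k hard voting, one-way ANOVA F arbitration and
# volcano-style deregulation flags.

#' Pre-filter features with zero counts or low variance
#'
#' Removes features that are constant across all samples (which includes
#' features with zero counts everywhere) and features whose variance across
#' samples falls in the lowest \code{var_quantile} fraction.
#'
#' @param mat Feature-by-sample matrix (typically log-CPM of embryo samples).
#' @param var_quantile Quantile of the nonzero variances below which
#'   features are dropped (default 0.10).
#' @return The reduced matrix.
#' @export
prefilter <- function(mat, var_quantile = 0.1) {
  v <- apply(mat, 1, stats::var)
  keep <- v > 0
  if (!any(keep)) stop("no features survive pre-filtering")
  thr <- stats::quantile(v[keep], var_quantile, names = FALSE)
  keep <- keep & v >= thr
  if (!any(keep)) stop("no features survive pre-filtering")
  mat[keep, , drop = FALSE]
}

#' Normality gate for choosing parametric versus rank-based arbitration
#'
#' Shapiro-Wilk test at alpha = 0.05 on a vector of residuals (in the
#' pipeline: within-group-centered log-CPM values of the consensus
#' features). Returns \code{"parametric"} when normality is not rejected,
#' \code{"nonparametric"} otherwise; the verdict selects plain one-way
#' ANOVA versus ANOVA on rank-transformed values downstream. Vectors longer
#' than 5000 values are thinned deterministically to 5000 (evenly spaced
#' after sorting by position) to stay inside the test's support.
#'
#' @param values Numeric vector of residuals, length >= 3.
#' @param alpha Rejection level (default 0.05).
#' @return \code{"parametric"} or \code{"nonparametric"}.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 observations")
  if (length(values) > 5000)
    values <- values[round(seq(1, length(values), length.out = 5000))]
  if (stats::sd(values) == 0) return("nonparametric")
  p <- stats::shapiro.test(values)$p.value
  if (p < alpha) "nonparametric" else "parametric"
}

#' Rank features by importance under one model family
#'
#' Fits the named model on standardized log-CPM features (samples as rows)
#' and returns the features sorted by importance: gain for gradient-boosted
#' trees, absolute coefficient for the L1-regularized logistic model (with
#' the penalty chosen by 5-fold cross-validated deviance), impurity
#' importance for extremely randomized trees. Deterministic given the seed;
#' ties broken by feature id.
#'
#' The boosted-trees ranker uses 500 depth-3 trees with shrinkage 0.05,
#' row subsampling 0.5, per-node column subsampling 0.1 and L2 penalty 10:
#' without subsampling and shrinkage, one of a set of redundant strong
#' predictors absorbs all the gain and the rest never enter the ranking.
#'
#' @param mat Feature-by-sample log-CPM matrix (pre-filtered).
#' @param labels Binary character/factor labels, one per sample.
#' @param model_kind One of \code{"boosted_trees"}, \code{"l1_linear"},
#'   \code{"extra_random_trees"}.
#' @param seed Integer seed.
#' @return data.frame with columns \code{feature_id}, \code{importance},
#'   \code{rank}, sorted by decreasing importance.
#' @export
rank_features <- function(mat, labels,
                          model_kind = c("boosted_trees", "l1_linear",
                                         "extra_random_trees"),
                          seed = 1L) {
  model_kind <- match.arg(model_kind)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("labels must contain two classes")
  x <- standardize_features(t(mat))
  y <- as.integer(labels == "success")
  if (length(unique(y)) < 2)  # labels other than success/failure: factor code
    y <- as.integer(factor(labels)) - 1L
  imp <- stats::setNames(numeric(nrow(mat)), rownames(mat))

  if (model_kind == "boosted_trees") {
    set.seed(as.integer(seed))
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.05, subsample = 0.5, colsample_bynode = 0.1,
                    lambda = 10, nthread = 1),
      data = dtrain, nrounds = 500, verbose = 0)
    it <- xgboost::xgb.importance(model = bst)
    imp[it$Feature] <- it$Gain
  } else if (model_kind == "l1_linear") {
    set.seed(as.integer(seed))
    imp[] <- abs(l1_coefficients(x, y))
  } else {
    fit <- ranger::ranger(x = x, y = factor(labels), num.trees = 500,
                          splitrule = "extratrees", num.random.splits = 1,
                          importance = "impurity", seed = as.integer(seed),
                          num.threads = 1)
    imp[names(fit$variable.importance)] <- fit$variable.importance
  }

  ord <- order(-imp, names(imp))
  data.frame(feature_id = names(imp)[ord], importance = unname(imp[ord]),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}

# L1-regularized logistic coefficients with the penalty chosen by 5-fold
# cross-validated deviance under the one-standard-error rule, with the CV
# curve averaged over `nrep` fold assignments. The averaging stabilizes the
# penalty choice so that on label-uninformative data the selected model is
# (almost always) empty, which keeps chance associations out of the
# consensus vote.
l1_coefficients <- function(x, y, nrep = 5) {
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        standardize = FALSE)
  lam <- fit$lambda
  cvm <- cvsd <- matrix(NA_real_, length(lam), nrep)
  for (r in seq_len(nrep)) {
    foldid <- sample(rep_len(1:5, length(y)))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            lambda = lam, foldid = foldid,
                            standardize = FALSE)
    k <- match(cv$lambda, lam)
    cvm[k, r] <- cv$cvm
    cvsd[k, r] <- cv$cvsd
  }
  m <- rowMeans(cvm, na.rm = TRUE)
  s <- rowMeans(cvsd, na.rm = TRUE)
  ok <- which(is.finite(m) & is.finite(s))
  i_min <- ok[which.min(m[ok])]
  lam_1se <- max(lam[ok][m[ok] <= m[i_min] + s[i_min]])
  as.numeric(stats::coef(fit, s = lam_1se))[-1]
}

standardize_features <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  scale(x, center = ctr, scale = scl)
}

#' Hard-voting consensus of ranked feature lists
#'
#' Takes the top-\code{top_k} prefix of each ranked list and returns the
#' features appearing in at least \code{min_votes} prefixes (default: all of
#' them, i.e. the intersection), ordered by mean rank across the lists that
#' contain them. An empty consensus is returned with a warning, not an
#' error.
#'
#' @param lists List (>= 2) of character vectors of feature ids, each
#'   ranked best-first.
#' @param top_k Prefix length considered per list (default 15).
#' @param min_votes Minimum number of lists a feature must appear in
#'   (default: \code{length(lists)}).
#' @return Character vector of consensus feature ids.
#' @export
hard_vote <- function(lists, top_k = 15, min_votes = length(lists)) {
  stopifnot(length(lists) >= 2, min_votes >= 1, min_votes <= length(lists))
  if (top_k < 1) stop("top_k must be >= 1")
  if (top_k > min(lengths(lists))) stop("top_k exceeds shortest list length")
  tops <- lapply(lists, utils::head, top_k)
  all_feat <- unique(unlist(tops))
  votes <- vapply(all_feat, function(f)
    sum(vapply(tops, function(l) f %in% l, logical(1))), integer(1))
  cons <- all_feat[votes >= min_votes]
  if (!length(cons)) {
    warning("hard vote produced an empty consensus set")
    return(character(0))
  }
  mean_rank <- vapply(cons, function(f) {
    r <- vapply(tops, function(l) match(f, l), numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  cons[order(mean_rank, cons)]
}

#' Two-group one-way ANOVA F statistic
#'
#' F = between-group mean square / within-group mean square with
#' df = (1, n - 2); p is the upper-tail F probability. Identical to the
#' squared pooled-variance two-sample t statistic. Zero within-group
#' variance with equal means is undefined (error); with unequal means the
#' p = 0 convention applies (with a warning).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Named list with \code{f_value}, \code{p_value}, \code{df}.
#' @export
anova_f <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  ma <- mean(group_a); mb <- mean(group_b)
  m <- mean(c(group_a, group_b))
  ssb <- na * (ma - m)^2 + nb * (mb - m)^2
  ssw <- sum((group_a - ma)^2) + sum((group_b - mb)^2)
  df2 <- na + nb - 2
  if (ssw == 0) {
    if (ssb == 0) stop("F undefined: zero variance within and between groups")
    warning("zero within-group variance with unequal means; p = 0")
    return(list(f_value = Inf, p_value = 0, df = c(1, df2)))
  }
  f <- (ssb / 1) / (ssw / df2)
  list(f_value = f, p_value = f_to_p(f, 1, df2), df = c(1, df2))
}

#' Upper-tail F probability
#'
#' @param f_value F statistic, >= 0.
#' @param df1,df2 Degrees of freedom, >= 1.
#' @return p-value.
#' @export
f_to_p <- function(f_value, df1, df2) {
  if (any(f_value < 0)) stop("negative F statistic")
  stopifnot(df1 >= 1, df2 >= 1)
  stats::pf(f_value, df1, df2, lower.tail = FALSE)
}

#' Per-feature log2 fold change of group mean CPM
#'
#' log2 of (mean success CPM + pseudocount) / (mean failure CPM +
#' pseudocount).
#'
#' @param cpm Feature-by-sample CPM matrix (linear scale).
#' @param labels Labels per sample; \code{"success"} vs \code{"failure"}.
#' @param pseudocount Added to both group means (default 1).
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(cpm, labels, pseudocount = 1) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("success", "failure")))
  ms <- rowMeans(cpm[, labels == "success", drop = FALSE])
  mf <- rowMeans(cpm[, labels == "failure", drop = FALSE])
  log2((ms + pseudocount) / (mf + pseudocount))
}

#' Volcano-style deregulation flags
#'
#' A feature is deregulated when |log2FC| >= \code{fc_cutoff} and
#' p <= \code{p_cutoff} (both boundaries inclusive).
#'
#' @param scores data.frame with \code{log2fc} and \code{p_value} columns.
#' @param fc_cutoff Absolute log2 fold-change cutoff (default 1).
#' @param p_cutoff p-value cutoff (default 0.05).
#' @return Logical vector of flags.
#' @export
volcano_flags <- function(scores, fc_cutoff = 1, p_cutoff = 0.05) {
  abs(scores$log2fc) >= fc_cutoff & scores$p_value <= p_cutoff
}

#' Full ensemble feature-selection stage
#'
#' Orchestrates pre-filtering, the three importance rankers, top-k hard
#' voting, the normality gate, one-way ANOVA F arbitration (on rank-
#' transformed values when the gate rejects normality) and the volcano
#' flags. Operates on exploratory-phase samples only.
#'
#' @param mat Feature-by-sample log-CPM matrix (log2(CPM + pseudocount)).
#' @param labels Per-sample labels, \code{"success"} / \code{"failure"}.
#' @param top_k Prefix length for hard voting (default 15).
#' @param min_votes Votes required for consensus (default 3 = all rankers).
#' @param seed Integer seed driving all three rankers.
#' @param var_quantile Pre-filter variance quantile.
#' @param fc_cutoff,p_cutoff Volcano cutoffs.
#' @param pseudocount Pseudocount that produced the log-CPM values (used to
#'   invert them to linear CPM for fold changes).
#' @return data.frame of class \code{"feature_scores"}: one row per
#'   surviving feature with importances, per-model ranks, log2fc, F, p,
#'   \code{consensus} and \code{deregulated} flags; consensus rows first,
#'   ordered by decreasing F. Attributes: \code{consensus} (ids ordered by
#'   F), \code{gate} (normality verdict).
#' @export
select_features <- function(mat, labels, top_k = 15, min_votes = 3,
                            seed = 1L, var_quantile = 0.1,
                            fc_cutoff = 1, p_cutoff = 0.05,
                            pseudocount = 1) {
  if (top_k < 1) stop("top_k must be >= 1")
  labels <- as.character(labels)
  stopifnot(ncol(mat) == length(labels))
  mat <- prefilter(mat, var_quantile = var_quantile)

  kinds <- c("boosted_trees", "l1_linear", "extra_random_trees")
  ranked <- lapply(seq_along(kinds), function(i)
    rank_features(mat, labels, kinds[i], seed = seed + i - 1L))
  names(ranked) <- kinds
  cons <- hard_vote(lapply(ranked, `[[`, "feature_id"), top_k = top_k,
                    min_votes = min_votes)

  # normality gate on within-group-centered values of the consensus
  # features (all surviving features when the consensus is empty)
  gate_feats <- if (length(cons)) cons else rownames(mat)
  resid <- unlist(lapply(unique(labels), function(g) {
    sub <- mat[gate_feats, labels == g, drop = FALSE]
    as.numeric(sub - rowMeans(sub))
  }))
  gate <- normality_gate(resid)

  is_s <- labels == "success"
  fp <- t(vapply(rownames(mat), function(f) {
    v <- mat[f, ]
    if (gate == "nonparametric") v <- rank(v)
    a <- anova_f(v[is_s], v[!is_s])
    c(a$f_value, a$p_value)
  }, numeric(2)))

  cpm <- pmax(2^mat - pseudocount, 0)
  l2fc <- log2_fold_change(cpm, labels, pseudocount = pseudocount)

  tab <- data.frame(
    feature_id = rownames(mat),
    importance_xgb = imp_of(ranked$boosted_trees, rownames(mat)),
    importance_lasso = imp_of(ranked$l1_linear, rownames(mat)),
    importance_xtrees = imp_of(ranked$extra_random_trees, rownames(mat)),
    rank_xgb = rank_of(ranked$boosted_trees, rownames(mat)),
    rank_lasso = rank_of(ranked$l1_linear, rownames(mat)),
    rank_xtrees = rank_of(ranked$extra_random_trees, rownames(mat)),
    log2fc = unname(l2fc[rownames(mat)]),
    f_value = fp[, 1], p_value = fp[, 2],
    consensus = rownames(mat) %in% cons,
    stringsAsFactors = FALSE, row.names = NULL)
  tab$deregulated <- volcano_flags(tab, fc_cutoff, p_cutoff)
  tab <- tab[order(-tab$consensus, -tab$f_value, tab$feature_id), ]
  rownames(tab) <- NULL

  cons_by_f <- tab$feature_id[tab$consensus]
  structure(tab, consensus = cons_by_f, gate = gate,
            class = c("feature_scores", "data.frame"))
}

imp_of <- function(ranked, feats) {
  i <- match(feats, ranked$feature_id)
  ranked$importance[i]
}

rank_of <- function(ranked, feats) {
  i <- match(feats, ranked$feature_id)
  ranked$rank[i]
}
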