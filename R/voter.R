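# Hard-voting ensemble classifier: RBF support-vector machine, random
# forest, and a stochastic-gradient-descent linear classifier, combined by
# majority vote on standardized log-CPM features.

#' Fit the hard-voting ensemble classifier
#'
#' Trains three base models on standardized features: an RBF support-vector
#' classifier (cost 1, gamma = 1/(d * var(x)) as fitted on the standardized
#' training matrix), a 500-tree random forest, and a hinge-loss linear
#' classifier trained by stochastic gradient descent (1000 epochs).
#' Prediction is the majority (hard) vote of the three; with three voters a
#' tie is impossible. Deterministic given the seed.
#'
#' @param x Feature-by-sample matrix restricted to the selected features
#'   (typically log-CPM of the consensus markers).
#' @param labels Per-sample class labels, \code{"success"} (positive) /
#'   \code{"failure"}.
#' @param seed Integer seed.
#' @return An object of class \code{"snc_voter"}.
#' @examples
#' set.seed(1)
#' x <- rbind(f1 = c(rnorm(10, 3), rnorm(10, -3)),
#'            f2 = c(rnorm(10, -3), rnorm(10, 3)))
#' colnames(x) <- paste0("s", 1:20)
#' y <- rep(c("success", "failure"), each = 10)
#' fit <- fit_voting_classifier(x, y, seed = 1)
#' mean(predict(fit, x)$predicted_label == y)  # 1
#' @export
fit_voting_classifier <- function(x, labels, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(ncol(x) == length(labels), nrow(x) >= 1)
  if (length(unique(labels)) < 2) stop("training labels contain one class")
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")

  xt <- t(x)                              # samples x features
  ctr <- colMeans(xt)
  scl <- apply(xt, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(xt, center = ctr, scale = scl)
  y <- factor(labels, levels = c("failure", "success"))

  set.seed(as.integer(seed))
  gamma <- 1 / (ncol(xs) * max(stats::var(as.vector(xs)), 1e-12))
  svm_fit <- e1071::svm(xs, y, kernel = "radial", cost = 1, gamma = gamma,
                        scale = FALSE)
  rf_fit <- randomForest::randomForest(xs, y, ntree = 500)
  sgd_fit <- sgd_hinge_fit(xs, as.integer(y == "success") * 2L - 1L,
                           seed = seed)

  structure(list(features = rownames(x), center = ctr, scale = scl,
                 svm = svm_fit, rf = rf_fit, sgd = sgd_fit,
                 levels = levels(y), seed = as.integer(seed),
                 n_train = ncol(x)),
            class = "snc_voter")
}

# Pegasos-style SGD for the hinge loss: w <- (1 - eta*lambda) w + eta*y_i*x_i
# on margin violations, eta_t = 1/(lambda*t), bias unregularized.
sgd_hinge_fit <- function(x, y, lambda = 1e-4, epochs = 1000, seed = 1L) {
  n <- nrow(x); d <- ncol(x)
  w <- numeric(d); b <- 0; t <- 0
  set.seed(as.integer(seed) + 7L)
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1
      eta <- 1 / (lambda * (t + 1e3))
      if (y[i] * (sum(w * x[i, ]) + b) < 1) {
        w <- (1 - eta * lambda) * w + eta * y[i] * x[i, ]
        b <- b + eta * y[i]
      } else {
        w <- (1 - eta * lambda) * w
      }
    }
  }
  list(w = w, b = b)
}

sgd_hinge_predict <- function(fit, x) {
  drop(x %*% fit$w) + fit$b
}

#' Predict method for the hard-voting classifier
#'
#' @param object An \code{snc_voter} fit.
#' @param newdata Feature-by-sample matrix containing (at least) the
#'   training features as rows.
#' @param ... Unused.
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{predicted_label}, per-base-model votes (\code{vote_svm},
#'   \code{vote_rf}, \code{vote_sgd}), and \code{score} (fraction of votes
#'   for success).
#' @export
predict.snc_voter <- function(object, newdata, ...) {
  missing <- setdiff(object$features, rownames(newdata))
  if (length(missing))
    stop("features missing from newdata: ", paste(missing, collapse = ", "))
  ids <- colnames(newdata)
  if (is.null(ids)) ids <- paste0("sample", seq_len(ncol(newdata)))
  if (ncol(newdata) == 0)
    return(data.frame(sample_id = character(), predicted_label = character(),
                      vote_svm = character(), vote_rf = character(),
                      vote_sgd = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  xs <- scale(t(newdata[object$features, , drop = FALSE]),
              center = object$center, scale = object$scale)
  v_svm <- as.character(stats::predict(object$svm, xs))
  v_rf <- as.character(stats::predict(object$rf, xs))
  v_sgd <- ifelse(sgd_hinge_predict(object$sgd, xs) >= 0,
                  "success", "failure")
  votes <- cbind(v_svm, v_rf, v_sgd)
  n_succ <- rowSums(votes == "success")
  data.frame(sample_id = ids,
             predicted_label = ifelse(n_succ >= 2, "success", "failure"),
             vote_svm = v_svm, vote_rf = v_rf, vote_sgd = v_sgd,
             score = n_succ / 3,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.snc_voter <- function(x, ...) {
  cat("Hard-voting ensemble classifier (SVM + random forest + SGD)\n")
  cat("  features (", length(x$features), "): ",
      paste(utils::head(x$features, 10), collapse = ", "),
      if (length(x$features) > 10) ", ..." else "", "\n", sep = "")
  cat("  trained on ", x$n_train, " samples; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.snc_voter <- function(object, ...) {
  cat("Hard-voting ensemble classifier\n")
  cat("Base models:\n")
  cat("  SVM: RBF kernel, cost 1, gamma ",
      format(object$svm$gamma, digits = 4), "\n", sep = "")
  cat("  Random forest: ", object$rf$ntree, " trees, OOB error ",
      format(mean(object$rf$err.rate[object$rf$ntree, "OOB"]), digits = 4),
      "\n", sep = "")
  cat("  SGD linear: hinge loss, |w| = ",
      format(sqrt(sum(object$sgd$w^2)), digits = 4), "\n", sep = "")
  cat("Features: ", paste(object$features, collapse = ", "), "\n", sep = "")
  invisible(object)
}
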