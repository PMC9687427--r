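test_that("the voting classifier separates well-separated blobs", {
  b <- blob_data(n_per = 10, d = 2, sep = 3, seed = 1)
  fit <- fit_voting_classifier(b$x, b$y, seed = 1)
  pred <- predict(fit, b$x)
  expect_equal(pred$predicted_label, b$y)
  # all three base models agree -> unanimous tallies, scores in {0, 1}
  expect_true(all(pred$vote_svm == pred$vote_rf &
                  pred$vote_rf == pred$vote_sgd))
  expect_true(all(pred$score %in% c(0, 1)))

  expect_error(fit_voting_classifier(b$x, rep("success", 20)), "one class")
  expect_error(fit_voting_classifier(b$x[, 1:3],
                                     c("success", "success", "failure")),
               "2 samples per class")
})

test_that("majority vote of three models never ties", {
  b <- blob_data(n_per = 8, d = 3, sep = 1, seed = 2)
  fit <- fit_voting_classifier(b$x, b$y, seed = 2)
  pred <- predict(fit, b$x)
  expect_true(all(pred$score != 0.5))
  expect_equal(pred$predicted_label, ifelse(pred$score > 0.5,
                                            "success", "failure"))
})

test_that("resubstitution accuracy is near-perfect on strong training data", {
  p <- prepared_scenario("strong", 1)
  cons <- attr(strong_selection(), "consensus")
  fit <- fit_voting_classifier(p$logcpm[cons, p$expl], p$y_expl, seed = 1)
  pred <- predict(fit, p$logcpm[, p$expl])
  expect_gte(mean(pred$predicted_label == p$y_expl), 0.98)
})

test_that("leave-one-out produces one prediction per sample", {
  b <- blob_data(n_per = 6, d = 3, sep = 3, seed = 3)
  pt <- loo_predict(b$x, b$y, features = rownames(b$x), nested = FALSE,
                    seed = 1)
  expect_equal(nrow(pt), 12L)
  expect_equal(pt$true_label, b$y)
  expect_true(all(pt$correct))
})

test_that("single-class folds fall back to the majority class", {
  set.seed(4)
  x <- matrix(rnorm(20), nrow = 5,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:4)))
  y <- c("success", "success", "success", "failure")
  expect_message(
    pt <- loo_predict(x, y, features = rownames(x), nested = FALSE,
                      seed = 1),
    "majority fallback")
  expect_equal(pt$predicted_label[4], "success")
})

test_that("holdout prediction uses the frozen model consistently", {
  b <- blob_data(n_per = 10, d = 3, sep = 3, seed = 5)
  fit <- fit_voting_classifier(b$x, b$y, seed = 1)
  resub <- predict(fit, b$x)
  # a validation sample that is a copy of a training sample gets the same call
  copy <- b$x[, 4, drop = FALSE]
  colnames(copy) <- "v1"
  hold <- predict_holdout(fit, copy, labels = b$y[4])
  expect_equal(hold$predicted_label, resub$predicted_label[4])
  expect_true(hold$correct)

  empty <- predict_holdout(fit, b$x[, integer(0), drop = FALSE])
  expect_equal(nrow(empty), 0L)

  bad <- b$x[1:2, , drop = FALSE]
  expect_error(predict_holdout(fit, bad), "missing from newdata")
})

test_that("PCA projection recovers structure and variance fractions", {
  # rank-1 matrix: first component carries all variance
  u <- matrix(1:6, ncol = 1); v <- matrix(c(1, -2, 3, 0.5), nrow = 1)
  m1 <- u %*% v
  rownames(m1) <- paste0("f", 1:6); colnames(m1) <- paste0("s", 1:4)
  pr <- pca_project(t(m1), n_components = 2)
  expect_equal(pr$explained[1], 1, tolerance = 1e-10)

  # known principal axis: points along y = 2x with tiny noise
  set.seed(6)
  tt <- rnorm(50)
  m2 <- rbind(x = tt + rnorm(50, sd = 1e-4),
              y = 2 * tt + rnorm(50, sd = 1e-4))
  colnames(m2) <- paste0("s", 1:50)
  pr2 <- pca_project(m2, n_components = 1)
  axis <- pr2$rotation[, 1]
  target <- c(1, 2) / sqrt(5)
  ang <- acos(min(1, abs(sum(axis * target)))) * 180 / pi
  expect_lt(ang, 1)

  # fractions sorted, sum <= 1; rotation invariance of the spectrum
  set.seed(7)
  m3 <- matrix(rnorm(120), nrow = 6,
               dimnames = list(paste0("f", 1:6), paste0("s", 1:20)))
  pr3 <- pca_project(m3, n_components = 4)
  expect_false(is.unsorted(rev(pr3$explained)))
  expect_lte(sum(pr3$explained), 1)
  q <- qr.Q(qr(matrix(rnorm(36), 6)))
  pr3r <- pca_project(q %*% m3, n_components = 4)
  expect_equal(pr3r$explained, pr3$explained, tolerance = 1e-9)

  expect_error(pca_project(m3, n_components = 10), "exceeds")
})

test_that("LDA projection separates planted groups and matches the reference", {
  set.seed(8)
  d <- 6
  mk_group <- function(shift, n) matrix(rnorm(d * n, mean = 0, sd = 1),
                                        nrow = d) + shift
  x2 <- cbind(mk_group(0, 12), mk_group(4, 12))
  rownames(x2) <- paste0("f", 1:d); colnames(x2) <- paste0("s", 1:24)
  g2 <- rep(c("a", "b"), each = 12)
  pr <- lda_project(x2, g2)
  ca <- pr$coords[g2 == "a", 1]; cb <- pr$coords[g2 == "b", 1]
  expect_true(max(ca) < min(cb) || max(cb) < min(ca))

  # agreement with MASS::lda on the first discriminant direction
  ml <- MASS::lda(t(x2), grouping = g2)
  ref <- as.numeric(scale(t(x2), scale = FALSE) %*% ml$scaling[, 1])
  expect_gt(abs(stats::cor(pr$coords[, 1], ref)), 0.99)

  # four planted groups: clear clusters; permuted labels: no separation
  shifts <- c(0, 5, 10, 15)
  x4 <- do.call(cbind, lapply(shifts, function(s) mk_group(s, 8)))
  rownames(x4) <- paste0("f", 1:d); colnames(x4) <- paste0("s", 1:32)
  g4 <- rep(letters[1:4], each = 8)
  pr4 <- lda_project(x4, g4)
  expect_gte(silhouette_score(pr4$coords, g4), 0.5)
  set.seed(9)
  gp <- sample(g4)
  prp <- lda_project(x4, gp)
  expect_lt(silhouette_score(prp$coords, gp), 0.2)
})

test_that("anomaly detection flags label-swapped samples", {
  set.seed(10)
  d <- 5; n_per <- 12
  x <- cbind(matrix(rnorm(d * n_per, mean = 3), nrow = d),
             matrix(rnorm(d * n_per, mean = -3), nrow = d))
  rownames(x) <- paste0("f", 1:d)
  colnames(x) <- paste0("s", 1:(2 * n_per))
  y <- rep(c("success", "failure"), each = n_per)
  expect_length(detect_anomalies(x, y), 0L)

  y_swapped <- y
  y_swapped[c(3, 15)] <- rev(y[c(3, 15)])
  flagged <- detect_anomalies(x, y_swapped)
  expect_setequal(as.character(flagged), c("s3", "s15"))

  expect_error(detect_anomalies(x[, 1:3], y[1:3]))
  xm <- matrix(1, 4, 5, dimnames = list(NULL, paste0("s", 1:5)))
  expect_error(detect_anomalies(xm, c("success", "success", "failure",
                                      "failure", "failure")),
               "identical")
})
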