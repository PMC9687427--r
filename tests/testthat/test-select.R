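test_that("pre-filtering removes zero-count, constant and low-variance features", {
  set.seed(3)
  m <- rbind(matrix(rnorm(90 * 10), nrow = 90),
             matrix(0, nrow = 8, ncol = 10),
             matrix(5, nrow = 2, ncol = 10))
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  out <- prefilter(m)
  expect_false(any(paste0("f", 91:100) %in% rownames(out)))
  # brute-force enumeration of the survivors
  v <- apply(m, 1, stats::var)
  thr <- stats::quantile(v[v > 0], 0.1, names = FALSE)
  expect_equal(nrow(out), sum(v > 0 & v >= thr))
  expect_error(prefilter(matrix(1, 5, 4)), "no features survive")
})

test_that("normality gate separates gaussian from skewed residuals", {
  set.seed(1)
  x <- rnorm(200); y <- rexp(200)
  expect_equal(normality_gate(x), "parametric")
  expect_equal(normality_gate(y), "nonparametric")
  # agreement with the reference test on the same draws
  expect_equal(normality_gate(x) == "parametric",
               stats::shapiro.test(x)$p.value >= 0.05)
  expect_equal(normality_gate(y) == "nonparametric",
               stats::shapiro.test(y)$p.value < 0.05)
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("one-way ANOVA F matches hand computation and the t-test identity", {
  eq <- anova_f(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$f_value, 0)
  expect_equal(eq$p_value, 1)

  # a = [1,2,3], b = [3,4,5]: SSB = 6, SSW = 4, df = (1,4) -> F = 6
  a <- anova_f(c(1, 2, 3), c(3, 4, 5))
  expect_equal(a$f_value, 6)
  expect_equal(a$df, c(1, 4))
  expect_equal(a$p_value, 0.0705, tolerance = 1e-3)

  # F equals the squared pooled-variance t statistic, p the two-sided t p
  set.seed(8)
  for (r in 1:10) {
    ga <- rnorm(5 + r); gb <- rnorm(7, mean = 0.5)
    res <- anova_f(ga, gb)
    tt <- stats::t.test(ga, gb, var.equal = TRUE)
    expect_equal(res$f_value, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }

  expect_error(anova_f(c(1, 1), c(1, 1)), "undefined")
  expect_warning(res0 <- anova_f(c(1, 1), c(2, 2)), "p = 0")
  expect_equal(res0$p_value, 0)
})

test_that("F-to-p conversion is a proper survival function", {
  expect_equal(f_to_p(0, 1, 46), 1)
  expect_error(f_to_p(-1, 1, 46), "negative F")
  fs <- seq(0, 20, by = 0.5)
  ps <- f_to_p(fs, 1, 46)
  expect_true(all(diff(ps) < 0))
})

test_that("log2 fold change on group mean CPM", {
  cpm <- rbind(fA = c(40, 40, 9, 9), fB = c(7, 7, 7, 7))
  y <- c("success", "success", "failure", "failure")
  fc <- log2_fold_change(cpm, y)
  expect_equal(unname(fc["fA"]), log2(41 / 10))
  expect_equal(unname(fc["fB"]), 0)
  # antisymmetry under label swap
  ysw <- c("failure", "failure", "success", "success")
  expect_equal(unname(log2_fold_change(cpm, ysw)["fA"]),
               -unname(fc["fA"]))
})

test_that("volcano flags apply inclusive joint cutoffs", {
  sc <- data.frame(log2fc = c(1.2, 0.5, -1.0, 2.0),
                   p_value = c(0.01, 0.001, 0.05, 0.06))
  expect_equal(volcano_flags(sc), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("hard voting returns the ordered intersection of top-k prefixes", {
  l1 <- paste0("f", 1:30)
  expect_equal(sort(hard_vote(list(l1, l1, l1))), sort(paste0("f", 1:15)))

  # three lists sharing only f1..f7 within their top-15
  shared <- paste0("f", 1:7)
  mk <- function(extra) c(shared, extra, paste0("pad", 1:30))
  lists <- list(mk(paste0("a", 1:8)), mk(paste0("b", 1:8)),
                mk(paste0("c", 1:8)))
  expect_setequal(hard_vote(lists), shared)

  # invariance to list order
  expect_equal(hard_vote(lists), hard_vote(rev(lists)))

  expect_warning(
    empty <- hard_vote(list(paste0("x", 1:20), paste0("y", 1:20),
                            paste0("z", 1:20))),
    "empty consensus")
  expect_length(empty, 0)

  expect_error(hard_vote(list(paste0("x", 1:5), paste0("y", 1:20)),
                         top_k = 10), "shortest list")

  # looser voting: features in at least 2 of 3 prefixes
  l2 <- c(paste0("f", 1:10), paste0("b", 1:20))
  loose <- hard_vote(list(l1, l1, l2), top_k = 15, min_votes = 2)
  expect_true(all(paste0("f", 1:15) %in% loose))
})

test_that("every ranker places all planted markers in its top 15 on strong data", {
  p <- prepared_scenario("strong", 1)
  m <- prefilter(p$logcpm[, p$expl])
  mk <- p$ds$truth$marker_ids
  for (kind in c("boosted_trees", "l1_linear", "extra_random_trees")) {
    r <- rank_features(m, p$y_expl, kind, seed = 1)
    expect_true(all(mk %in% utils::head(r$feature_id, 15)),
                label = paste(kind, "top-15 contains all markers"))
    # determinism
    r2 <- rank_features(m, p$y_expl, kind, seed = 1)
    expect_identical(r$feature_id, r2$feature_id)
  }
})

test_that("marker ranks collapse to chance under label permutation", {
  p <- prepared_scenario("strong", 1)
  m <- prefilter(p$logcpm[, p$expl])
  mk <- p$ds$truth$marker_ids
  set.seed(99)
  mean_ranks <- vapply(1:20, function(i) {
    yp <- sample(p$y_expl)
    r <- rank_features(m, yp, "extra_random_trees", seed = i)
    mean(match(mk, r$feature_id))
  }, numeric(1))
  # not better (lower) than the chance level (n+1)/2 at alpha = 0.05
  tt <- stats::t.test(mean_ranks, mu = (nrow(m) + 1) / 2,
                      alternative = "less")
  expect_gt(tt$p.value, 0.05)
})

test_that("constant features get zero importance in the L1 model", {
  set.seed(5)
  m <- rbind(matrix(rnorm(200), nrow = 10), const = 3)
  rownames(m)[1:10] <- paste0("f", 1:10)
  colnames(m) <- paste0("s", 1:20)
  y <- rep(c("success", "failure"), 10)
  # small-fold glmnet emits a sample-size caution irrelevant to the check
  r <- suppressWarnings(rank_features(m, y, "l1_linear", seed = 1))
  expect_equal(r$importance[r$feature_id == "const"], 0)
  expect_error(rank_features(m, rep("success", 20), "l1_linear"),
               "two classes")
})

test_that("select_features output is coherent", {
  p <- prepared_scenario("strong", 1)
  sc <- strong_selection()
  expect_s3_class(sc, "feature_scores")
  # consensus features pass prefilter and appear consensus-first, F-sorted
  surv <- rownames(prefilter(p$logcpm[, p$expl]))
  cons <- attr(sc, "consensus")
  expect_true(all(cons %in% surv))
  expect_equal(sc$feature_id[seq_along(cons)], cons)
  expect_false(is.unsorted(rev(sc$f_value[seq_along(cons)])))
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1))
  # per-model ranks are permutations
  expect_setequal(sc$rank_xgb, seq_len(nrow(sc)))
  expect_error(select_features(p$logcpm[, p$expl], p$y_expl, top_k = 0),
               "top_k")
})
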