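# Shared fixtures. Expensive objects (full-size scenario runs) are computed
# once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

prepared_scenario <- function(preset, seed) {
  key <- paste(preset, seed, sep = "_")
  if (!exists(key, envir = .fixture_env)) {
    ds <- generate_dataset(make_scenario(preset), seed = seed)
    meta <- ds$metadata
    bg <- meta$sample_id[meta$background]
    fac <- tmm_factors(ds$counts, exclude = bg)
    logcpm <- normalize_cpm(ds$counts, fac, log = TRUE)
    expl <- meta$sample_id[!meta$background & meta$split == "exploratory"]
    val <- meta$sample_id[!meta$background & meta$split == "validation"]
    assign(key, list(
      ds = ds, meta = meta, fac = fac, logcpm = logcpm,
      expl = expl, val = val,
      y_expl = meta$label[match(expl, meta$sample_id)],
      y_val = meta$label[match(val, meta$sample_id)]
    ), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

strong_selection <- function() {
  if (!exists("strong_sel", envir = .fixture_env)) {
    p <- prepared_scenario("strong", 1)
    assign("strong_sel",
           select_features(p$logcpm[, p$expl], p$y_expl, seed = 1),
           envir = .fixture_env)
  }
  get("strong_sel", envir = .fixture_env)
}

# two well-separated Gaussian blobs, features as rows
blob_data <- function(n_per = 10, d = 3, sep = 3, seed = 1) {
  set.seed(seed)
  x <- cbind(matrix(rnorm(d * n_per, mean = sep), nrow = d),
             matrix(rnorm(d * n_per, mean = -sep), nrow = d))
  rownames(x) <- paste0("f", seq_len(d))
  colnames(x) <- paste0("s", seq_len(2 * n_per))
  list(x = x, y = rep(c("success", "failure"), each = n_per))
}

# mean silhouette width, computed directly from pairwise distances
silhouette_score <- function(coords, groups) {
  groups <- as.character(groups)
  d <- as.matrix(stats::dist(coords))
  s <- vapply(seq_along(groups), function(i) {
    own <- which(groups == groups[i])
    a <- if (length(own) > 1) mean(d[i, setdiff(own, i)]) else 0
    b <- min(vapply(setdiff(unique(groups), groups[i]), function(g)
      mean(d[i, groups == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
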