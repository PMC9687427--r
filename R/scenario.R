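#' Scenario presets for synthetic spent-blastocyst-medium sncRNA datasets
#'
#' A scenario config describes the study design the generator emulates:
#' 32 implantation-success and 28 implantation-failure embryo samples plus
#' 3 background medium samples, a catalogue of features of which a small
#' number are planted differential markers, negative-binomial counts with
#' log-normal library sizes, and a stratified exploratory/validation split.
#'
#' Presets: \code{"default"} (|log2FC| = 2.5, dispersion 0.3),
#' \code{"strong"} (|log2FC| = 3.0, dispersion 0.1) and
#' \code{"moderate_noise"} (|log2FC| = 1.5, dispersion 0.4). All presets
#' share n_success = 32, n_failure = 28, n_background = 3, 1000 features,
#' 7 markers, mean library size 1e6 (CV 0.3), background attenuation 0.05,
#' exploratory fraction 0.8 and baseline means log-uniform on [5, 500].
#'
#' @param name Preset name: one of \code{"default"}, \code{"strong"},
#'   \code{"moderate_noise"}.
#' @param ... Named overrides for individual config fields (e.g.
#'   \code{marker_log2fc = 0} for a null scenario).
#' @return A list of class \code{"scenario_config"}.
#' @examples
#' cfg <- make_scenario("default")
#' cfg$n_success   # 32
#' @export
make_scenario <- function(name = c("default", "strong", "moderate_noise"),
                          ...) {
  if (length(name) != 1L || !name %in% c("default", "strong", "moderate_noise"))
    stop("unknown scenario preset: ", paste(name, collapse = ", "))
  cfg <- list(
    name = name,
    n_success = 32L,
    n_failure = 28L,
    n_background = 3L,
    n_features = 1000L,
    n_markers = 7L,
    marker_log2fc = switch(name, default = 2.5, strong = 3.0,
                           moderate_noise = 1.5),
    baseline_mean_range = c(5, 500),
    dispersion = switch(name, default = 0.3, strong = 0.1,
                        moderate_noise = 0.4),
    libsize_mean = 1e6,
    libsize_cv = 0.3,
    background_scale = 0.05,
    exploratory_fraction = 0.8,
    seed = 42L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_scenario(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

validate_scenario <- function(cfg) {
  stopifnot(
    cfg$n_success >= 1, cfg$n_failure >= 1, cfg$n_background >= 1,
    cfg$n_features >= 1, cfg$n_markers >= 0,
    cfg$n_markers <= cfg$n_features,
    cfg$dispersion > 0,
    cfg$exploratory_fraction > 0, cfg$exploratory_fraction < 1,
    cfg$background_scale > 0, cfg$background_scale <= 1,
    length(cfg$baseline_mean_range) == 2,
    cfg$baseline_mean_range[1] > 0,
    cfg$baseline_mean_range[2] >= cfg$baseline_mean_range[1]
  )
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario config '", x$name, "'\n", sep = "")
  cat("  samples: ", x$n_success, " success / ", x$n_failure, " failure / ",
      x$n_background, " background\n", sep = "")
  cat("  features: ", x$n_features, " (", x$n_markers,
      " markers, |log2FC| = ", x$marker_log2fc, ")\n", sep = "")
  cat("  NB dispersion: ", x$dispersion, "; library size ",
      format(x$libsize_mean, big.mark = ","), " (CV ", x$libsize_cv, ")\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic sncRNA count dataset
#'
#' Draws per-feature baseline means log-uniformly from the configured range,
#' plants \code{n_markers} differential markers whose success-group mean is
#' baseline * 2^(direction * marker_log2fc) (5 up-regulated, 2 down-regulated
#' in success by convention), scales means by per-sample log-normal library
#' size factors, and draws counts from a negative binomial with
#' variance mu + dispersion * mu^2. Background medium samples carry all
#' baseline means attenuated by \code{background_scale}. The
#' exploratory/validation split is stratified by outcome at
#' \code{exploratory_fraction}; day (4/5) and storage (fresh/cryo) covariates
#' are assigned at random. Fully reproducible from the seed.
#'
#' @param config A \code{scenario_config} from \code{\link{make_scenario}}.
#' @param seed Integer seed; defaults to \code{config$seed}.
#' @return A list of class \code{"snc_dataset"} with elements
#'   \code{counts} (feature x sample integer matrix, features named
#'   \code{mir_*}/\code{pir_*}), \code{metadata} (data.frame with
#'   \code{sample_id}, \code{label}, \code{day}, \code{storage},
#'   \code{split}, \code{background}), and \code{truth} (marker ids,
#'   per-marker direction, true labels).
#' @examples
#' ds <- generate_dataset(make_scenario("default"), seed = 42)
#' dim(ds$counts)  # 1000 x 63
#' @export
generate_dataset <- function(config, seed = config$seed) {
  validate_scenario(config)
  set.seed(as.integer(seed))
  nf <- config$n_features
  ns <- config$n_success; nfl <- config$n_failure; nb <- config$n_background
  n_embryo <- ns + nfl

  # two size classes in the id, roughly 30% miRNA-like / 70% piRNA-like
  n_mir <- max(1L, round(0.3 * nf))
  feat_ids <- c(sprintf("mir_%04d", seq_len(n_mir)),
                sprintf("pir_%04d", seq_len(nf - n_mir)))

  lo <- log(config$baseline_mean_range[1])
  hi <- log(config$baseline_mean_range[2])
  baseline <- exp(stats::runif(nf, lo, hi))

  marker_idx <- sort(sample.int(nf, config$n_markers))
  marker_dir <- rep(1L, config$n_markers)
  if (config$n_markers >= 3L)           # 5 up / 2 down at the preset size
    marker_dir[seq(config$n_markers - 1L, config$n_markers)] <- -1L

  labels <- c(rep("success", ns), rep("failure", nfl), rep("background", nb))
  sample_ids <- c(sprintf("S%02d", seq_len(ns)),
                  sprintf("F%02d", seq_len(nfl)),
                  sprintf("B%02d", seq_len(nb)))

  # per-sample expected totals: log-normal with stated mean and CV
  cv <- config$libsize_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(config$libsize_mean) - sdlog^2 / 2
  lib_factor <- stats::rlnorm(ns + nfl + nb, meanlog, sdlog) / config$libsize_mean

  mu <- matrix(baseline, nrow = nf, ncol = ns + nfl + nb)
  mu[marker_idx, seq_len(ns)] <-
    mu[marker_idx, seq_len(ns)] * 2^(marker_dir * config$marker_log2fc)
  if (nb > 0)
    mu[, n_embryo + seq_len(nb)] <- mu[, n_embryo + seq_len(nb)] *
      config$background_scale
  mu <- sweep(mu, 2, lib_factor, `*`)

  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
    nrow = nf, dimnames = list(feat_ids, sample_ids))

  split <- rep(NA_character_, length(labels))
  n_expl_s <- round(config$exploratory_fraction * ns)
  n_expl_f <- round(config$exploratory_fraction * nfl)
  expl <- c(sample(which(labels == "success"), n_expl_s),
            sample(which(labels == "failure"), n_expl_f))
  split[labels != "background"] <- "validation"
  split[expl] <- "exploratory"

  meta <- data.frame(
    sample_id = sample_ids,
    label = labels,
    day = ifelse(labels == "background", NA_integer_,
                 sample(c(4L, 5L), length(labels), replace = TRUE)),
    storage = ifelse(labels == "background", NA_character_,
                     sample(c("fresh", "cryo"), length(labels),
                            replace = TRUE)),
    split = split,
    background = labels == "background",
    stringsAsFactors = FALSE
  )

  structure(list(
    counts = counts,
    metadata = meta,
    truth = list(marker_ids = feat_ids[marker_idx],
                 marker_direction = stats::setNames(marker_dir,
                                                    feat_ids[marker_idx]),
                 true_labels = stats::setNames(labels, sample_ids)),
    config = config
  ), class = "snc_dataset")
}

#' @export
print.snc_dataset <- function(x, ...) {
  cat("Synthetic sncRNA dataset: ", nrow(x$counts), " features x ",
      ncol(x$counts), " samples\n", sep = "")
  print(table(x$metadata$label))
  cat("markers:", paste(x$truth$marker_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Generate synthetic alignment-like read records
#'
#' Produces record-level fixtures for the counting rules: each read has a
#' length drawn uniformly on 15--40 nt and maps to 1--3 reference features
#' (multi-mapping emulated), with an alignment overlap equal to the read
#' length. Reproducible from the seed.
#'
#' @param config A \code{scenario_config} (supplies the feature universe).
#' @param n_reads Number of records to generate.
#' @param seed Integer seed.
#' @return A data.frame with columns \code{read_id}, \code{length},
#'   \code{hits} (comma-separated feature ids), \code{overlap}.
#' @export
generate_read_records <- function(config, n_reads, seed = config$seed) {
  stopifnot(n_reads >= 0)
  set.seed(as.integer(seed))
  if (n_reads == 0)
    return(data.frame(read_id = character(), length = integer(),
                      hits = character(), overlap = integer(),
                      stringsAsFactors = FALSE))
  nf <- config$n_features
  n_mir <- max(1L, round(0.3 * nf))
  feat_ids <- c(sprintf("mir_%04d", seq_len(n_mir)),
                sprintf("pir_%04d", seq_len(nf - n_mir)))
  len <- sample(15:40, n_reads, replace = TRUE)
  nhits <- sample(1:3, n_reads, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  hits <- vapply(nhits, function(k)
    paste(sample(feat_ids, k), collapse = ","), character(1))
  data.frame(read_id = sprintf("r%06d", seq_len(n_reads)),
             length = len, hits = hits, overlap = len,
             stringsAsFactors = FALSE)
}
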