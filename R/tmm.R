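# Trimmed mean of M-values (TMM) between-sample normalization, written out
# from the canonical definition: log-ratios (M) and log-abundances (A) of
# library-size-scaled counts against a reference sample, doubly trimmed,
# averaged with inverse asymptotic binomial variance weights.

#' Select the TMM reference sample
#'
#' Returns the sample whose 75th percentile of nonzero library-size-scaled
#' counts is closest to the mean of that quantity across samples (ties go to
#' the first sample in column order).
#'
#' @param mat Feature-by-sample count matrix.
#' @param exclude Sample ids (column names) to exclude from the choice,
#'   e.g. background medium controls.
#' @return A sample id (column name).
#' @export
select_reference <- function(mat, exclude = NULL) {
  cand <- setdiff(colnames(mat), exclude)
  if (length(cand) < 2) stop("need at least 2 candidate samples")
  sub <- mat[, cand, drop = FALSE]
  if (all(sub == 0)) stop("all-zero count matrix")
  q75 <- apply(sub, 2, function(y) {
    v <- y / sum(y)
    v <- v[v > 0]
    if (!length(v)) return(NA_real_)
    stats::quantile(v, 0.75, names = FALSE)
  })
  cand[which.min(abs(q75 - mean(q75, na.rm = TRUE)))]
}

#' TMM scaling factor of one sample against a reference
#'
#' Using only features nonzero in both samples, computes
#' M = log2((y_s/N_s)/(y_r/N_r)) and A = (1/2) log2((y_s/N_s)(y_r/N_r)),
#' discards the top and bottom \code{trim_m} fraction by M and
#' \code{trim_a} fraction by A, and returns 2 to the power of the weighted
#' mean of the surviving M values, with weights the inverse asymptotic
#' binomial variances (N_s - y_s)/(N_s y_s) + (N_r - y_r)/(N_r y_r).
#' A sample against itself gives exactly 1.
#'
#' @param sample,reference Count vectors of equal length.
#' @param lib_sample,lib_reference Library sizes; default to the vector sums.
#' @param trim_m Trim fraction on M (log-ratios), default 0.30.
#' @param trim_a Trim fraction on A (log-abundances), default 0.05.
#' @return Positive scaling factor.
#' @export
tmm_factor <- function(sample, reference,
                       lib_sample = sum(sample),
                       lib_reference = sum(reference),
                       trim_m = 0.30, trim_a = 0.05) {
  stopifnot(length(sample) == length(reference),
            lib_sample > 0, lib_reference > 0)
  keep <- sample > 0 & reference > 0
  ys <- sample[keep]; yr <- reference[keep]
  if (!length(ys)) stop("no features nonzero in both samples")
  ps <- ys / lib_sample; pr <- yr / lib_reference
  M <- log2(ps / pr)
  A <- 0.5 * log2(ps * pr)
  if (max(abs(M)) < 1e-10) return(1)
  # asymptotic binomial variance of M; the weight is its inverse
  v <- (lib_sample - ys) / (lib_sample * ys) +
       (lib_reference - yr) / (lib_reference * yr)

  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  surv <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(surv)) stop("no features survive trimming")
  f <- sum(M[surv] / v[surv]) / sum(1 / v[surv])
  if (!is.finite(f)) stop("non-finite TMM factor")
  2^f
}

#' TMM normalization factors for a count matrix
#'
#' Computes a TMM factor per column against the selected reference, then
#' rescales so the geometric mean of the factors over the non-excluded
#' samples is 1. Excluded samples (background controls) still receive
#' factors but do not influence the reference choice or the geometric-mean
#' constraint.
#'
#' @inheritParams select_reference
#' @inheritParams tmm_factor
#' @return A list of class \code{"tmm_factors"}: \code{reference_sample},
#'   \code{factors} (named, geometric mean 1 over non-excluded samples),
#'   \code{effective_libsizes} (library size x factor).
#' @export
tmm_factors <- function(mat, exclude = NULL, trim_m = 0.30, trim_a = 0.05) {
  ref_id <- select_reference(mat, exclude = exclude)
  ref <- mat[, ref_id]
  f <- vapply(colnames(mat), function(s)
    if (s == ref_id) 1 else
      tmm_factor(mat[, s], ref, trim_m = trim_m, trim_a = trim_a),
    numeric(1))
  core <- setdiff(colnames(mat), exclude)
  f <- f / exp(mean(log(f[core])))
  libs <- colSums(mat)
  structure(list(reference_sample = ref_id,
                 factors = f,
                 effective_libsizes = libs * f),
            class = "tmm_factors")
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("TMM factors (reference: ", x$reference_sample, ")\n", sep = "")
  print(round(x$factors, 4))
  invisible(x)
}

#' Counts-per-million on TMM-effective library sizes
#'
#' @param mat Count matrix the factors were computed on.
#' @param factors A \code{tmm_factors} object (or NULL for plain CPM).
#' @param log If TRUE, return log2(CPM + pseudocount).
#' @param pseudocount Added before the log (default 1).
#' @return Matrix of (log-)CPM values.
#' @export
normalize_cpm <- function(mat, factors = NULL, log = FALSE, pseudocount = 1) {
  eff <- if (is.null(factors)) colSums(mat)
         else factors$effective_libsizes[colnames(mat)]
  if (any(eff <= 0)) stop("zero effective library size")
  cpm <- sweep(mat, 2, eff, `/`) * 1e6
  if (log) log2(cpm + pseudocount) else cpm
}

#' Per-batch median centering of log-CPM values
#'
#' Optional post-hoc batch adjustment: for each feature, subtracts the
#' within-batch median and adds back the feature's overall median. Off by
#' default in the pipeline; the canonical TMM path is the tested default.
#'
#' @param logmat Feature-by-sample log-CPM matrix.
#' @param batch Factor of batch labels, one per column.
#' @return Adjusted matrix.
#' @export
batch_center <- function(logmat, batch) {
  stopifnot(length(batch) == ncol(logmat))
  batch <- as.factor(batch)
  grand <- apply(logmat, 1, stats::median)
  out <- logmat
  for (b in levels(batch)) {
    j <- which(batch == b)
    med <- apply(logmat[, j, drop = FALSE], 1, stats::median)
    out[, j] <- logmat[, j, drop = FALSE] - med + grand
  }
  out
}
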