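# Record-level counting rules: size-class filtering and fractional division
# of multi-mapped reads into their mapped references.

#' Size-filter read records by sncRNA class
#'
#' Keeps records whose length falls in the expected size window of the RNA
#' class: 19--25 nt for miRNA, 24--32 nt for piRNA (bounds inclusive; the
#' 24--25 nt zone belongs to both classes). When the records carry an
#' \code{overlap} column, records with alignment overlap below 19 nt are
#' dropped as well.
#'
#' @param records data.frame with columns \code{read_id}, \code{length},
#'   \code{hits}, optionally \code{overlap}.
#' @param rna_class \code{"miRNA"} or \code{"piRNA"}.
#' @param min_overlap Minimum alignment overlap when an \code{overlap}
#'   column is present (nt).
#' @return The filtered data.frame.
#' @export
size_filter <- function(records, rna_class, min_overlap = 19L) {
  range <- switch(rna_class,
    miRNA = c(19L, 25L),
    piRNA = c(24L, 32L),
    stop("unknown RNA class: ", rna_class))
  keep <- records$length >= range[1] & records$length <= range[2]
  if (!is.null(records$overlap))
    keep <- keep & records$overlap >= min_overlap
  records[keep, , drop = FALSE]
}

#' Fractionally count multi-mapped reads
#'
#' Each record contributes 1/|hits| to every feature it maps to, so the
#' total assigned mass equals the number of records exactly.
#'
#' @param records data.frame with a \code{hits} column of comma-separated
#'   feature ids (each record must have at least one hit).
#' @return Named numeric vector of per-feature fractional counts.
#' @export
fractional_count <- function(records) {
  if (nrow(records) == 0) return(stats::setNames(numeric(0), character(0)))
  hit_list <- strsplit(records$hits, ",", fixed = TRUE)
  nh <- lengths(hit_list)
  if (any(nh == 0 | vapply(hit_list, function(h) any(!nzchar(h)), logical(1))))
    stop("record with empty hit set")
  feats <- unlist(hit_list, use.names = FALSE)
  w <- rep(1 / nh, nh)
  out <- tapply(w, feats, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Assemble per-sample fractional counts into a count matrix
#'
#' @param count_list Named list of per-feature count vectors, one per sample.
#' @param sample_ids Sample ids giving column order; defaults to list names.
#' @return Feature-by-sample numeric matrix, missing features filled with 0.
#' @export
assemble_matrix <- function(count_list, sample_ids = names(count_list)) {
  if (anyDuplicated(sample_ids)) stop("duplicate sample id")
  if (length(count_list) != length(sample_ids))
    stop("count_list and sample_ids lengths differ")
  feats <- sort(unique(unlist(lapply(count_list, names))))
  mat <- matrix(0, nrow = length(feats), ncol = length(sample_ids),
                dimnames = list(feats, sample_ids))
  for (j in seq_along(count_list)) {
    v <- count_list[[j]]
    mat[names(v), j] <- v
  }
  mat
}

#' Read a record fixture from TSV
#'
#' Columns: read_id, length, hits (comma-separated), optional overlap.
#' @param path File path.
#' @return data.frame of read records.
#' @export
read_records_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a count matrix as TSV (features as rows, samples as columns)
#' @param mat Feature-by-sample matrix.
#' @param path File path.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
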