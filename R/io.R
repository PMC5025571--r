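#' Read a count matrix from TSV or CSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs;
#' remaining cells must be non-negative integers. Duplicate gene IDs,
#' negative values and non-integer cells are rejected with the offending
#' gene/sample named.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.csv` is comma-separated,
#'   anything else tab-separated), `"tsv"`, or `"csv"`.
#' @param conditions optional condition vector or path to a two-column
#'   (sample_id, condition) TSV; see [read_conditions()].
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv"),
                        conditions = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- switch(format,
                auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
                tsv = "\t",
                csv = ",")
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed header: need gene IDs plus at least ",
                          "one sample column", call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(mat), nrow = nrow(mat)))), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell for gene %s, sample %s",
                 ids[bad[1L]], colnames(mat)[bad[2L]]), call. = FALSE)
  }
  rownames(mat) <- ids
  if (any(mat < 0, na.rm = TRUE)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count for gene %s, sample %s",
                 ids[bad[1L]], colnames(mat)[bad[2L]]), call. = FALSE)
  }
  if (any(mat != floor(mat), na.rm = TRUE)) {
    bad <- which(mat != floor(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count for gene %s, sample %s",
                 ids[bad[1L]], colnames(mat)[bad[2L]]), call. = FALSE)
  }
  if (is.character(conditions) && length(conditions) == 1L &&
      file.exists(conditions)) {
    conditions <- read_conditions(conditions, colnames(mat))
  }
  count_matrix(mat, conditions = conditions)
}

#' Read a sample-to-condition assignment
#'
#' Two-column tab-separated file (`sample_id`, `condition`), with or
#' without a header. Every sample of the count matrix must appear exactly
#' once; the returned vector is ordered to match `sample_ids`.
#'
#' @param path file path.
#' @param sample_ids character vector of the count matrix's sample IDs.
#' @return Character vector of conditions, in `sample_ids` order.
#' @export
read_conditions <- function(path, sample_ids) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (identical(tolower(as.character(df[1L, 1L])), "sample_id")) {
    df <- df[-1L, , drop = FALSE]
  }
  if (ncol(df) < 2L) stop("condition file needs two columns ",
                          "(sample_id, condition)", call. = FALSE)
  idx <- match(sample_ids, as.character(df[[1L]]))
  if (anyNA(idx)) {
    stop("condition file missing sample(s): ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  as.character(df[[2L]])[idx]
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts()]: gene IDs in the first column (`gene_id`),
#' sample IDs as the header.
#'
#' @param cm a [count_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a sample-to-condition assignment to TSV
#'
#' @param cm a [count_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_conditions <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(sample_id = colnames(cm$counts),
                   condition = as.character(cm$conditions),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write normalization factors to TSV
#'
#' One row per sample with columns `sample_id`, `condition`, `method`,
#' `relative_factor`, `adjusted_factor`, `effective_library_size`,
#' `size_factor`. Factors are printed with 7 decimal places; components a
#' method does not define are `NA`.
#'
#' @param result a `norm_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_factors <- function(result, path) {
  stopifnot(inherits(result, "norm_result"))
  df <- as.data.frame(result)
  for (col in c("relative_factor", "adjusted_factor",
                "effective_library_size", "size_factor")) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA,
                        sprintf("%.7f", df[[col]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
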