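#' Construct a validated count matrix with condition labels
#'
#' The basic container of the package: a genes x samples matrix of
#' non-negative read counts together with a per-sample condition assignment.
#' Rows are genes (indexed by unique gene IDs), columns are samples (unique
#' sample IDs); each sample belongs to exactly one condition, and the
#' replicate index of a sample is its ordinal within its condition.
#'
#' Counts are expected to be integers. Real-valued input (e.g. expected
#' counts from an upstream estimator) is accepted with a warning; negative
#' or non-finite values are rejected. Every column sum (library size) must
#' be strictly positive.
#'
#' @param counts numeric matrix (or object coercible to one), genes in rows,
#'   samples in columns. Dimnames are used as gene/sample IDs; defaults
#'   (`gene_1..G`, `sample_1..S`) are generated when absent.
#' @param conditions character or factor of length `ncol(counts)` assigning
#'   each sample to a condition. Default: every sample its own condition
#'   (the no-replicate design). Condition level order is order of first
#'   appearance.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (numeric matrix with dimnames) and `conditions` (factor, levels in
#'   order of appearance).
#' @examples
#' cm <- count_matrix(matrix(c(1, 4, 9, 4, 16, 36), nrow = 3),
#'                    conditions = c("ctrl", "trt"))
#' library_sizes(cm)
#' @export
count_matrix <- function(counts, conditions = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("counts must be numeric", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts must be finite and non-missing", call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (any(counts != floor(counts))) {
    warning("non-integer counts supplied; treating as expected counts",
            call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample IDs", call. = FALSE)
  }
  if (is.null(conditions)) {
    conditions <- colnames(counts)
  }
  if (length(conditions) != ncol(counts)) {
    stop(sprintf("conditions has length %d but there are %d samples",
                 length(conditions), ncol(counts)), call. = FALSE)
  }
  conditions <- as.character(conditions)
  conditions <- factor(conditions, levels = unique(conditions))
  obj <- structure(list(counts = counts, conditions = conditions),
                   class = "count_matrix")
  library_sizes(obj)  # validates positive column sums
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples, %d condition(s)\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$conditions)))
  tab <- table(x$conditions)
  cat("  samples per condition:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Per-sample library sizes (column sums)
#'
#' The library size of sample `(k, r)` is its total read count,
#' `N_kr = sum_g X_gkr`.
#'
#' @param cm a [count_matrix()].
#' @return Named numeric vector of positive column sums, one per sample.
#' @export
library_sizes <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  n <- colSums(cm$counts)
  if (any(n <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(cm$counts)[n <= 0], collapse = ", "), call. = FALSE)
  }
  n
}

#' Pre-normalize counts by library size
#'
#' Divides each column by its library size: `Y_gkr = X_gkr / N_kr`. Every
#' column of the result sums to 1; the values are the per-gene shares of
#' each library, the common currency of the TMM and MRN methods.
#'
#' @param cm a [count_matrix()].
#' @return Numeric matrix of the same shape as `cm$counts`, columns summing
#'   to 1.
#' @export
pre_normalize <- function(cm) {
  n <- library_sizes(cm)
  sweep(cm$counts, 2L, n, "/")
}
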