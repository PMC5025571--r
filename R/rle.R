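#' RLE pseudo-reference sample
#'
#' Per-gene geometric mean of raw counts across all samples. A gene with a
#' zero count in any sample gets reference value 0 (the geometric mean is
#' annihilated by a zero) and is excluded from the downstream median.
#'
#' @param cm a [count_matrix()].
#' @return Named numeric vector, one value per gene, zero where any sample
#'   has a zero count.
#' @export
rle_pseudo_reference <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  # log(0) = -Inf propagates through the row mean; exp(-Inf) = 0
  exp(rowMeans(log(cm$counts)))
}

#' RLE size factors (median-of-ratios)
#'
#' For each sample, the median over usable genes (pseudo-reference > 0,
#' i.e. genes expressed in every sample) of the ratio of the raw count to
#' the pseudo-reference. RLE defines no separate adjustment step: the size
#' factor is the median ratio itself, and it carries the library-size
#' component (deeper libraries get larger factors).
#'
#' @param cm a [count_matrix()].
#' @return Named per-sample numeric vector of size factors.
#' @export
rle_size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  .rle_factors(cm$counts)
}

# median-of-ratios on a bare non-negative matrix
.rle_factors <- function(x) {
  ref <- exp(rowMeans(log(x)))
  usable <- ref > 0
  if (!any(usable)) {
    stop("no gene expressed in all samples", call. = FALSE)
  }
  apply(x[usable, , drop = FALSE], 2L,
        function(col) median_of(col / ref[usable]))
}

#' Normalize counts by per-sample factors
#'
#' `Z_gkr = X_gkr / f_kr`, dividing each column by its size factor.
#'
#' @param cm a [count_matrix()].
#' @param f per-sample positive factors.
#' @return Numeric matrix of normalized counts.
#' @export
rle_normalize <- function(cm, f) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(f) != ncol(cm$counts) || any(f <= 0)) {
    stop("f must be one positive factor per sample", call. = FALSE)
  }
  sweep(cm$counts, 2L, f, "/")
}

#' RLE factors as computed by the TMM toolchain
#'
#' The TMM reference implementation also offers an RLE mode, but it runs
#' the median-of-ratios on \emph{pre-normalized} counts (each column
#' divided by its library size) and then rescales the factors to unit
#' product. The result therefore differs from [rle_size_factors()]: it is
#' `rle_size_factors(X) / N`, rescaled so its geometric mean is 1. This
#' function reproduces that variant so the two conventions can be compared
#' directly.
#'
#' @param cm a [count_matrix()].
#' @return Named per-sample numeric vector with geometric mean 1.
#' @export
rle_edger_style_factors <- function(cm) {
  f <- .rle_factors(pre_normalize(cm))
  adjust_to_unit_product(f)
}

#' Full RLE normalization
#'
#' @param cm a [count_matrix()].
#' @param edger_style if `TRUE`, use [rle_edger_style_factors()] (median of
#'   ratios on pre-normalized counts, rescaled to unit product) instead of
#'   the raw-count median-of-ratios.
#' @return A `norm_result`. RLE defines no adjusted factors and no
#'   effective library sizes; `relative_factors` and `size_factors` are the
#'   same vector.
#' @examples
#' cm <- count_matrix(matrix(c(1, 4, 9, 4, 16, 36), nrow = 3))
#' rle_normalization(cm)$size_factors  # (0.5, 2)
#' @export
rle_normalization <- function(cm, edger_style = FALSE) {
  f <- if (edger_style) rle_edger_style_factors(cm) else rle_size_factors(cm)
  usable <- sum(rle_pseudo_reference(cm) > 0)
  new_norm_result("RLE",
                  sample_ids = colnames(cm$counts),
                  conditions = cm$conditions,
                  relative_factors = f,
                  size_factors = f,
                  usable_genes = stats::setNames(
                    rep(usable, ncol(cm$counts)), colnames(cm$counts)),
                  settings = list(edger_style = edger_style))
}
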