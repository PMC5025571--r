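#' Geometric mean of a positive vector
#'
#' Computed in the log domain, `exp(mean(log(x)))`, so products of many
#' large or small factors do not overflow.
#'
#' @param x numeric vector, all entries strictly positive.
#' @return Positive scalar.
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) stop("empty vector", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires strictly positive finite values",
         call. = FALSE)
  }
  exp(mean(log(x)))
}

#' Median with midpoint interpolation
#'
#' The central order statistic for odd length; the arithmetic mean of the
#' two central order statistics for even length (the convention of
#' [stats::median()]). Errors on an empty vector rather than returning
#' `NA`, because an empty vector here always means no usable genes survived
#' a filtering step.
#'
#' @param x non-empty numeric vector.
#' @return Scalar median.
#' @export
median_of <- function(x) {
  if (length(x) == 0L) stop("no usable genes", call. = FALSE)
  stats::median(x)
}

#' Trimmed mean with a per-tail trimming proportion
#'
#' Drops `floor(trim_frac * n)` values from each tail of the sorted vector
#' and returns the arithmetic mean of the remainder. `trim_frac = 0.5` is
#' the exact median: trimming half of the values from each tail leaves the
#' central order statistic(s), so the limit is [median_of()] and is
#' special-cased to it (reference TMM implementations can only approach
#' this limit with trim fractions slightly below 0.5).
#'
#' @param x non-empty numeric vector.
#' @param trim_frac proportion in `[0, 0.5]` removed from each tail.
#' @return Scalar.
#' @export
trimmed_mean <- function(x, trim_frac) {
  if (length(trim_frac) != 1L || is.na(trim_frac) ||
      trim_frac < 0 || trim_frac > 0.5) {
    stop("trim_frac must be a single value in [0, 0.5]", call. = FALSE)
  }
  if (length(x) == 0L) stop("no usable genes", call. = FALSE)
  if (trim_frac == 0.5) return(median_of(x))
  n <- length(x)
  k <- floor(trim_frac * n)
  s <- sort(x)
  mean(s[(k + 1L):(n - k)])
}

#' M- and A-values of one sample against a reference
#'
#' For each gene, given pre-normalized values `y_sample` and `y_ref`, the
#' M-value is the log2 fold change `log2(y_sample / y_ref)` and the A-value
#' the log2 mean abundance `0.5 * log2(y_sample * y_ref)`. Both are defined
#' only where both inputs are strictly positive; elsewhere the gene is
#' flagged invalid and `m`/`a` are `NA`.
#'
#' @param y_sample,y_ref numeric vectors of equal length (pre-normalized
#'   columns).
#' @return List with numeric vectors `m`, `a` and logical vector `valid`.
#' @export
ma_values <- function(y_sample, y_ref) {
  if (length(y_sample) != length(y_ref)) {
    stop("y_sample and y_ref must have equal length", call. = FALSE)
  }
  valid <- y_sample > 0 & y_ref > 0
  m <- a <- rep(NA_real_, length(y_sample))
  m[valid] <- log2(y_sample[valid] / y_ref[valid])
  a[valid] <- 0.5 * log2(y_sample[valid] * y_ref[valid])
  list(m = m, a = a, valid = valid)
}
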