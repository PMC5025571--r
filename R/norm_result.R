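#' @keywords internal
#' @noRd
new_norm_result <- function(method, sample_ids, conditions,
                            relative_factors, adjusted_factors = NULL,
                            effective_library_sizes = NULL,
                            size_factors, usable_genes, settings = list()) {
  stopifnot(all(is.finite(size_factors)), all(size_factors > 0),
            all(is.finite(relative_factors)), all(relative_factors > 0))
  structure(list(method = method,
                 sample_ids = sample_ids,
                 conditions = conditions,
                 relative_factors = stats::setNames(relative_factors, sample_ids),
                 adjusted_factors = if (!is.null(adjusted_factors))
                   stats::setNames(adjusted_factors, sample_ids),
                 effective_library_sizes = if (!is.null(effective_library_sizes))
                   stats::setNames(effective_library_sizes, sample_ids),
                 size_factors = stats::setNames(size_factors, sample_ids),
                 usable_genes = usable_genes,
                 settings = settings),
            class = "norm_result")
}

#' @export
print.norm_result <- function(x, ...) {
  cat(sprintf("%s normalization, %d samples\n", x$method,
              length(x$size_factors)))
  cat("size factors:\n")
  print(round(x$size_factors, 7))
  invisible(x)
}

#' Tabulate a normalization result
#'
#' @param x a `norm_result` as returned by [tmm_normalization()],
#'   [rle_normalization()] or [mrn_normalization()].
#' @param ... unused.
#' @return A data.frame with one row per sample and columns `sample_id`,
#'   `condition`, `method`, `relative_factor`, `adjusted_factor`,
#'   `effective_library_size`, `size_factor`. Components a method does not
#'   define are `NA`.
#' @export
as.data.frame.norm_result <- function(x, ...) {
  s <- length(x$size_factors)
  data.frame(sample_id = x$sample_ids,
             condition = as.character(x$conditions),
             method = rep(x$method, s),
             relative_factor = unname(x$relative_factors),
             adjusted_factor = if (is.null(x$adjusted_factors))
               rep(NA_real_, s) else unname(x$adjusted_factors),
             effective_library_size = if (is.null(x$effective_library_sizes))
               rep(NA_real_, s) else unname(x$effective_library_sizes),
             size_factor = unname(x$size_factors),
             stringsAsFactors = FALSE)
}
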