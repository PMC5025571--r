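#' Select the TMM reference sample
#'
#' With `ref_sample = "auto"` the reference is the sample whose upper
#' quartile (75th percentile, linearly interpolated) of pre-normalized
#' values is closest to the mean upper quartile across samples, ties broken
#' by lowest column index. An explicit sample index or sample ID is passed
#' through after range checking.
#'
#' @param y pre-normalized matrix from [pre_normalize()].
#' @param ref_sample `"auto"`, a column index, or a sample ID.
#' @return Integer column index of the reference sample.
#' @export
select_reference <- function(y, ref_sample = "auto") {
  s <- ncol(y)
  if (is.character(ref_sample) && length(ref_sample) == 1L &&
      ref_sample != "auto") {
    idx <- match(ref_sample, colnames(y))
    if (is.na(idx)) stop("unknown reference sample: ", ref_sample,
                         call. = FALSE)
    return(idx)
  }
  if (is.numeric(ref_sample)) {
    idx <- as.integer(ref_sample)
    if (idx < 1L || idx > s) {
      stop(sprintf("reference index %d out of range 1..%d", idx, s),
           call. = FALSE)
    }
    return(idx)
  }
  uq <- apply(y, 2L, stats::quantile, probs = 0.75, names = FALSE)
  which.min(abs(uq - mean(uq)))
}

#' TMM relative scaling factors
#'
#' For each sample, the relative size of its transcriptome versus a
#' reference sample, estimated from the genes surviving a double trim:
#' genes with invalid M/A-values (a zero in either column) are dropped,
#' then the `m_trim` fraction of genes with the most extreme M-values and
#' the `a_trim` fraction with the most extreme A-values are removed from
#' each tail (rank-based, ties by original gene order), keeping the
#' intersection. The factor is either the arithmetic mean of the surviving
#' pre-normalized count ratios (`mean_scale = "ratio"`) or
#' `2^mean(M)` over the survivors (`mean_scale = "log2"`, the scale used by
#' the reference TMM implementation). Weighting is intentionally not
#' implemented: the unweighted trimmed mean is the quantity under study.
#'
#' `m_trim = 0.5` is the exact-median limit: the A-trim is applied first
#' and the factor is the median of the surviving ratios (or `2^median(M)`),
#' which is what makes the no-replicate TMM/MRN equivalence hold to machine
#' precision.
#'
#' The reference sample's factor is exactly 1.
#'
#' @param cm a [count_matrix()].
#' @param ref_sample reference sample: `"auto"` (upper-quartile rule),
#'   index, or sample ID.
#' @param m_trim fraction of M-values trimmed from each tail, in `[0, 0.5]`
#'   (default 0.30).
#' @param a_trim fraction of A-values trimmed from each tail, in `[0, 0.5]`
#'   (default 0.05).
#' @param mean_scale `"ratio"` or `"log2"`.
#' @return List with `tau` (named per-sample factors, reference exactly 1),
#'   `ref` (reference column index) and `usable_genes` (per-sample count of
#'   genes entering each mean/median).
#' @export
tmm_relative_factors <- function(cm, ref_sample = "auto",
                                 m_trim = 0.30, a_trim = 0.05,
                                 mean_scale = c("ratio", "log2")) {
  mean_scale <- match.arg(mean_scale)
  for (tr in c(m_trim, a_trim)) {
    if (length(tr) != 1L || is.na(tr) || tr < 0 || tr > 0.5) {
      stop("trim fractions must lie in [0, 0.5]", call. = FALSE)
    }
  }
  y <- pre_normalize(cm)
  ref <- select_reference(y, ref_sample)
  s <- ncol(y)
  tau <- numeric(s)
  usable <- integer(s)
  for (j in seq_len(s)) {
    if (j == ref) {
      tau[j] <- 1
      usable[j] <- sum(y[, j] > 0)
      next
    }
    ma <- ma_values(y[, j], y[, ref])
    v <- which(ma$valid)
    if (length(v) == 0L) {
      stop("no gene with positive counts in both sample ",
           colnames(y)[j], " and the reference", call. = FALSE)
    }
    m <- ma$m[v]
    a <- ma$a[v]
    ratios <- y[v, j] / y[v, ref]
    n <- length(v)
    ka <- floor(a_trim * n)
    keep_a <- if (ka > 0L) order(a)[(ka + 1L):(n - ka)] else seq_len(n)
    if (m_trim == 0.5) {
      if (length(keep_a) == 0L) {
        stop("no usable genes after trimming for sample ", colnames(y)[j],
             call. = FALSE)
      }
      tau[j] <- if (mean_scale == "ratio") median_of(ratios[keep_a])
                else 2^median_of(m[keep_a])
      usable[j] <- length(keep_a)
      next
    }
    km <- floor(m_trim * n)
    keep_m <- order(m)[(km + 1L):(n - km)]
    keep <- intersect(keep_m, keep_a)
    if (length(keep) == 0L) {
      stop("no usable genes after trimming for sample ", colnames(y)[j],
           call. = FALSE)
    }
    tau[j] <- if (mean_scale == "ratio") mean(ratios[keep])
              else 2^mean(m[keep])
    usable[j] <- length(keep)
  }
  list(tau = stats::setNames(tau, colnames(y)), ref = ref,
       usable_genes = stats::setNames(usable, colnames(y)))
}

#' Adjust factors to multiply to 1
#'
#' Divides each factor by the geometric mean of all factors, so the
#' adjusted factors have geometric mean exactly 1 (product 1).
#'
#' @param tau numeric vector of strictly positive factors.
#' @return Numeric vector of the same length, geometric mean 1.
#' @export
adjust_to_unit_product <- function(tau) {
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("factors must be strictly positive and finite", call. = FALSE)
  }
  tau / geometric_mean(tau)
}

#' Effective library sizes
#'
#' `e_kr = tau_adj_kr * N_kr`: the library size rescaled by the adjusted
#' relative scaling factor, i.e. the depth a sample effectively has once
#' its transcriptome size relative to the other samples is accounted for.
#'
#' @param tau_adj adjusted per-sample factors.
#' @param n per-sample library sizes.
#' @return Numeric vector of effective library sizes.
#' @export
tmm_effective_library_sizes <- function(tau_adj, n) {
  if (length(tau_adj) != length(n)) {
    stop("factor and library-size vectors must have equal length",
         call. = FALSE)
  }
  tau_adj * n
}

#' Counts-per-million on effective library sizes
#'
#' `Z_gkr = X_gkr / e_kr * 1e6`.
#'
#' @param cm a [count_matrix()].
#' @param e per-sample effective library sizes (all positive).
#' @return Numeric matrix of CPM values.
#' @export
tmm_cpm <- function(cm, e) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(e <= 0)) stop("effective library sizes must be positive",
                        call. = FALSE)
  sweep(cm$counts, 2L, e, "/") * 1e6
}

#' Full TMM normalization
#'
#' Runs the complete TMM pipeline: pre-normalization, reference selection,
#' relative scaling factors ([tmm_relative_factors()]), unit-product
#' adjustment, effective library sizes, and size factors. The TMM size
#' factor \emph{is} the adjusted relative scaling factor; by design it
#' carries no library-size component (library sizes enter only through the
#' effective library sizes used for CPM), so TMM size factors are
#' uncorrelated with sequencing depth.
#'
#' @inheritParams tmm_relative_factors
#' @return A `norm_result` with `relative_factors` (tau),
#'   `adjusted_factors`, `effective_library_sizes`, and `size_factors`
#'   (equal to the adjusted factors).
#' @examples
#' cm <- count_matrix(matrix(c(1, 4, 9, 4, 16, 36), nrow = 3))
#' tmm_normalization(cm, ref_sample = 1, m_trim = 0.5, a_trim = 0)
#' @export
tmm_normalization <- function(cm, ref_sample = "auto",
                              m_trim = 0.30, a_trim = 0.05,
                              mean_scale = c("ratio", "log2")) {
  mean_scale <- match.arg(mean_scale)
  rel <- tmm_relative_factors(cm, ref_sample, m_trim, a_trim, mean_scale)
  tau_adj <- adjust_to_unit_product(rel$tau)
  n <- library_sizes(cm)
  e <- tmm_effective_library_sizes(tau_adj, n)
  new_norm_result("TMM",
                  sample_ids = colnames(cm$counts),
                  conditions = cm$conditions,
                  relative_factors = rel$tau,
                  adjusted_factors = tau_adj,
                  effective_library_sizes = e,
                  size_factors = tau_adj,
                  usable_genes = rel$usable_genes,
                  settings = list(ref_sample = rel$ref, m_trim = m_trim,
                                  a_trim = a_trim, mean_scale = mean_scale))
}
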