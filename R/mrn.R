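#' Per-condition means of pre-normalized counts
#'
#' Averages the pre-normalized columns over the replicates of each
#' condition: `Ybar_gk = mean_r(Y_gkr)`. With a single replicate the
#' condition mean is the pre-normalized column itself.
#'
#' @param y pre-normalized matrix from [pre_normalize()].
#' @param conditions factor of length `ncol(y)`.
#' @return Genes x conditions numeric matrix, columns named by condition
#'   level.
#' @export
condition_means <- function(y, conditions) {
  conditions <- as.factor(conditions)
  stopifnot(length(conditions) == ncol(y))
  out <- vapply(levels(conditions),
                function(k) rowMeans(y[, conditions == k, drop = FALSE]),
                numeric(nrow(y)))
  dimnames(out) <- list(rownames(y), levels(conditions))
  out
}

#' MRN relative transcriptome sizes
#'
#' For each condition, the median over usable genes of the ratio of its
#' mean pre-normalized profile to the reference condition's:
#' `tau_k = median_g(Ybar_gk / Ybar_g,ref)`. A gene is usable for
#' condition `k` when both condition means are strictly positive; this
#' rule reduces to the RLE usable set (genes expressed in every sample)
#' in the two-condition no-replicate design, which is what makes the
#' RLE/MRN size-factor equality exact there. The reference condition's
#' factor is exactly 1. MRN factors are per condition, not per sample:
#' all replicates of a condition share one relative transcriptome size.
#'
#' @param cm a [count_matrix()].
#' @param ref_condition reference condition label; default is the first
#'   condition in order of appearance.
#' @return List with `tau` (named per-condition factors, reference exactly
#'   1), `ref_condition`, and `usable_genes` (per-condition counts).
#' @export
mrn_relative_factors <- function(cm, ref_condition = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  lev <- levels(cm$conditions)
  if (is.null(ref_condition)) ref_condition <- lev[1L]
  if (!ref_condition %in% lev) {
    stop("unknown reference condition: ", ref_condition, call. = FALSE)
  }
  ybar <- condition_means(pre_normalize(cm), cm$conditions)
  yref <- ybar[, ref_condition]
  tau <- numeric(length(lev))
  usable <- integer(length(lev))
  names(tau) <- names(usable) <- lev
  for (k in lev) {
    if (k == ref_condition) {
      tau[k] <- 1
      usable[k] <- sum(yref > 0)
      next
    }
    ok <- ybar[, k] > 0 & yref > 0
    if (!any(ok)) {
      stop("no usable gene for condition ", k,
           " against reference ", ref_condition, call. = FALSE)
    }
    tau[k] <- median_of(ybar[ok, k] / yref[ok])
    usable[k] <- sum(ok)
  }
  list(tau = tau, ref_condition = ref_condition, usable_genes = usable)
}

#' Full MRN normalization
#'
#' Combines the per-condition relative transcriptome sizes with the
#' per-sample library sizes: effective library sizes `e_kr = tau_k * N_kr`
#' and size factors `f_kr = e_kr / geometric_mean(e)`, which by
#' construction have geometric mean 1. Replicates of a condition share the
#' same relative factor but not the same size factor, because their
#' library sizes differ.
#'
#' @inheritParams mrn_relative_factors
#' @return A `norm_result` with per-sample `relative_factors` (the
#'   condition's tau broadcast to its samples), `effective_library_sizes`
#'   and `size_factors` (geometric mean 1).
#' @examples
#' cm <- count_matrix(matrix(c(1, 4, 9, 4, 16, 36), nrow = 3))
#' mrn_normalization(cm)$size_factors  # (0.5, 2)
#' @export
mrn_normalization <- function(cm, ref_condition = NULL) {
  rel <- mrn_relative_factors(cm, ref_condition)
  n <- library_sizes(cm)
  tau_s <- rel$tau[as.character(cm$conditions)]
  e <- tau_s * n
  f <- e / geometric_mean(e)
  new_norm_result("MRN",
                  sample_ids = colnames(cm$counts),
                  conditions = cm$conditions,
                  relative_factors = tau_s,
                  effective_library_sizes = e,
                  size_factors = f,
                  usable_genes = rel$usable_genes[as.character(cm$conditions)],
                  settings = list(ref_condition = rel$ref_condition))
}

#' Normalize counts by MRN size factors
#'
#' `Z_gkr = X_gkr / f_kr`; identical mechanics to [rle_normalize()], kept
#' as a named step of the MRN pipeline.
#'
#' @param cm a [count_matrix()].
#' @param f per-sample positive size factors.
#' @return Numeric matrix of normalized counts.
#' @export
mrn_normalize <- function(cm, f) {
  rle_normalize(cm, f)
}
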