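#' @keywords internal
#' @noRd
.rel_discrepancy <- function(a, b) {
  d <- abs(a - b)
  scale <- pmax(abs(a), abs(b))
  out <- ifelse(d == 0, 0, d / scale)
  max(out)
}

#' @keywords internal
#' @noRd
new_proposition_report <- function(proposition, preconditions,
                                   discrepancy, values) {
  structure(list(proposition = proposition,
                 preconditions_met = preconditions,
                 max_abs_rel_discrepancy = discrepancy,
                 per_sample_values = values),
            class = "proposition_report")
}

#' @export
print.proposition_report <- function(x, ...) {
  ok <- all(unlist(x$preconditions_met))
  cat(sprintf("Proposition %d: preconditions %s\n", x$proposition,
              if (ok) "met" else "NOT met"))
  for (nm in names(x$preconditions_met)) {
    cat(sprintf("  %s: %s\n", nm, x$preconditions_met[[nm]]))
  }
  if (is.na(x$max_abs_rel_discrepancy)) {
    cat("  no comparison performed\n")
  } else {
    cat(sprintf("  max |rel. discrepancy| = %.3g\n",
                x$max_abs_rel_discrepancy))
  }
  invisible(x)
}

#' Verify the TMM/MRN relative-factor equality (no replicates)
#'
#' In a design with no replicates (every condition has exactly one
#' sample), TMM run with the first sample as reference, a 50% M-value trim,
#' a 0% A-value trim and an unweighted mean collapses to a median of
#' pre-normalized count ratios — exactly the MRN relative factor. This
#' check computes both factor vectors and reports their maximum relative
#' discrepancy, expected at machine precision because the 50% trim is
#' special-cased to the exact median.
#'
#' @param cm a [count_matrix()].
#' @return A `proposition_report`: precondition flags, the two factor
#'   vectors, and the maximum relative discrepancy (`NA` when the
#'   no-replicate precondition fails; the factors are still reported for
#'   inspection).
#' @export
check_proposition1 <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  r1 <- all(table(cm$conditions) == 1L)
  pre <- list(no_replicates = r1)
  tau_tmm <- tmm_relative_factors(cm, ref_sample = 1L, m_trim = 0.5,
                                  a_trim = 0, mean_scale = "ratio")$tau
  tau_mrn <- mrn_relative_factors(cm)$tau[as.character(cm$conditions)]
  names(tau_mrn) <- colnames(cm$counts)
  disc <- if (r1) .rel_discrepancy(tau_tmm, tau_mrn) else NA_real_
  new_proposition_report(1L, pre, disc,
                         list(tmm = tau_tmm, mrn = tau_mrn))
}

#' Verify the RLE/MRN size-factor equality (two conditions, no replicates)
#'
#' With exactly two conditions and one sample each, the RLE median ratio
#' to the geometric-mean pseudo-reference and the MRN size factor (built
#' from the median ratio of pre-normalized columns, library sizes, and the
#' unit-geometric-mean rescaling) are algebraically identical. The
#' equality is exact when the usable-gene count is odd, so the median is a
#' data point; with an even count the two paths interpolate the two
#' central order statistics on different scales and agree only to
#' second order in the central gap (see the package vignette).
#'
#' @param cm a [count_matrix()].
#' @return A `proposition_report` comparing RLE and MRN size factors; the
#'   report also records whether the usable-gene count is odd.
#' @export
check_proposition2 <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  k2 <- nlevels(cm$conditions) == 2L
  r1 <- all(table(cm$conditions) == 1L)
  usable <- sum(rle_pseudo_reference(cm) > 0)
  pre <- list(two_conditions = k2, no_replicates = r1,
              odd_usable_genes = usable %% 2L == 1L)
  f_rle <- rle_size_factors(cm)
  f_mrn <- mrn_normalization(cm)$size_factors
  disc <- if (k2 && r1) .rel_discrepancy(f_rle, f_mrn) else NA_real_
  new_proposition_report(2L, pre, disc,
                         list(rle = f_rle, mrn = f_mrn))
}

#' Verify that all three normalized count matrices coincide
#'
#' Under the combined preconditions of the two factor equalities (two
#' conditions, no replicates, TMM at 50% M-trim / 0% A-trim with the first
#' sample as reference), RLE- and MRN-normalized counts are equal, and
#' TMM's counts-per-million equal them up to the constant
#' `sqrt(N1 * N2) / 1e6`: the TMM effective library sizes are the RLE size
#' factors multiplied by the geometric mean of the two library sizes.
#' The check rescales the CPM matrix by that constant and reports the
#' maximum elementwise relative discrepancy across all three pairings.
#'
#' @param cm a [count_matrix()].
#' @return A `proposition_report`; `per_sample_values` holds the three
#'   normalized matrices (TMM already rescaled).
#' @export
check_proposition3 <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  k2 <- nlevels(cm$conditions) == 2L
  r1 <- all(table(cm$conditions) == 1L)
  usable <- sum(rle_pseudo_reference(cm) > 0)
  pre <- list(two_conditions = k2, no_replicates = r1,
              odd_usable_genes = usable %% 2L == 1L)
  n <- library_sizes(cm)
  tmm <- tmm_normalization(cm, ref_sample = 1L, m_trim = 0.5, a_trim = 0)
  z_tmm <- tmm_cpm(cm, tmm$effective_library_sizes) *
    geometric_mean(n) / 1e6
  z_rle <- rle_normalize(cm, rle_size_factors(cm))
  z_mrn <- mrn_normalize(cm, mrn_normalization(cm)$size_factors)
  disc <- if (k2 && r1) {
    max(.rel_discrepancy(z_tmm, z_rle),
        .rel_discrepancy(z_rle, z_mrn),
        .rel_discrepancy(z_tmm, z_mrn))
  } else NA_real_
  new_proposition_report(3L, pre, disc,
                         list(tmm_rescaled = z_tmm, rle = z_rle,
                              mrn = z_mrn))
}
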