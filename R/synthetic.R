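#' Configuration for the synthetic count generator
#'
#' Assembles the ingredients of the expected-count model
#' `E(X_gkr) = mu_gk * L_g / S_k * N_kr`: per-gene per-condition expected
#' transcript numbers `mu_gk`, gene lengths `L_g`, the per-condition
#' transcriptome sizes `S_k = sum_g mu_gk * L_g` they imply, and
#' per-sample library sizes `N_kr`. Components not supplied explicitly are
#' drawn reproducibly from the seed:
#'
#' \itemize{
#'   \item baseline `mu` log-normal (`mu_meanlog`, `mu_sdlog`) — a
#'     heavy-tailed expression distribution, the regime median-based
#'     estimators are designed for;
#'   \item a fraction `de_fraction` of genes differentially expressed in
#'     every non-reference condition, a fraction `de_up_share` of them
#'     up-regulated by `fold_change` and the rest down-regulated by
#'     `1 / fold_change`. `de_up_share != 0.5` makes the transcriptomes of
#'     the conditions differ in total size — composition bias;
#'   \item gene lengths log-normal around 1.5 kb;
#'   \item library sizes uniform on `[1e6, 2e6]` reads.
#' }
#'
#' @param n_genes number of genes.
#' @param conditions character vector of condition labels.
#' @param replicates replicates per condition (scalar, same for all).
#' @param mu optional genes x conditions matrix of positive expected
#'   transcript numbers per cell; drawn if `NULL`.
#' @param lengths optional per-gene positive lengths (bases).
#' @param library_sizes optional per-sample positive integer library sizes,
#'   ordered by condition then replicate.
#' @param dispersion negative-binomial overdispersion; variance is
#'   `m + dispersion * m^2`. `0` gives Poisson counts.
#' @param de_fraction fraction of genes differentially expressed.
#' @param de_up_share fraction of DE genes up-regulated in non-reference
#'   conditions.
#' @param fold_change fold change applied to DE genes (> 0).
#' @param mu_meanlog,mu_sdlog log-normal parameters of the baseline `mu`.
#' @param seed integer seed; the whole configuration and the counts drawn
#'   from it are deterministic given the seed.
#' @return A list of class `simulation_config` with the resolved `mu`,
#'   `lengths`, `library_sizes`, `de_status` (per-gene -1/0/+1) and
#'   `transcriptome_sizes`.
#' @export
simulation_config <- function(n_genes = 1000,
                              conditions = c("A", "B"),
                              replicates = 1,
                              mu = NULL,
                              lengths = NULL,
                              library_sizes = NULL,
                              dispersion = 0.1,
                              de_fraction = 0,
                              de_up_share = 0.5,
                              fold_change = 2,
                              mu_meanlog = log(20),
                              mu_sdlog = 1.5,
                              seed = 1) {
  stopifnot(n_genes >= 1, replicates >= 1, length(conditions) >= 1,
            !anyDuplicated(conditions),
            dispersion >= 0, de_fraction >= 0, de_fraction <= 1,
            de_up_share >= 0, de_up_share <= 1, fold_change > 0)
  k <- length(conditions)
  s <- k * replicates
  set.seed(seed)
  de_status <- integer(n_genes)
  if (is.null(mu)) {
    base <- rlnorm(n_genes, meanlog = mu_meanlog, sdlog = mu_sdlog)
    mu <- matrix(base, nrow = n_genes, ncol = k)
    n_de <- floor(de_fraction * n_genes)
    if (n_de > 0 && k > 1) {
      de_genes <- sample.int(n_genes, n_de)
      n_up <- round(de_up_share * n_de)
      up <- de_genes[seq_len(n_up)]
      down <- setdiff(de_genes, up)
      de_status[up] <- 1L
      de_status[down] <- -1L
      mu[up, -1L] <- mu[up, -1L] * fold_change
      mu[down, -1L] <- mu[down, -1L] / fold_change
    }
  } else {
    mu <- as.matrix(mu)
    stopifnot(nrow(mu) == n_genes, ncol(mu) == k, all(mu > 0))
  }
  if (is.null(lengths)) {
    lengths <- rlnorm(n_genes, meanlog = log(1500), sdlog = 0.5)
  }
  stopifnot(length(lengths) == n_genes, all(lengths > 0))
  if (is.null(library_sizes)) {
    library_sizes <- round(runif(s, 1e6, 2e6))
  }
  stopifnot(length(library_sizes) == s, all(library_sizes > 0))
  colnames(mu) <- conditions
  structure(list(n_genes = n_genes,
                 conditions = conditions,
                 replicates = replicates,
                 mu = mu,
                 lengths = lengths,
                 library_sizes = library_sizes,
                 dispersion = dispersion,
                 de_fraction = de_fraction,
                 de_up_share = de_up_share,
                 fold_change = fold_change,
                 de_status = de_status,
                 transcriptome_sizes = transcriptome_size(mu, lengths),
                 seed = seed),
            class = "simulation_config")
}

#' Per-condition transcriptome sizes
#'
#' `S_k = sum_g mu_gk * L_g`: the total expected transcribed mass of a
#' cell in condition `k`. The ratio `S_1 / S_2` is the quantity the
#' scaling normalizations must estimate to remove composition bias.
#'
#' @param mu genes x conditions matrix of positive expected transcript
#'   numbers.
#' @param lengths per-gene positive lengths.
#' @return Named per-condition numeric vector.
#' @export
transcriptome_size <- function(mu, lengths) {
  mu <- as.matrix(mu)
  stopifnot(length(lengths) == nrow(mu), all(mu > 0), all(lengths > 0))
  colSums(mu * lengths)
}

#' Simulate a count matrix from the expected-count model
#'
#' Draws `X_gkr` negative-binomial (Poisson when `dispersion = 0`) with
#' mean `mu_gk * L_g / S_k * N_kr`. A gene's expected share of a library
#' is its share of the condition's transcriptome mass, so libraries of
#' conditions with enlarged transcriptomes spread the same read budget
#' over more transcribed material — the composition bias the normalization
#' methods correct. Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return A [count_matrix()] with samples named
#'   `<condition>_r<replicate>`; the generating truth (the config, with
#'   `de_status` and `transcriptome_sizes`) is attached as attribute
#'   `"truth"`.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  k <- length(cfg$conditions)
  s <- k * cfg$replicates
  cond_of_sample <- rep(cfg$conditions, each = cfg$replicates)
  share <- sweep(cfg$mu * cfg$lengths, 2L, cfg$transcriptome_sizes, "/")
  means <- share[, rep(seq_len(k), each = cfg$replicates), drop = FALSE]
  means <- sweep(means, 2L, cfg$library_sizes, "*")
  set.seed(cfg$seed)
  counts <- if (cfg$dispersion == 0) {
    rpois(length(means), lambda = means)
  } else {
    rnbinom(length(means), mu = means, size = 1 / cfg$dispersion)
  }
  counts <- matrix(as.double(counts), nrow = cfg$n_genes, ncol = s,
                   dimnames = list(
                     paste0("gene_", seq_len(cfg$n_genes)),
                     paste0(cond_of_sample, "_r",
                            rep(seq_len(cfg$replicates), times = k))))
  cm <- count_matrix(counts, conditions = cond_of_sample)
  attr(cm, "truth") <- cfg
  cm
}

#' Two-sample fixture with one-sided composition bias
#'
#' A two-condition, no-replicate count matrix in which every
#' differentially expressed gene is up-regulated in the second condition
#' (`de_up_share = 1`), so the second transcriptome is strictly larger and
#' raw count ratios are biased. About 1001 genes; the generator redraws
#' (advancing a sub-seed) until the usable-gene count — genes with
#' positive counts in both samples — is odd, so that all medians fall on
#' data points and the cross-method equalities are exact.
#'
#' @param seed integer seed.
#' @param odd if `FALSE`, redraw until the usable-gene count is even
#'   instead (for exercising the interpolation caveat).
#' @param dispersion negative-binomial overdispersion; the default 0.1 is
#'   typical bulk RNA-seq biological noise. Use 0 (Poisson) for
#'   exact-limit checks whose tolerance depends on the local spacing of
#'   the ratio distribution, such as the even-count interpolation caveat.
#' @return A [count_matrix()] with 2 samples and truth attached.
#' @export
make_composition_bias_fixture <- function(seed, odd = TRUE,
                                          dispersion = 0.1) {
  for (i in 0:100) {
    sub_seed <- (seed + i * 7919L) %% 2147483647L
    cfg <- simulation_config(n_genes = 1001, conditions = c("A", "B"),
                             replicates = 1, dispersion = dispersion,
                             de_fraction = 0.3, de_up_share = 1,
                             fold_change = 4, seed = sub_seed)
    cm <- simulate_counts(cfg)
    usable <- sum(rle_pseudo_reference(cm) > 0)
    if ((usable %% 2L == 1L) == odd) return(cm)
  }
  stop("could not reach the requested usable-gene parity", call. = FALSE)
}

#' Composition-biased fixture with strongly varying sequencing depth
#'
#' Emulates the situation where the TMM and RLE/MRN size-factor
#' conventions visibly part ways: two conditions with one-sided
#' differential expression (composition bias) and library sizes spanning
#' a 10-fold range. Depths sit on a fixed geometric ladder (jittered by
#' ~10%) and the same ladder is used in both conditions, so sequencing
#' depth is balanced across conditions rather than confounded with them —
#' any factor/depth correlation is then attributable to the method, not
#' to the design. TMM size factors carry no library-size component and
#' should be uncorrelated with depth; RLE and MRN size factors include it
#' and should track depth closely.
#'
#' @param seed integer seed.
#' @param replicates samples per condition (default 5, i.e. 10 samples).
#' @return A [count_matrix()] with truth attached.
#' @export
make_depth_gradient_fixture <- function(seed, replicates = 5) {
  set.seed(seed)
  ladder <- 5e5 * 10^(seq(0, 1, length.out = replicates))
  n <- round(rep(ladder, 2) * runif(2 * replicates, 0.9, 1.1))
  cfg <- simulation_config(n_genes = 2000, conditions = c("A", "B"),
                           replicates = replicates, library_sizes = n,
                           dispersion = 0.1, de_fraction = 0.3,
                           de_up_share = 1, fold_change = 4, seed = seed)
  simulate_counts(cfg)
}
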