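test_that("transcriptome size is the mu-weighted length sum", {
  g <- 7
  ones <- matrix(1, g, 2)
  expect_equal(unname(transcriptome_size(ones, rep(1, g))), c(g, g))
  mu <- cbind(c(1, 2, 3), c(2, 4, 6))
  expect_equal(unname(transcriptome_size(mu, c(100, 200, 300))),
               c(1400, 2800))
})

test_that("simulation is deterministic and respects configured library sizes", {
  cfg <- simulation_config(n_genes = 300, seed = 42)
  cm1 <- simulate_counts(cfg)
  cm2 <- simulate_counts(cfg)
  expect_identical(cm1$counts, cm2$counts)

  # Poisson-scale fluctuation of column sums around the configured depth
  cfg0 <- simulation_config(n_genes = 1000, conditions = c("A", "B"),
                            replicates = 2, dispersion = 0, seed = 3)
  cm0 <- simulate_counts(cfg0)
  n <- library_sizes(cm0)
  expect_true(all(abs(n - cfg0$library_sizes) <=
                    5 * sqrt(cfg0$library_sizes)))
})

test_that("without differential expression all factors approach 1", {
  # the null limit: identical expected profiles and depths, Poisson noise
  cfg <- simulation_config(n_genes = 2000, conditions = c("A", "B"),
                           replicates = 2, de_fraction = 0, dispersion = 0,
                           library_sizes = rep(15e5, 4), seed = 8)
  cm <- simulate_counts(cfg)
  for (f in list(tmm_normalization(cm)$size_factors,
                 adjust_to_unit_product(rle_size_factors(cm)),
                 mrn_normalization(cm)$size_factors)) {
    expect_lt(max(abs(f - 1)), 0.02)
  }
})

test_that("Poisson sample means converge to the configured expectations", {
  cfg <- simulation_config(n_genes = 400, conditions = "A",
                           replicates = 50, dispersion = 0,
                           de_fraction = 0, seed = 12)
  cm <- simulate_counts(cfg)
  truth <- attr(cm, "truth")
  expected <- truth$mu[, 1] * truth$lengths / truth$transcriptome_sizes[1]
  expected <- outer(expected, truth$library_sizes)
  high <- rowMeans(expected) >= 500  # LLN regime
  ratio <- rowMeans(cm$counts[high, ]) / rowMeans(expected[high, ])
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("composition-bias fixture has the advertised structure and direction", {
  cm <- make_composition_bias_fixture(23)
  expect_equal(ncol(cm$counts), 2L)
  expect_equal(nlevels(cm$conditions), 2L)
  expect_equal(sum(rle_pseudo_reference(cm) > 0) %% 2L, 1L)
  even <- make_composition_bias_fixture(23, odd = FALSE)
  expect_equal(sum(rle_pseudo_reference(even) > 0) %% 2L, 0L)

  # enlarged second transcriptome: tau_2 below 1, near the analytic
  # median of the configured per-gene ratios
  truth <- attr(cm, "truth")
  analytic <- naive_median(truth$mu[, 2] / truth$mu[, 1]) *
    truth$transcriptome_sizes[1] / truth$transcriptome_sizes[2]
  tau2 <- mrn_relative_factors(cm)$tau[["B"]]
  expect_lt(tau2, 1)
  expect_lt(abs(tau2 / analytic - 1), 0.3)
})

test_that("one-sided DE enlarges the second transcriptome", {
  cfg <- simulation_config(n_genes = 1000, conditions = c("A", "B"),
                           replicates = 1, de_fraction = 0.3,
                           de_up_share = 1, fold_change = 4, seed = 2)
  s <- cfg$transcriptome_sizes
  expect_gt(s["B"], s["A"])
  expect_equal(sum(cfg$de_status == 1L), 300L)
  expect_equal(sum(cfg$de_status == -1L), 0L)
})
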