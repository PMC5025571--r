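test_that("reference selection follows the upper-quartile rule", {
  y <- pre_normalize(random_cm(5))
  expect_identical(select_reference(y, 1), 1L)
  expect_identical(select_reference(y, colnames(y)[3]), 3L)
  expect_error(select_reference(y, 99), "out of range")
  expect_error(select_reference(y, "nope"), "unknown reference")

  same <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  expect_identical(select_reference(same), 1L)  # tie-break: lowest index

  # columns with upper quartiles 1, 2, 3; mean 2 picks the middle one
  uq <- cbind(rep(1, 8), rep(2, 8), rep(3, 8))
  expect_identical(select_reference(uq), 2L)
})

test_that("proportional columns give unit factors; reference tau is exactly 1", {
  cm <- toy_cm()  # columns proportional after pre-normalization
  rel <- tmm_relative_factors(cm, ref_sample = 1, m_trim = 0.5, a_trim = 0)
  expect_identical(unname(rel$tau), c(1, 1))

  prop <- count_matrix(outer(c(3, 10, 40, 7), c(1, 2, 5)))
  rel2 <- tmm_relative_factors(prop)  # default trims
  expect_equal(unname(rel2$tau), rep(1, 3))

  cm3 <- make_composition_bias_fixture(2)
  rel3 <- tmm_relative_factors(cm3, ref_sample = 1)
  expect_identical(unname(rel3$tau[1]), 1)
})

test_that("unit-product adjustment and effective library sizes", {
  expect_equal(adjust_to_unit_product(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(adjust_to_unit_product(c(1, 4)), c(0.5, 2))
  set.seed(9)
  x <- rlnorm(7)
  expect_lt(abs(prod(adjust_to_unit_product(x)) - 1), 1e-10)
  expect_error(adjust_to_unit_product(c(1, 0)), "positive")

  expect_equal(tmm_effective_library_sizes(c(1, 1), c(14, 56)), c(14, 56))
  expect_equal(tmm_effective_library_sizes(c(0.5, 2), c(100, 100)),
               c(50, 200))
  expect_error(tmm_effective_library_sizes(c(1, 2), c(1, 2, 3)),
               "equal length")
})

test_that("CPM uses effective library sizes and preserves zeros and scale", {
  cm <- count_matrix(matrix(c(5, 0, 15), ncol = 1))
  z <- tmm_cpm(cm, library_sizes(cm))
  expect_equal(sum(z), 1e6)
  expect_equal(z[2, 1], 0)

  cm2 <- random_cm(8)
  e <- library_sizes(cm2)
  cm2x2 <- count_matrix(cm2$counts * 2, conditions = cm2$conditions)
  expect_equal(tmm_cpm(cm2x2, 2 * e), tmm_cpm(cm2, e))
})

test_that("TMM size factors ignore a global count rescaling", {
  cm <- random_cm(13)
  f1 <- tmm_normalization(cm)$size_factors
  f2 <- tmm_normalization(
    count_matrix(cm$counts * 3, conditions = cm$conditions))$size_factors
  expect_equal(f1, f2)
})

test_that("ratio and log2 mean scales coincide at the 50% trim on odd valid sets", {
  cm <- make_composition_bias_fixture(4)  # odd usable count
  t_ratio <- tmm_relative_factors(cm, 1, 0.5, 0, "ratio")$tau
  t_log2 <- tmm_relative_factors(cm, 1, 0.5, 0, "log2")$tau
  expect_lt(max(abs(t_ratio / t_log2 - 1)), 1e-12)
})

test_that("double trimming agrees with a brute-force loop oracle", {
  for (seed in 1:5) {
    cm <- random_cm(seed)
    got <- tmm_relative_factors(cm, ref_sample = 2,
                                m_trim = 0.3, a_trim = 0.05)$tau
    expect_equal(unname(got), naive_tmm_tau(cm, 2, 0.3, 0.05),
                 tolerance = 1e-12)
  }
})

test_that("log2-scale TMM with the upper-quartile reference tracks edgeR", {
  skip_if_not_installed("edgeR")
  cfg <- simulation_config(n_genes = 2000, conditions = c("A", "B"),
                           replicates = 3, de_fraction = 0.3,
                           de_up_share = 1, fold_change = 4, seed = 5)
  cm <- simulate_counts(cfg)
  mine <- tmm_normalization(cm, ref_sample = "auto", m_trim = 0.3,
                            a_trim = 0.05,
                            mean_scale = "log2")$size_factors
  theirs <- edgeR::calcNormFactors(cm$counts, method = "TMM",
                                   doWeighting = FALSE)
  # not bit-exact: rank ties at the trim boundaries are resolved
  # differently (stable order here, average ranks there)
  expect_lt(max(abs(mine / theirs - 1)), 2e-3)
})

test_that("disjoint M- and A-survivors raise an informative error", {
  # four genes whose central M-values belong to the outer A-values, so a
  # 25% trim on each leaves an empty intersection
  x <- cbind(c(32, 1, 2^18, 2^13), c(512, 4, 2^16, 512))
  cm <- count_matrix(x)
  expect_error(tmm_relative_factors(cm, 2, m_trim = 0.25, a_trim = 0.25),
               "no usable genes after trimming")
})
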