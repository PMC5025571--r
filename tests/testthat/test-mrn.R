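test_that("condition means average pre-normalized replicates", {
  y <- cbind(c(0.1, 0.9), c(0.3, 0.7), c(0.5, 0.5))
  cm1 <- condition_means(y, c("a", "b", "c"))
  expect_equal(unname(cm1), y)  # single replicates pass through

  y2 <- cbind(c(0.1, 0.9), c(0.1, 0.9), c(0.3, 0.7), c(0.5, 0.5))
  cm2 <- condition_means(y2, c("a", "a", "b", "b"))
  expect_equal(unname(cm2[, 1]), c(0.1, 0.9))  # identical replicates
  expect_equal(unname(cm2[, 2]), c(0.4, 0.6))  # midpoint of 0.3 and 0.5
})

test_that("toy matrix: relative factors, effective sizes, size factors", {
  cm <- toy_cm()
  rel <- mrn_relative_factors(cm)
  expect_identical(unname(rel$tau), c(1, 1))
  res <- mrn_normalization(cm)
  expect_equal(unname(res$effective_library_sizes), c(14, 56))
  expect_equal(unname(res$size_factors), c(0.5, 2))   # e / gm(e), gm = 28
  expect_equal(unname(mrn_normalize(cm, res$size_factors)),
               matrix(c(2, 8, 18, 2, 8, 18), nrow = 3))
})

test_that("reference tau is exactly 1 and size factors have unit geometric mean", {
  for (seed in 1:3) {
    cm <- random_cm(seed, conditions = rep(c("x", "y", "z"), each = 2))
    rel <- mrn_relative_factors(cm)
    expect_identical(unname(rel$tau["x"]), 1)
    f <- mrn_normalization(cm)$size_factors
    expect_lt(abs(exp(mean(log(f))) - 1), 1e-10)
  }
})

test_that("a half-doubled condition recovers the brute-force median ratio", {
  # condition 2 doubles the share of the first half of the genes
  set.seed(17)
  base <- rpois(21, 100) + 1
  shifted <- base
  shifted[1:10] <- shifted[1:10] * 2
  cm <- count_matrix(cbind(a = base, b = shifted))
  y <- cbind(base / sum(base), shifted / sum(shifted))
  ratios <- y[, 2] / y[, 1]
  expect_equal(unname(mrn_relative_factors(cm)$tau["b"]),
               sort(ratios)[11])  # brute-force median, odd count
})

test_that("replicates share tau but not f; sample permutation permutes f only", {
  cfg <- simulation_config(n_genes = 500, conditions = c("A", "B"),
                           replicates = 3, de_fraction = 0.2,
                           de_up_share = 1, fold_change = 3, seed = 6)
  cm <- simulate_counts(cfg)
  res <- mrn_normalization(cm)
  expect_equal(length(unique(res$relative_factors)), 2L)
  expect_gt(length(unique(res$size_factors)), 2L)

  perm <- c(2, 3, 1, 4, 5, 6)  # shuffle replicates within condition A
  cmp <- count_matrix(cm$counts[, perm], conditions = cm$conditions[perm])
  resp <- mrn_normalization(cmp)
  expect_equal(unname(resp$size_factors), unname(res$size_factors[perm]))
  expect_equal(mrn_relative_factors(cmp)$tau, mrn_relative_factors(cm)$tau)
})

test_that("choice of reference condition leaves size factors unchanged (odd sets)", {
  cm <- make_composition_bias_fixture(9)  # odd usable count: medians commute
  fa <- mrn_normalization(cm, ref_condition = "A")$size_factors
  fb <- mrn_normalization(cm, ref_condition = "B")$size_factors
  expect_lt(max(abs(fa / fb - 1)), 1e-12)
})

test_that("errors name the offending condition or label", {
  cm <- count_matrix(matrix(c(0, 3, 5, 0), nrow = 2),
                     conditions = c("c1", "c2"))
  expect_error(mrn_relative_factors(cm), "c2")
  expect_error(mrn_normalization(toy_cm(), ref_condition = "nope"),
               "unknown reference condition")
})
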