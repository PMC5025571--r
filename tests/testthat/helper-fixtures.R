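# Shared fixtures and independent brute-force oracles. The oracles use
# explicit per-gene loops and their own median/trim arithmetic so they
# stay independent of the vectorized production paths they check.

toy_cm <- function() {
  count_matrix(matrix(c(1, 4, 9, 4, 16, 36), nrow = 3,
                      dimnames = list(paste0("g", 1:3), c("s1", "s2"))))
}

random_cm <- function(seed, n_genes = 50, n_samples = 6, max_count = 500,
                      conditions = NULL) {
  set.seed(seed)
  m <- matrix(sample.int(max_count, n_genes * n_samples, replace = TRUE),
              nrow = n_genes)
  count_matrix(m, conditions = conditions)
}

naive_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# median-of-ratios against a per-gene geometric-mean reference, all loops
naive_rle_factors <- function(cm) {
  x <- cm$counts
  f <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    ratios <- c()
    for (g in seq_len(nrow(x))) {
      if (all(x[g, ] > 0)) {
        ref <- prod(x[g, ])^(1 / ncol(x))
        ratios <- c(ratios, x[g, j] / ref)
      }
    }
    f[j] <- naive_median(ratios)
  }
  f
}

# doubly trimmed mean of ratios against a fixed reference column, loops +
# explicit index bookkeeping
naive_tmm_tau <- function(cm, ref, m_trim, a_trim) {
  n_lib <- numeric(ncol(cm$counts))
  for (j in seq_len(ncol(cm$counts))) n_lib[j] <- sum(cm$counts[, j])
  y <- cm$counts
  for (j in seq_len(ncol(y))) y[, j] <- y[, j] / n_lib[j]
  tau <- numeric(ncol(y))
  for (j in seq_len(ncol(y))) {
    if (j == ref) {
      tau[j] <- 1
      next
    }
    m <- a <- r <- c()
    for (g in seq_len(nrow(y))) {
      if (y[g, j] > 0 && y[g, ref] > 0) {
        m <- c(m, log2(y[g, j] / y[g, ref]))
        a <- c(a, 0.5 * log2(y[g, j] * y[g, ref]))
        r <- c(r, y[g, j] / y[g, ref])
      }
    }
    n <- length(m)
    km <- floor(m_trim * n)
    ka <- floor(a_trim * n)
    keep_m <- order(m)[seq.int(km + 1L, n - km)]
    keep_a <- order(a)[seq.int(ka + 1L, n - ka)]
    keep <- keep_m[keep_m %in% keep_a]
    tau[j] <- sum(r[keep]) / length(keep)
  }
  tau
}
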