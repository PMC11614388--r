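# Correction matrices, NNLS deconvolution, enrichment and normalization.

test_that("correction matrix columns match the convolution forward model", {
  A <- build_correction_matrix(parse_formula("C2"), n_tracer = 2, K = 2)
  expect_equal(A[, 1], dbinom(0:2, 2, 0.0107), tolerance = 1e-12)
  expect_equal(A[, 2], c(0, 0.9893, 0.0107))
  expect_equal(A[, 3], c(0, 0, 1))
  # purity 1 makes the matrix lower triangular with positive diagonal
  expect_true(all(A[upper.tri(A)] == 0))
  expect_true(all(diag(A) > 0))
})

test_that("fully labeled column is a delta plus heavy-element tail only", {
  frag <- tbdms_m57_fragment(parse_formula("C3H6O3"), 2)  # lactate M-57
  n <- 3
  A <- build_correction_matrix(frag, n)
  col <- A[, n + 1]
  expect_true(all(col[seq_len(n)] == 0))  # nothing below shift n
  backbone <- formula_subtract(frag, elemental_formula(c(C = n)))
  expect_equal(col[n + 1], natural_pattern(backbone, 0)[1], tolerance = 1e-12)
  expect_gt(sum(col[(n + 2):length(col)]), 0)  # Si/O tail present
})

test_that("tracer impurity spreads label as a binomial", {
  A <- build_correction_matrix(parse_formula("C1"), 1, purity = 0.99, K = 1)
  expect_equal(A[, 2], c(0.01, 0.99))
  A2 <- build_correction_matrix(parse_formula("C2"), 2, purity = 0.95, K = 2)
  expect_equal(A2[, 3], dbinom(0:2, 2, 0.95), tolerance = 1e-12)
})

test_that("matrix construction rejects impossible inputs", {
  expect_error(build_correction_matrix(parse_formula("C2H4"), 3),
               "exceeds fragment carbon count")
  expect_error(build_correction_matrix(parse_formula("C2"), 2, purity = 0),
               "purity")
})

test_that("correct_mid inverts the forward model", {
  A <- build_correction_matrix(parse_formula("C2"), 2, K = 2)
  # unlabeled sample corrects to pure m+0
  unl <- correct_mid(1e6 * A[, 1], A)
  expect_equal(unl$fractions, c(1, 0, 0), tolerance = 1e-9)
  # fully labeled corrects to pure m+n
  lab <- correct_mid(A[, 3], A)
  expect_equal(lab$fractions, c(0, 0, 1), tolerance = 1e-9)
  # equal mixture round trip, and the pool is preserved
  mix <- correct_mid(as.vector(A %*% c(0.5, 0, 0.5)) * 3e7, A)
  expect_equal(mix$fractions, c(0.5, 0, 0.5), tolerance = 1e-9)
  expect_equal(mix$pool, 3e7, tolerance = 1e-6)
  expect_false(mix$flagged)
})

test_that("NNLS equals forward-substitution oracle on noise-free data", {
  set.seed(404)
  for (i in 1:25) {
    f <- random_formula()
    n <- sample(seq_len(f[["C"]]), 1)
    A <- build_correction_matrix(f, n)
    x <- random_mid(n)
    raw <- as.vector(unclass(A) %*% x) * stats::runif(1, 1e4, 1e9)
    got <- correct_mid(raw, A)
    expect_equal(got$fractions, back_substitution_mid(raw, unclass(A)),
                 tolerance = 1e-8)
    expect_equal(got$fractions, x, tolerance = 1e-8)
  }
})

test_that("degenerate and malformed raw vectors are handled explicitly", {
  A <- build_correction_matrix(parse_formula("C2"), 2, K = 2)
  expect_error(correct_mid(c(0, 0, 0), A), "all-zero")
  expect_error(correct_mid(c(-1, 2, 3), A), "non-negative")
  # short vectors are zero-padded, long ones truncated with a warning
  expect_equal(correct_mid(c(A[1:2, 1]), A)$fractions,
               correct_mid(A[, 1] * c(1, 1, 0), A)$fractions, tolerance = 1e-9)
  expect_warning(correct_mid(c(A[, 1], 0.5), A), "truncating")
  # a large spurious peak in a heavy channel cannot be explained by any
  # non-negative MID and raises the residual flag
  A_lac <- registry_correction_matrix(default_registry(), "lactate")
  raw <- 1e6 * A_lac[, 1]
  raw[nrow(A_lac)] <- 0.5e6
  bad <- correct_mid(raw, A_lac)
  expect_true(bad$residual > 0.05)
  expect_true(bad$flagged)
})

test_that("fractional enrichment is the mean labeled-carbon fraction", {
  expect_equal(fractional_enrichment(c(1, 0, 0), 2), 0)
  expect_equal(fractional_enrichment(c(0.5, 0, 0.5), 2), 0.5)
  expect_equal(fractional_enrichment(c(0, 1), 1), 1)
  set.seed(505)
  m <- random_mid(4)
  expect_gte(fractional_enrichment(m, 4), 0)
  expect_lte(fractional_enrichment(m, 4), 1)
})

test_that("abundance normalization divides by IS and cells per 1e6", {
  expect_equal(normalize_abundance(100, 50, 1e6), 2)
  expect_equal(normalize_abundance(0, 50, 1e6), 0)
  expect_equal(normalize_abundance(750, 750, 2e6), 0.5)
  expect_error(normalize_abundance(1, 0, 1e6), "internal standard")
  expect_error(normalize_abundance(1, 1, 0), "cell count")
})

test_that("per-sample MIDs are invariant to sample order", {
  fx <- bundled_fixture("palmitate_4h", seed = 11)
  cs1 <- correct_samples(fx$areas, fx$design)
  shuffle <- sample(nrow(fx$areas))
  cs2 <- correct_samples(fx$areas[shuffle, ], fx$design)
  key <- function(d) d[order(d$sample, d$metabolite, d$isotopologue), ]
  expect_equal(key(cs1)$mid, key(cs2)$mid, tolerance = 1e-12)
})
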