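test_that("approximate entropy matches the literal transcription oracle", {
  # a short near-periodic series, frozen against the oracle
  x <- c(85, 80, 89, 85, 80, 89, 85, 80, 89, 85)
  expect_equal(approximate_entropy(x)$value, -0.016416758629342,
               tolerance = 1e-12)
  expect_equal(approximate_entropy(x)$value, apen_oracle(x), tolerance = 1e-13)

  set.seed(14)
  for (k in 1:25) {
    n <- sample(30:120, 1)
    x <- 140 + cumsum(rnorm(n, 0, 3))
    m <- sample(1:3, 1)
    expect_equal(approximate_entropy(x, m = m)$value,
                 apen_oracle(x, m = m), tolerance = 1e-12)
  }
})

test_that("ApEn is zero for constant input and shift-invariant", {
  expect_identical(approximate_entropy(rep(7, 50))$value, 0)
  set.seed(15)
  x <- rnorm(200)
  expect_equal(approximate_entropy(x)$value,
               approximate_entropy(x + 1000)$value, tolerance = 1e-9)
  # non-negative on generic random series
  for (k in 1:10) {
    x <- rnorm(sample(50:200, 1))
    expect_gte(approximate_entropy(x)$value, -1e-12)
  }
  expect_error(approximate_entropy(c(1, 2, 3), m = 2), "at least")
})

test_that("a periodic series is more regular than its permutations", {
  set.seed(16)
  x <- rep(c(135, 140, 145, 140), length.out = 300) + rnorm(300, 0, 0.01)
  ap_per <- approximate_entropy(x)$value
  ap_shuf <- vapply(1:20, function(i) approximate_entropy(sample(x))$value,
                    numeric(1))
  expect_true(all(ap_per < ap_shuf))
})

test_that("windowed ApEn reduces to per-slice whole-series values", {
  expect_true(all(apen_series(rep(5, 600))$value == 0))

  set.seed(17)
  x <- 140 + cumsum(rnorm(700, 0, 2))
  aps <- apen_series(x, window_len = 256, window_step = 128)
  for (i in seq_len(nrow(aps))) {
    s <- aps$start[i]
    expect_equal(aps$value[i],
                 approximate_entropy(x[s:(s + 255)])$value, tolerance = 1e-12)
  }
  # window covering the whole series equals the plain statistic
  one <- apen_series(x, window_len = length(x), window_step = length(x))
  expect_equal(nrow(one), 1)
  expect_equal(one$value, approximate_entropy(x)$value)
  expect_error(apen_series(x, window_len = 1000), "exceeds")
})

test_that("pearson_r follows the product-moment formula", {
  expect_equal(pearson_r(1:10, 1:10), 1.0)
  expect_equal(pearson_r(1:10, -(1:10)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.9819805061, tolerance = 1e-9)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("cohort correlation skips absent parameters and short branches", {
  set.seed(18)
  recs <- lapply(1:6, function(i) {
    fhr_recording(bpm = 140 + cumsum(rnorm(300, 0, 4)),
                  record_id = paste0("r", i),
                  panel = blood_gas_panel(pH = 7.1 + i * 0.04))
  })
  tab <- cohort_correlation(recs, "non-downward")
  expect_equal(tab$n[tab$parameter == "pH"], 6)
  # PCO2 absent in every panel: skipped with NA correlation and n = 0
  expect_equal(tab$n[tab$parameter == "PCO2"], 0)
  expect_true(is.na(tab$r[tab$parameter == "PCO2"]))
})

test_that("paired t-test matches the textbook formula and handles degeneracy", {
  a <- c(0.91, 0.84, 0.88, 0.79, 0.95)
  b <- c(0.82, 0.80, 0.85, 0.81, 0.86)
  got <- paired_t_test(a, b)
  want <- paired_t_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  # identical inputs: zero differences are well defined
  same <- paired_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # constant non-zero difference admits no t statistic
  expect_error(paired_t_test(a, a + 1), "zero variance")

  # a clear shift with small noise is detected
  set.seed(19)
  x <- rnorm(20)
  expect_lt(paired_t_test(x + 0.5, x + rnorm(20, 0, 0.05))$p, 0.05)
})
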