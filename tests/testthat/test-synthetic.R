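test_that("trace generation is seed-deterministic and meets its invariants", {
  spec <- synthetic_cohort_spec()
  r1 <- generate_trace(2, spec, seed = 99)
  r2 <- generate_trace(2, spec, seed = 99)
  expect_identical(r1$bpm, r2$bpm)
  expect_identical(r1$panel$pH, r2$panel$pH)
  expect_false(identical(generate_trace(2, spec, seed = 100)$bpm, r1$bpm))

  # the post-delivery tail qualifies as noise and is removed in full
  tail_vals <- tail(r1$bpm, spec$noise_tail_len)
  expect_true(all(tail_vals < 100))
  out <- clean_recording(r1)
  expect_gte(out$report$n_noise_samples_removed, spec$noise_tail_len)
  runs <- rle(out$recording$bpm < 100)
  expect_true(all(runs$lengths[runs$values] < 5))
})

test_that("acidotic traces show more downward beats than normal traces", {
  spec <- synthetic_cohort_spec(trace_len = 1800L)
  frac <- function(cl, i) {
    rec <- clean_recording(generate_trace(cl, spec, seed = 500 + i))$recording
    p <- detect_downward(rec)
    length(p$downward_series) / length(p$labels)
  }
  f1 <- vapply(1:20, function(i) frac(1, i), numeric(1))
  f4 <- vapply(1:20, function(i) frac(4, i), numeric(1))
  expect_gt(mean(f1), 1.3 * mean(f4))
})

test_that("cohorts honor per-class counts and pH intervals", {
  spec <- synthetic_cohort_spec(n_per_class = rep(3L, 4), trace_len = 600L,
                                seed = 2)
  coh <- generate_cohort(spec)
  expect_length(coh$recordings, 12)
  expect_equal(as.vector(table(coh$classes)), rep(3, 4))
  for (i in seq_along(coh$recordings)) {
    ph <- coh$recordings[[i]]$panel$pH
    expect_equal(ph_to_state(ph), coh$classes[i])
  }

  # the clinical class distribution scales to the full cohort size
  spec469 <- synthetic_cohort_spec(trace_len = 60L, noise_tail_len = 5L)
  expect_equal(sum(spec469$n_per_class), 469)
})

test_that("ground-truth HMM sampling follows (pi, A, B) exactly", {
  gt <- ground_truth_hmm()
  expect_gte(gt$min_row_tv, 0.8)

  # deterministic one-hot emissions identify the hidden states
  Bdet <- matrix(0, 4, 8)
  for (j in 1:4) Bdet[j, j] <- 1
  det <- hmm_params(A = gt$params$A, B = Bdet)
  out <- generate_hmm_sequences(det, n_seq = 5, len = 40, seed = 3)
  expect_identical(out$symbols, out$states)

  out1 <- generate_hmm_sequences(gt$params, 10, 50, seed = 4)
  out2 <- generate_hmm_sequences(gt$params, 10, 50, seed = 4)
  expect_identical(out1$symbols, out2$symbols)

  # empirical symbol frequencies near the stationary expectation
  big <- generate_hmm_sequences(gt$params, n_seq = 100, len = 200, seed = 5)
  # uniform stationary distribution by symmetry; each symbol's expected
  # frequency is the column mean of B
  expected <- colMeans(gt$params$B)
  n <- length(big$symbols)
  freq <- tabulate(big$symbols, 8) / n
  se <- sqrt(expected * (1 - expected) / n)
  # sequential dependence inflates the variance; allow a generous multiple
  expect_true(all(abs(freq - expected) < 9 * se))
})

test_that("generated dynamics carry the class signal through the encoder", {
  spec <- synthetic_cohort_spec()
  doms <- integer(4)
  for (cl in 1:4) {
    rec <- clean_recording(generate_trace(cl, spec, seed = 700 + cl))$recording
    doms[cl] <- which.max(tabulate(symbolize(rec)$symbols, 8))
  }
  # each class has its own dominant symbol
  expect_equal(length(unique(doms)), 4)
})
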