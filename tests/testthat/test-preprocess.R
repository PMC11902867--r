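test_that("outlier band is closed and computed from the input series", {
  # constant series: sigma = 0, every point sits exactly on the (degenerate)
  # band boundary -- all retained, proving the bounds are inclusive
  rec <- fhr_recording(bpm = rep(140, 100))
  out <- remove_outliers(rec)
  expect_equal(out$report$n_outliers_removed, 0)
  expect_equal(out$report$n_retained, 100)
  expect_equal(out$report$sigma, 0)

  # 99 x 140 plus one 250: recompute the band directly and check the spike
  # falls outside while everything else stays
  bpm <- c(rep(140, 99), 250)
  mu <- mean(bpm); sigma <- sd(bpm)
  expect_gt(250, mu + 3 * sigma)
  out <- remove_outliers(fhr_recording(bpm = bpm))
  expect_equal(out$report$n_outliers_removed, 1)
  expect_false(250 %in% out$recording$bpm)

  # random series: retained set equals a direct closed-band re-evaluation
  set.seed(11)
  bpm <- 140 + rnorm(500, 0, 8)
  out <- remove_outliers(fhr_recording(bpm = bpm))
  keep <- bpm >= mean(bpm) - 3 * sd(bpm) & bpm <= mean(bpm) + 3 * sd(bpm)
  expect_identical(out$recording$bpm, bpm[keep])
})

test_that("noise runs of five or more sub-100 samples are removed in full", {
  bpm <- c(rep(130, 20), rep(90, 5), rep(130, 5))
  out <- remove_noise_runs(fhr_recording(bpm = bpm))
  expect_equal(out$report$n_noise_samples_removed, 5)
  expect_equal(length(out$recording$bpm), 25)
  expect_true(all(out$recording$bpm == 130))

  # a run of four is physiological and retained
  bpm4 <- c(rep(130, 10), rep(95, 4), rep(130, 10))
  out4 <- remove_noise_runs(fhr_recording(bpm = bpm4))
  expect_equal(out4$report$n_noise_samples_removed, 0)

  # cutoff is strict: exactly 100 is not noise
  bpm100 <- c(rep(130, 10), rep(100, 8), rep(130, 10))
  expect_equal(remove_noise_runs(fhr_recording(bpm = bpm100))$report$n_noise_samples_removed, 0)

  # all samples >= 100: identity
  out_id <- remove_noise_runs(fhr_recording(bpm = rep(120, 30)))
  expect_equal(out_id$recording$bpm, rep(120, 30))

  # a long run is removed entirely, not truncated to five
  bpm_long <- c(rep(130, 10), rep(85, 12), rep(130, 10))
  expect_equal(remove_noise_runs(fhr_recording(bpm = bpm_long))$report$n_noise_samples_removed, 12)
})

test_that("noise-run removal is idempotent", {
  set.seed(3)
  for (k in 1:10) {
    bpm <- sample(c(runif(50, 80, 99), runif(150, 110, 160)))
    bpm <- c(bpm, rep(88, sample(3:9, 1)))
    r1 <- remove_noise_runs(fhr_recording(bpm = bpm))$recording
    r2 <- remove_noise_runs(r1)
    expect_equal(r2$report$n_noise_samples_removed, 0)
    expect_identical(r2$recording$bpm, r1$bpm)
  }
})

test_that("clean composes both rules, removes tails and spikes, keeps values", {
  rec <- fhr_recording(bpm = rep(135, 50))
  out <- clean_recording(rec)
  expect_equal(out$report$n_retained, 50)
  expect_equal(out$report$n_outliers_removed + out$report$n_noise_samples_removed, 0)

  # injected artifact spike and post-delivery tail are both removed
  set.seed(21)
  body <- 140 + rnorm(400, 0, 3)
  bpm <- c(body, 220, body + 1, rep(70, 8))
  out <- clean_recording(fhr_recording(bpm = bpm))
  expect_equal(out$report$n_noise_samples_removed, 8)
  expect_gte(out$report$n_outliers_removed, 1)
  expect_false(any(out$recording$bpm == 220))
  expect_true(all(out$recording$bpm >= 100))
  # never lengthens, never modifies retained values
  expect_lte(length(out$recording$bpm), length(bpm))
  expect_true(all(out$recording$bpm %in% bpm))
})

test_that("three-sigma rule removes roughly 0.3% of a long Gaussian series", {
  set.seed(5)
  bpm <- 140 + rnorm(2e4, 0, 5)
  out <- remove_outliers(fhr_recording(bpm = bpm))
  frac <- out$report$n_outliers_removed / length(bpm)
  expect_gte(frac, 0.0005)
  expect_lte(frac, 0.01)
})
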