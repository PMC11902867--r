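test_that("confusion matrix tallies actual vs predicted classes", {
  cm <- confusion_matrix(rep(1:4, each = 10), rep(1:4, each = 10))
  expect_equal(unname(diag(cm)), rep(10L, 4))
  expect_equal(sum(cm), 40)

  cm <- confusion_matrix("H1", "H3")
  expect_equal(cm[1, 3], 1L)
  expect_equal(sum(cm), 1)

  set.seed(41)
  a <- sample.int(4, 200, replace = TRUE)
  p <- sample.int(4, 200, replace = TRUE)
  cm <- confusion_matrix(a, p)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(cm[i, j], sum(a == i & p == j))
  }
  expect_error(confusion_matrix(c(1, 5), c(1, 2)), "H1..H4")
})

test_that("one-vs-rest metrics follow their defining ratios", {
  cm <- matrix(c(5, 2, 1, 0,
                 1, 6, 2, 0,
                 0, 1, 7, 1,
                 0, 0, 2, 8), 4, 4, byrow = TRUE)
  m <- class_metrics(cm)
  total <- sum(cm)
  # hand-checked class H2: TP=6, FN=3, FP=3, TN=24
  expect_equal(m$per_class$sensitivity[2], 6 / 9)
  expect_equal(m$per_class$precision[2], 6 / 9)
  expect_equal(m$per_class$specificity[2], 24 / 27)
  expect_equal(m$per_class$f1[2], 2 * (6 / 9) * (6 / 9) / (12 / 9))
  expect_equal(m$per_class$accuracy[2], 30 / total)
  expect_equal(m$overall_accuracy, 26 / total)

  perfect <- class_metrics(diag(c(10, 10, 10, 10)))
  expect_true(all(perfect$per_class$sensitivity == 1))
  expect_true(all(perfect$per_class$f1 == 1))
  expect_equal(perfect$overall_accuracy, 1)

  # a never-predicted class has precision 0 (flagged) and a defined F1
  cm0 <- matrix(0, 4, 4)
  cm0[1, 2] <- 5
  cm0[2, 2] <- 5
  m0 <- class_metrics(cm0)
  expect_equal(m0$per_class$precision[1], 0)
  expect_true(m0$per_class$empty_prediction[1])
  expect_equal(m0$per_class$f1[1], 0)
  expect_error(class_metrics(matrix(0, 4, 4)), "empty")
})

test_that("metrics are invariant to permuting the evaluated pairs", {
  set.seed(42)
  a <- sample.int(4, 100, replace = TRUE)
  p <- sample.int(4, 100, replace = TRUE)
  perm <- sample(100)
  expect_identical(confusion_matrix(a, p), confusion_matrix(a[perm], p[perm]))
})

test_that("two-decimal reporting rounds half away from zero", {
  expect_equal(round2(17 / 40), 0.43)
  expect_equal(round2(0.425), 0.43)
  expect_equal(round2(-0.425), -0.43)
  expect_equal(round2(5 / 6), 0.83)
  expect_equal(round2(0.994999), 0.99)
})

test_that("balanced resampling draws exact per-class counts, seeded", {
  cls <- rep(1:4, times = c(21, 50, 146, 252))  # the clinical distribution
  sp <- balance_cohort(cls, seed = 5)
  expect_length(sp$train, 60)
  expect_length(sp$test, 24)
  expect_length(intersect(sp$train, sp$test), 0)
  for (j in 1:4) {
    expect_equal(sum(cls[sp$train] == j), 15)
    expect_equal(sum(cls[sp$test] == j), 6)
  }
  expect_identical(balance_cohort(cls, seed = 5), sp)
  expect_false(identical(balance_cohort(cls, seed = 6), sp))

  short <- rep(1:4, times = c(20, 50, 50, 50))
  expect_error(balance_cohort(short), "H1")
})

test_that("model evaluation classifies a test set against true labels", {
  Bdet <- matrix(0, 4, 8)
  for (j in 1:4) Bdet[j, j] <- 1
  pd <- hmm_params(B = Bdet)
  seqs <- lapply(c(1, 2, 3, 4, 2), function(j) rep(as.integer(j), 10))
  truth <- c(1L, 2L, 3L, 4L, 2L)
  ev <- evaluate_model(pd, seqs, truth)
  expect_equal(ev$metrics$overall_accuracy, 1)
  expect_equal(unname(diag(ev$confusion)), c(1L, 2L, 1L, 1L))
  expect_error(evaluate_model(pd, list(), integer(0)), "empty")
})
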