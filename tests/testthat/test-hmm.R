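test_that("emission rows are class-conditional symbol frequencies", {
  B <- estimate_emissions(list(c(1, 1, 1, 2)), classes = 3L)
  expect_equal(B[3, ], c(0.75, 0.25, rep(0, 6)))
  # classes with no windows fall back to uniform
  expect_equal(B[1, ], rep(1 / 8, 8))

  set.seed(31)
  seqs <- lapply(1:12, function(i) sample.int(8, 40, replace = TRUE))
  cls <- sample.int(4, 12, replace = TRUE)
  B <- estimate_emissions(seqs, cls)
  for (j in unique(cls)) {
    pool <- unlist(seqs[cls == j])
    expect_equal(B[j, ], as.numeric(tabulate(pool, 8) / length(pool)))
  }
  expect_equal(unname(rowSums(B)), rep(1, 4))
})

test_that("transition matrix comes from the concatenated pseudo-label sequence", {
  # one recording of class H3 with 10 windows: only (3,3) pairs observed
  A <- init_transitions(3L, 10L)
  expect_equal(A[3, ], c(0, 0, 1, 0))
  expect_equal(A[1, ], rep(0.25, 4))  # unobserved rows are uniform

  # pseudo-sequence H1,H1,H2 -> row 1 = (0.5, 0.5, 0, 0)
  A <- init_transitions(c(1L, 1L, 2L), c(1L, 1L, 1L))
  expect_equal(A[1, ], c(0.5, 0.5, 0, 0))

  set.seed(32)
  cls <- sample.int(4, 20, replace = TRUE)
  nw <- sample.int(6, 20, replace = TRUE)
  A <- init_transitions(cls, nw)
  pseudo <- rep(cls, nw)
  cnt <- matrix(0, 4, 4)
  for (t in seq_len(length(pseudo) - 1)) {
    cnt[pseudo[t], pseudo[t + 1]] <- cnt[pseudo[t], pseudo[t + 1]] + 1
  }
  for (i in 1:4) {
    if (sum(cnt[i, ]) > 0) expect_equal(A[i, ], cnt[i, ] / sum(cnt[i, ]))
  }
})

test_that("Baum-Welch handles a degenerate one-symbol alphabet", {
  seqs <- list(rep(1L, 30), rep(1L, 25))
  fit <- baum_welch(seqs, init = hmm_params(), tol = 1e-9, max_iter = 50)
  expect_true(all(abs(fit$params$B[, 1] - 1) < 1e-9))
  # likelihood is flat once the first update has been applied
  expect_lt(max(abs(diff(fit$loglik[-1]))), 1e-9)
})

test_that("EM log-likelihood is non-decreasing and rows stay stochastic", {
  set.seed(33)
  for (k in 1:10) {
    init <- random_hmm_params()
    seqs <- lapply(1:3, function(i) sample.int(8, 40, replace = TRUE))
    fit <- baum_welch(seqs, init = init, tol = 1e-8, max_iter = 40)
    expect_gte(min(diff(fit$loglik)), -1e-10)
    expect_equal(sum(fit$params$pi), 1, tolerance = 1e-9)
    expect_equal(unname(rowSums(fit$params$A)), rep(1, 4), tolerance = 1e-9)
    expect_equal(unname(rowSums(fit$params$B)), rep(1, 4), tolerance = 1e-9)
  }
})

test_that("scaled forward log-likelihood equals the unscaled computation", {
  set.seed(34)
  for (k in 1:20) {
    params <- random_hmm_params()
    obs <- sample.int(8, sample(2:20, 1), replace = TRUE)
    expect_equal(hmm_loglik(obs, params),
                 loglik_unscaled_oracle(obs, params), tolerance = 1e-9)
  }
})

test_that("Viterbi initialization, deterministic emissions and tie-breaking", {
  set.seed(35)
  params <- random_hmm_params()
  # T = 1 reduces to argmax_i pi_i b_i(O_1)
  for (o in 1:8) {
    expect_equal(viterbi(o, params)$states,
                 which.max(params$pi * params$B[, o]))
  }

  # each state emits a unique symbol: the path reads off the symbols
  Bdet <- matrix(0, 4, 8)
  for (j in 1:4) Bdet[j, j] <- 1
  pd <- hmm_params(A = matrix(0.25, 4, 4), B = Bdet)
  obs <- c(3L, 1L, 4L, 4L, 2L)
  expect_equal(viterbi(obs, pd)$states, as.integer(obs))

  # full symmetry: ties break toward the lowest state index
  expect_equal(viterbi(c(5L, 5L, 5L), hmm_params())$states, rep(1L, 3))
})

test_that("Viterbi equals brute-force path enumeration", {
  set.seed(36)
  for (k in 1:30) {
    params <- random_hmm_params()
    obs <- sample.int(8, sample(1:6, 1), replace = TRUE)
    got <- viterbi(obs, params)
    want <- viterbi_bruteforce(obs, params)
    expect_equal(got$log_prob, want$log_prob, tolerance = 1e-9)
  }
})

test_that("recording classification reduces the decoded path to one class", {
  # absorbing state H4: every state transitions there with high probability
  A <- matrix(0, 4, 4)
  diag(A) <- 0.1
  A[, 4] <- A[, 4] + 0.9
  A[4, 4] <- 1
  p_abs <- hmm_params(A = A, B = matrix(1 / 8, 4, 8))
  expect_equal(classify_recording(rep(1L, 50), p_abs), 4L)

  set.seed(37)
  params <- random_hmm_params()
  o <- sample.int(8, 1)
  expect_equal(classify_recording(o, params), viterbi(o, params)$states[1])

  # majority rule counts states along the path
  Bdet <- matrix(0, 4, 8)
  for (j in 1:4) Bdet[j, j] <- 1
  pd <- hmm_params(B = Bdet)
  obs <- c(2L, 2L, 2L, 3L)
  expect_equal(classify_recording(obs, pd, rule = "final"), 3L)
  expect_equal(classify_recording(obs, pd, rule = "majority"), 2L)
})

test_that("state matching finds the relabelling of a permuted model", {
  truth <- ground_truth_hmm()$params
  perm <- c(3L, 1L, 4L, 2L)
  scrambled <- hmm_params(pi = truth$pi[perm], A = truth$A[perm, perm],
                          B = truth$B[perm, ])
  m <- match_states(scrambled, truth)
  expect_equal(m$params$B, truth$B)
  expect_equal(m$params$A, truth$A)
  expect_lt(m$max_row_l1_B, 1e-12)
})

test_that("invalid parameters and symbols are rejected", {
  expect_error(hmm_params(pi = c(0.5, 0.5, 0, 0.1)), "sum to 1")
  expect_error(hmm_params(A = matrix(-0.25, 4, 4)), "non-negative")
  expect_error(viterbi(c(0L, 3L), hmm_params()), "1..8")
  expect_error(baum_welch(list(), hmm_params()), "no sequences")
})

test_that("restarted fitting keeps the highest-likelihood candidate", {
  gt <- ground_truth_hmm()
  out <- generate_hmm_sequences(gt$params, n_seq = 20, len = 80, seed = 8)
  seqs <- lapply(seq_len(nrow(out$symbols)), function(i) out$symbols[i, ])
  fit <- fit_hmm(seqs, n_restarts = 2, seed = 8, tol = 1e-4, max_iter = 60)
  expect_length(fit$restart_logliks, 3)  # informed init + 2 random restarts
  expect_equal(fit$loglik[length(fit$loglik)], max(fit$restart_logliks))
})
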