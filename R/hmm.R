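#' Discrete hidden Markov model parameters
#'
#' The model couples 4 hidden acid-base classes (H1..H4, see [ph_to_state()])
#' to 8 observed beat-dynamics symbols (O1..O8, see [symbolize()]) through an
#' initial distribution `pi`, a 4x4 transition matrix `A` and a 4x8 emission
#' matrix `B`. All rows are stochastic (non-negative, summing to 1 within
#' 1e-9). The default initial distribution is uniform, reflecting no prior
#' preference among acid-base states at the onset of labour.
#'
#' @param pi Length-4 initial state distribution.
#' @param A 4x4 row-stochastic transition matrix.
#' @param B 4x8 row-stochastic emission matrix.
#' @return An object of class `hmm_params`.
#' @examples
#' p <- hmm_params()
#' rowSums(p$B)
#' @export
hmm_params <- function(pi = rep(0.25, 4),
                       A = matrix(0.25, 4, 4),
                       B = matrix(1 / 8, 4, 8)) {
  params <- structure(
    list(pi = as.numeric(pi), A = unname(as.matrix(A)), B = unname(as.matrix(B))),
    class = "hmm_params"
  )
  validate_hmm_params(params)
  params
}

#' Validate HMM parameter stochasticity
#'
#' @param params An `hmm_params` object (or bare list with `pi`, `A`, `B`).
#' @param tol Row-sum tolerance, default 1e-9.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_hmm_params <- function(params, tol = 1e-9) {
  pi <- params$pi; A <- params$A; B <- params$B
  if (length(pi) != 4 || !all(dim(A) == c(4, 4)) || !all(dim(B) == c(4, 8))) {
    stop("expected pi[4], A[4x4], B[4x8]", call. = FALSE)
  }
  if (any(pi < 0) || any(A < 0) || any(B < 0)) {
    stop("HMM parameters must be non-negative", call. = FALSE)
  }
  if (abs(sum(pi) - 1) > tol || any(abs(rowSums(A) - 1) > tol) ||
      any(abs(rowSums(B) - 1) > tol)) {
    stop("HMM parameter rows must sum to 1", call. = FALSE)
  }
  invisible(params)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> 4 hidden states x 8 symbols\n")
  cat("pi:", sprintf("%.3f", x$pi), "\n")
  cat("A:\n"); print(round(x$A, 3))
  cat("B:\n"); print(round(x$B, 3))
  invisible(x)
}

#' Estimate the emission matrix from labelled symbol sequences
#'
#' `b_j(k)` is the relative frequency of symbol `O_k` among the windows of
#' recordings labelled with hidden class `H_j`. A class with no windows gets
#' a uniform row.
#'
#' @param sequences List of [symbolize()] results or bare integer vectors
#'   (codes 1..8).
#' @param classes Integer vector of hidden classes (1..4), one per sequence.
#' @return A 4x8 row-stochastic emission matrix.
#' @export
estimate_emissions <- function(sequences, classes) {
  if (length(sequences) != length(classes)) {
    stop("`sequences` and `classes` must have equal length", call. = FALSE)
  }
  classes <- as.integer(classes)
  if (any(classes < 1 | classes > 4)) stop("classes must be in 1..4", call. = FALSE)
  B <- matrix(0, 4, 8)
  for (i in seq_along(sequences)) {
    sym <- symbol_codes(sequences[[i]])
    B[classes[i], ] <- B[classes[i], ] + tabulate(sym, nbins = 8)
  }
  for (j in 1:4) {
    tot <- sum(B[j, ])
    B[j, ] <- if (tot > 0) B[j, ] / tot else rep(1 / 8, 8)
  }
  B
}

#' Initialize the transition matrix from a labelled recording order
#'
#' Builds a pseudo hidden-state training sequence by assigning every window
#' its recording's class label and concatenating the recordings in input
#' order, then counts adjacent (i, j) co-occurrences and normalizes each row.
#' Rows with no observed transitions become uniform.
#'
#' @param classes Integer vector of hidden classes (1..4), one per recording.
#' @param n_windows Integer vector: the number of symbol windows in each
#'   recording.
#' @return A 4x4 row-stochastic transition matrix.
#' @export
init_transitions <- function(classes, n_windows) {
  classes <- as.integer(classes)
  n_windows <- as.integer(n_windows)
  if (length(classes) != length(n_windows)) {
    stop("`classes` and `n_windows` must have equal length", call. = FALSE)
  }
  pseudo <- rep(classes, n_windows)
  if (length(pseudo) < 2) stop("need at least 2 windows in total", call. = FALSE)
  A <- matrix(0, 4, 4)
  from <- pseudo[-length(pseudo)]
  to <- pseudo[-1]
  for (k in seq_along(from)) A[from[k], to[k]] <- A[from[k], to[k]] + 1
  for (i in 1:4) {
    tot <- sum(A[i, ])
    A[i, ] <- if (tot > 0) A[i, ] / tot else rep(0.25, 4)
  }
  A
}

#' Baum-Welch training of the discrete HMM
#'
#' Expectation-maximization over one or more observation sequences. The
#' E-step runs scaled forward-backward recursions (per-step normalization, so
#' arbitrarily long sequences do not underflow) and accumulates the transition
#' posteriors `xi` and occupancy posteriors `gamma` across sequences; the
#' M-step re-estimates `pi`, `A`, `B` from the pooled numerators and
#' denominators. Iteration stops when the total log-likelihood changes by
#' less than `tol` or after `max_iter` iterations. The log-likelihood trace
#' is non-decreasing (a property of EM), which the test suite verifies.
#'
#' Emission entries that fall below `floor` (in particular, symbols never
#' observed in the data) are raised to `floor` and the row renormalized, so a
#' later sequence containing such a symbol cannot have zero likelihood.
#'
#' @param sequences List of [symbolize()] results or integer vectors (1..8).
#' @param init Initial [hmm_params()].
#' @param tol Absolute convergence tolerance on the log-likelihood delta.
#' @param max_iter Maximum number of EM iterations.
#' @param floor Emission probability floor (default 1e-12).
#' @return List with `params` (the trained [hmm_params()]), `loglik` (the
#'   per-iteration log-likelihood trace, evaluated at the start of each
#'   iteration), `n_iter`, and `converged`.
#' @export
baum_welch <- function(sequences, init = hmm_params(), tol = 1e-6,
                       max_iter = 500L, floor = 1e-12) {
  validate_hmm_params(init)
  obs_list <- lapply(sequences, symbol_codes)
  if (length(obs_list) == 0) stop("no sequences supplied", call. = FALSE)
  if (any(lengths(obs_list) < 1)) stop("empty sequence supplied", call. = FALSE)
  params <- list(pi = init$pi, A = init$A, B = floor_rows(init$B, floor))
  # group sequences of equal length into matrices so the recursions run
  # vectorized across sequences
  len <- lengths(obs_list)
  groups <- lapply(split(seq_along(obs_list), len), function(idx) {
    do.call(rbind, obs_list[idx])
  })
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    es <- bw_e_step(groups, params)
    trace <- c(trace, es$loglik)
    n_iter <- iter
    A_new <- es$A_num
    for (i in 1:4) {
      tot <- sum(A_new[i, ])
      A_new[i, ] <- if (tot > 0) A_new[i, ] / tot else params$A[i, ]
    }
    B_new <- es$B_num
    for (j in 1:4) {
      tot <- sum(B_new[j, ])
      B_new[j, ] <- if (tot > 0) B_new[j, ] / tot else params$B[j, ]
    }
    params <- list(pi = es$pi_num / sum(es$pi_num), A = A_new,
                   B = floor_rows(B_new, floor))
    if (iter >= 2 && abs(trace[iter] - trace[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  out_params <- structure(params, class = "hmm_params")
  validate_hmm_params(out_params)
  list(params = out_params, loglik = trace, n_iter = n_iter,
       converged = converged)
}

# one E-step over all length-groups; returns pooled numerators and the total
# log-likelihood of the data under `params`
bw_e_step <- function(groups, params) {
  A <- params$A; B <- params$B; pi <- params$pi
  A_num <- matrix(0, 4, 4)
  B_num <- matrix(0, 4, 8)
  pi_num <- numeric(4)
  loglik <- 0
  n_total <- 0L
  for (obs in groups) {
    n <- nrow(obs); TT <- ncol(obs)
    n_total <- n_total + n
    # scaled forward pass: alphahat[, , t] rows sum to 1, scales c[, t]
    alphahat <- array(0, c(n, 4, TT))
    cs <- matrix(0, n, TT)
    raw <- matrix(pi, n, 4, byrow = TRUE) * t(B[, obs[, 1], drop = FALSE])
    cs[, 1] <- rowSums(raw)
    alphahat[, , 1] <- raw / cs[, 1]
    if (TT > 1) {
      for (t in 2:TT) {
        raw <- (matrix(alphahat[, , t - 1], n, 4) %*% A) *
          t(B[, obs[, t], drop = FALSE])
        cs[, t] <- rowSums(raw)
        alphahat[, , t] <- raw / cs[, t]
      }
    }
    loglik <- loglik + sum(log(cs))
    # scaled backward pass, accumulating xi and gamma on the fly
    betahat <- matrix(1, n, 4)
    gamma_T <- matrix(alphahat[, , TT], n, 4)  # betahat_T = 1
    B_num <- B_num + gamma_acc(gamma_T, obs[, TT])
    if (TT > 1) {
      for (t in (TT - 1):1) {
        a_t <- matrix(alphahat[, , t], n, 4)
        W <- (betahat * t(B[, obs[, t + 1], drop = FALSE])) / cs[, t + 1]
        A_num <- A_num + crossprod(a_t, W) * A
        betahat <- W %*% t(A)
        gamma_t <- a_t * betahat
        B_num <- B_num + gamma_acc(gamma_t, obs[, t])
        if (t == 1) pi_num <- pi_num + colSums(gamma_t)
      }
    } else {
      pi_num <- pi_num + colSums(gamma_T)
    }
  }
  list(A_num = A_num, B_num = B_num, pi_num = pi_num, loglik = loglik,
       n_total = n_total)
}

# add gamma mass (n x 4) into symbol columns of a 4 x 8 accumulator
gamma_acc <- function(gamma, sym) {
  out <- matrix(0, 4, 8)
  for (k in unique(sym)) {
    sel <- sym == k
    out[, k] <- if (sum(sel) == 1) gamma[sel, ] else colSums(gamma[sel, , drop = FALSE])
  }
  out
}

# raise sub-floor entries and renormalize; untouched rows stay bit-identical
floor_rows <- function(M, floor) {
  hit <- M < floor
  if (!any(hit)) return(M)
  M[hit] <- floor
  M / rowSums(M)
}

#' Fit an HMM by Baum-Welch with informed initialization and restarts
#'
#' Runs [baum_welch()] first from an informed initialization -- emission
#' rows seeded by k-means clustering of short-block symbol histograms
#' (hidden states persist across neighbouring windows, so short blocks are
#' nearly state-pure and their histograms sit close to the true emission
#' rows) -- and then from additional seeded random initializations, keeping
#' the fit with the highest final log-likelihood. This is the standard guard
#' against EM local optima when no labelled initialization is available.
#'
#' @inheritParams baum_welch
#' @param n_restarts Number of additional random initializations (default 3).
#' @param seed Integer seed controlling k-means and the random restarts.
#' @param block_len Block length (symbols) for the histogram clustering.
#' @return The best [baum_welch()] result, with an extra element
#'   `restart_logliks` (final log-likelihood of every candidate, informed
#'   initialization first).
#' @export
fit_hmm <- function(sequences, n_restarts = 3L, seed = 1L, tol = 1e-6,
                    max_iter = 500L, block_len = 10L) {
  obs_list <- lapply(sequences, symbol_codes)
  inits <- list()
  # informed candidate: k-means on block symbol histograms
  blocks <- do.call(rbind, lapply(obs_list, function(s) {
    nb <- max(1L, length(s) %/% block_len)
    t(vapply(seq_len(nb), function(b) {
      idx <- (block_len * (b - 1) + 1):min(block_len * b, length(s))
      tabulate(s[idx], 8) / length(idx)
    }, numeric(8)))
  }))
  if (nrow(unique(blocks)) >= 4) {
    km <- with_seed(seed, stats::kmeans(blocks, centers = 4, nstart = 5))
    B0 <- km$centers + 0.01  # keep rows strictly positive
    inits[[1]] <- hmm_params(pi = rep(0.25, 4),
                             A = matrix(0.075, 4, 4) + diag(0.7, 4),
                             B = B0 / rowSums(B0))
  }
  for (r in seq_len(n_restarts)) {
    inits[[length(inits) + 1]] <- with_seed(seed + r, {
      nr <- function(M) M / rowSums(M)
      hmm_params(pi = rep(0.25, 4),
                 A = nr(matrix(stats::runif(16, 0.5, 1.5), 4, 4)),
                 B = nr(matrix(stats::runif(32, 0.5, 1.5), 4, 8)))
    })
  }
  best <- NULL
  finals <- numeric(length(inits))
  for (r in seq_along(inits)) {
    fit <- baum_welch(sequences, init = inits[[r]], tol = tol,
                      max_iter = max_iter)
    finals[r] <- fit$loglik[length(fit$loglik)]
    if (is.null(best) || finals[r] > best$loglik[length(best$loglik)]) {
      best <- fit
    }
  }
  best$restart_logliks <- finals
  best
}

#' Log-likelihood of a symbol sequence under an HMM
#'
#' Scaled forward recursion; numerically safe for long sequences.
#'
#' @param seq A [symbolize()] result or integer vector (codes 1..8).
#' @param params An [hmm_params()].
#' @return The log-likelihood (natural log).
#' @export
hmm_loglik <- function(seq, params) {
  validate_hmm_params(params)
  obs <- symbol_codes(seq)
  alpha <- params$pi * params$B[, obs[1]]
  ll <- log(sum(alpha))
  alpha <- alpha / sum(alpha)
  for (t in seq_along(obs)[-1]) {
    alpha <- as.numeric(alpha %*% params$A) * params$B[, obs[t]]
    s <- sum(alpha)
    ll <- ll + log(s)
    alpha <- alpha / s
  }
  ll
}

#' Viterbi decoding of the most probable hidden-state path
#'
#' Log-space dynamic programming with backtracking. Ties in the running
#' maximum are broken toward the lowest state index, so decoding is fully
#' deterministic. Zero emission probabilities for an observed symbol are
#' floored (1e-12, row-renormalized) so that no observation has zero
#' likelihood under every state.
#'
#' @param seq A [symbolize()] result or integer vector (codes 1..8).
#' @param params An [hmm_params()].
#' @return An object of class `decoded_path`: list with `states` (integer
#'   path, 1..4), `log_prob` (log probability of the joint path) and
#'   `labels` (the `H1..H4` names).
#' @export
viterbi <- function(seq, params) {
  validate_hmm_params(params)
  obs <- symbol_codes(seq)
  TT <- length(obs)
  if (TT < 1) stop("empty observation sequence", call. = FALSE)
  B <- floor_rows(params$B, 1e-12)
  logA <- log(params$A)
  logB <- log(B)
  delta <- matrix(-Inf, TT, 4)
  psi <- matrix(0L, TT, 4)
  delta[1, ] <- log(params$pi) + logB[, obs[1]]
  if (TT > 1) {
    for (t in 2:TT) {
      for (i in 1:4) {
        cand <- delta[t - 1, ] + logA[, i]
        j <- which.max(cand)  # first maximum = lowest state index
        psi[t, i] <- j
        delta[t, i] <- cand[j] + logB[i, obs[t]]
      }
    }
  }
  states <- integer(TT)
  states[TT] <- which.max(delta[TT, ])
  if (TT > 1) {
    for (t in (TT - 1):1) states[t] <- psi[t + 1, states[t + 1]]
  }
  structure(
    list(states = states, log_prob = max(delta[TT, ]),
         labels = state_labels()[states]),
    class = "decoded_path"
  )
}

#' @export
print.decoded_path <- function(x, ...) {
  cat(sprintf("<decoded_path> T=%d, log P = %.4f, final state %s\n",
              length(x$states), x$log_prob, x$labels[length(x$labels)]))
  invisible(x)
}

#' Classify a recording from its decoded hidden-state path
#'
#' A labour recording carries a single postnatal cord pH, so the decoded path
#' is reduced to one class: by default the final Viterbi state (the state the
#' model believes the fetus is in at the end of the observation window,
#' closest to delivery); alternatively the majority state along the path
#' (ties toward the lowest state index).
#'
#' @param seq A [symbolize()] result or integer vector (codes 1..8).
#' @param params An [hmm_params()].
#' @param rule `"final"` (default) or `"majority"`.
#' @return Integer class in 1..4.
#' @export
classify_recording <- function(seq, params, rule = c("final", "majority")) {
  rule <- match.arg(rule)
  path <- viterbi(seq, params)
  if (rule == "final") {
    path$states[length(path$states)]
  } else {
    which.max(tabulate(path$states, nbins = 4))
  }
}

#' Align estimated HMM states to a reference by permutation
#'
#' Unsupervised EM recovers hidden states only up to relabelling. This
#' searches all 24 permutations of the 4 states and returns the one whose
#' permuted emission matrix minimizes the maximum row-wise L1 distance to the
#' reference (the standard label-switching correction in HMM recovery
#' studies).
#'
#' @param est Estimated [hmm_params()].
#' @param ref Reference [hmm_params()].
#' @return List with `params` (the permuted estimate), `perm` (the applied
#'   permutation: new index `i` holds old state `perm[i]`), and
#'   `max_row_l1_A`, `max_row_l1_B` against the reference.
#' @export
match_states <- function(est, ref) {
  perms <- perms4()
  best <- NULL
  best_score <- Inf
  for (p in perms) {
    Bp <- est$B[p, , drop = FALSE]
    score <- max(abs(Bp - ref$B) %*% rep(1, 8))
    if (score < best_score) {
      best_score <- score
      best <- p
    }
  }
  p <- best
  out <- hmm_params(pi = est$pi[p], A = est$A[p, p], B = est$B[p, ])
  list(params = out, perm = p,
       max_row_l1_A = max(rowSums(abs(out$A - ref$A))),
       max_row_l1_B = max(rowSums(abs(out$B - ref$B))))
}

perms4 <- function() {
  out <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    out[[length(out) + 1]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  }
  out
}

# accept symbol_sequence objects or bare integer vectors
symbol_codes <- function(seq) {
  sym <- if (inherits(seq, "symbol_sequence")) seq$symbols else as.integer(seq)
  if (length(sym) < 1) stop("empty symbol sequence", call. = FALSE)
  if (any(is.na(sym)) || any(sym < 1L | sym > 8L)) {
    stop("symbol codes must be integers in 1..8", call. = FALSE)
  }
  sym
}
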