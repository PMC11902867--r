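# Independent reference implementations used as oracles. These are literal,
# slow transcriptions of the defining formulas, deliberately sharing no code
# with the package internals.

# Approximate entropy by direct O(N^2) evaluation: embedding vectors,
# Chebyshev distances, self-match-inclusive counts, natural log.
apen_oracle <- function(x, m = 2L, r = NULL, r_frac = 0.2) {
  N <- length(x)
  if (is.null(r)) r <- r_frac * sd(x)
  phi <- function(mm) {
    n <- N - mm + 1
    C <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        d <- 0
        for (k in seq_len(mm)) {
          d <- max(d, abs(x[i + k - 1] - x[j + k - 1]))
        }
        if (d <= r) cnt <- cnt + 1L
      }
      C[i] <- cnt / n
    }
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

# Most probable hidden path by exhaustive enumeration of all K^T paths.
viterbi_bruteforce <- function(obs, params) {
  K <- length(params$pi)
  TT <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), TT)))
  best_lp <- -Inf
  best_path <- NULL
  for (p in seq_len(nrow(paths))) {
    q <- as.integer(paths[p, ])
    lp <- log(params$pi[q[1]]) + log(params$B[q[1], obs[1]])
    if (TT > 1) {
      for (t in 2:TT) {
        lp <- lp + log(params$A[q[t - 1], q[t]]) + log(params$B[q[t], obs[t]])
      }
    }
    if (lp > best_lp) {
      best_lp <- lp
      best_path <- q
    }
  }
  list(states = best_path, log_prob = best_lp)
}

# Paired t statistic straight from the textbook formula.
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1))
}

# Subgroup labels by literal re-evaluation of the midpoint rule.
subgroup_oracle <- function(diffs, category) {
  out <- integer(length(diffs))
  for (cc in unique(category)) {
    sel <- category == cc
    mid <- (min(diffs[sel]) + max(diffs[sel])) / 2
    for (i in which(sel)) {
      d <- diffs[i]
      if (d == mid) {
        out[i] <- 1L
      } else if (mid >= 0) {
        out[i] <- if (d < mid) 1L else 2L
      } else {
        out[i] <- if (d > mid) 1L else 2L
      }
    }
  }
  out
}

# Unscaled forward-algorithm likelihood (direct sum-product, underflows for
# long sequences; used only at small T).
loglik_unscaled_oracle <- function(obs, params) {
  alpha <- params$pi * params$B[, obs[1]]
  for (t in seq_along(obs)[-1]) {
    alpha <- as.numeric(alpha %*% params$A) * params$B[, obs[t]]
  }
  log(sum(alpha))
}

# Random row-stochastic HMM parameters.
random_hmm_params <- function() {
  norm_rows <- function(M) M / rowSums(M)
  fetalph::hmm_params(
    pi = {
      p <- runif(4, 0.1, 1)
      p / sum(p)
    },
    A = norm_rows(matrix(runif(16, 0.05, 1), 4, 4)),
    B = norm_rows(matrix(runif(32, 0.05, 1), 4, 8))
  )
}

# Literal re-evaluation of the whole symbol-encoding rule: categories,
# per-recording midpoint subgroups, per-window dominant subgroup, O-code.
symbolize_oracle <- function(bpm, window_len, window_step, halfwidth = 2) {
  d <- diff(bpm)
  category <- character(length(d))
  for (i in seq_along(d)) {
    category[i] <- if (d[i] <= -halfwidth) "D"
    else if (d[i] >= halfwidth) "I" else "S"
  }
  sub <- subgroup_oracle(d, category)
  starts <- seq(1, length(d) - window_len + 1, by = window_step)
  vapply(starts, function(s) {
    idx <- s:(s + window_len - 1)
    dom <- integer(3)
    names(dom) <- c("D", "S", "I")
    for (cc in c("D", "S", "I")) {
      n1 <- sum(category[idx] == cc & sub[idx] == 1)
      n2 <- sum(category[idx] == cc & sub[idx] == 2)
      dom[cc] <- if (n2 > n1) 2L else 1L
    }
    1L + 4L * (dom[["D"]] - 1L) + 2L * (dom[["S"]] - 1L) + (dom[["I"]] - 1L)
  }, integer(1))
}
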