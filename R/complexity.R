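#' Approximate entropy of a heart-rate series
#'
#' Approximate entropy (ApEn) quantifies the irregularity of a time series:
#' `ApEn(m, r, N) = Phi_m(r) - Phi_{m+1}(r)`, where `Phi_m(r)` is the average
#' natural logarithm of the fraction of length-`m` template vectors lying
#' within Chebyshev distance `r` of each template (self-matches included, the
#' classic Pincus convention, which keeps every count positive and the
#' logarithms defined). Low values indicate regular, predictable dynamics;
#' higher values indicate complexity. For heart-rate work the tolerance is
#' conventionally a fraction of the series standard deviation, so the
#' statistic is invariant to adding a constant to the series.
#'
#' A constant series (SD = 0) is defined to have ApEn 0, the limit of the
#' constant case, rather than raising an error.
#'
#' @param series Numeric vector (bpm or any HRV-derived series).
#' @param m Embedding dimension, default 2.
#' @param r_frac Tolerance as a fraction of `sd(series)`, default 0.20.
#' @param r Absolute tolerance; overrides `r_frac` when supplied.
#' @return An object of class `apen_result`: list with `value` (nats), `N`,
#'   `m`, `r`, `r_frac`.
#' @examples
#' approximate_entropy(sin(1:100))$value
#' approximate_entropy(rep(7, 50))$value  # exactly 0
#' @export
approximate_entropy <- function(series, m = 2L, r_frac = 0.2, r = NULL) {
  x <- as.numeric(series)
  m <- as.integer(m)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  N <- length(x)
  if (N < m + 2) {
    stop(sprintf("need at least m + 2 = %d samples, got %d", m + 2, N),
         call. = FALSE)
  }
  if (is.null(r)) {
    s <- stats::sd(x)
    if (s == 0) {
      return(structure(list(value = 0, N = N, m = m, r = 0, r_frac = r_frac),
                       class = "apen_result"))
    }
    r <- r_frac * s
  }
  value <- apen_phi(x, m, r) - apen_phi(x, m + 1L, r)
  structure(list(value = value, N = N, m = m, r = r, r_frac = r_frac),
            class = "apen_result")
}

#' @export
print.apen_result <- function(x, ...) {
  cat(sprintf("<apen_result> ApEn(m=%d, r=%.4g, N=%d) = %.6f nats\n",
              x$m, x$r, x$N, x$value))
  invisible(x)
}

# Phi_m(r): mean log fraction of templates within Chebyshev distance r;
# the O(N^2) pair scan runs compiled (src/apen.cpp)
apen_phi <- function(x, m, r) {
  apen_phi_cpp(as.numeric(x), as.integer(m), as.numeric(r))
}

#' Windowed approximate-entropy time course
#'
#' Slides a window along the series and computes [approximate_entropy()] on
#' each complete window, recomputing the tolerance `r` from that window's own
#' standard deviation. Used to follow complexity over the course of labour.
#'
#' @inheritParams approximate_entropy
#' @param window_len Window length in samples (default 256).
#' @param window_step Step between window starts (default 128).
#' @return An object of class `apen_series`: a data frame with columns
#'   `start` (1-based window start index), `N`, `value`.
#' @export
apen_series <- function(series, m = 2L, r_frac = 0.2,
                        window_len = 256L, window_step = 128L) {
  x <- as.numeric(series)
  window_len <- as.integer(window_len)
  window_step <- as.integer(window_step)
  if (window_len < m + 2) stop("`window_len` must be at least m + 2", call. = FALSE)
  if (window_len > length(x)) {
    stop("`window_len` exceeds the series length", call. = FALSE)
  }
  starts <- seq(1L, length(x) - window_len + 1L, by = window_step)
  vals <- vapply(starts, function(s) {
    approximate_entropy(x[s:(s + window_len - 1L)], m = m, r_frac = r_frac)$value
  }, numeric(1))
  structure(data.frame(start = starts, N = window_len, value = vals),
            class = c("apen_series", "data.frame"),
            m = m, r_frac = r_frac, window_step = window_step)
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation between two equal-length sequences; errors on
#' degenerate (zero-variance) input rather than returning `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @examples
#' pearson_r(1:3, c(1, 2, 4))
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Cohort-level correlation between branch ApEn and blood gas parameters
#'
#' For each recording, computes the whole-series approximate entropy of the
#' chosen autonomic branch (the downward or non-downward beat series), then
#' correlates those per-recording values against each blood gas parameter
#' available across the cohort.
#'
#' @param recordings List of [fhr_recording()] objects with panels attached
#'   (assumed already cleaned).
#' @param branch `"downward"` or `"non-downward"`.
#' @param threshold Downward-beat threshold in bpm, see [detect_downward()].
#' @param m,r_frac ApEn settings, see [approximate_entropy()].
#' @return A data frame with one row per blood gas parameter: `parameter`,
#'   `r` (Pearson correlation with branch ApEn), `n` (complete pairs).
#'   Parameters with fewer than 3 complete pairs are skipped (reported with
#'   `NA` correlation).
#' @export
cohort_correlation <- function(recordings, branch = c("downward", "non-downward"),
                               threshold = 5, m = 2L, r_frac = 0.2) {
  branch <- match.arg(branch)
  apens <- rep(NA_real_, length(recordings))
  panels <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    panels[[i]] <- rec$panel
    part <- detect_downward(rec, threshold = threshold)
    s <- if (branch == "downward") part$downward_series else part$nondownward_series
    if (length(s) >= m + 2) {
      apens[i] <- approximate_entropy(s, m = m, r_frac = r_frac)$value
    }
  }
  pars <- c("pH", "PCO2", "PO2", "HCO3", "BE")
  rows <- lapply(pars, function(p) {
    y <- vapply(panels, function(pl) {
      if (is.null(pl)) NA_real_ else pl[[p]]
    }, numeric(1))
    ok <- !is.na(apens) & !is.na(y)
    if (sum(ok) < 3 || stats::sd(apens[ok]) == 0 || stats::sd(y[ok]) == 0) {
      data.frame(parameter = p, r = NA_real_, n = sum(ok))
    } else {
      data.frame(parameter = p, r = pearson_r(apens[ok], y[ok]), n = sum(ok))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "apen") <- apens
  attr(out, "branch") <- branch
  out
}

#' Paired t-test between per-recording value sets
#'
#' Classical paired t-test on the differences `a - b`, used to compare the
#' complexity of the two autonomic branches across a cohort. The degenerate
#' case where every difference is exactly zero is well defined (`t = 0`,
#' `p = 1`); zero-variance differences with a non-zero mean admit no t
#' statistic and raise an error.
#'
#' @param a,b Numeric vectors of equal length >= 2 (paired by recording).
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
paired_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (all(abs(d) <= 1e-12)) {
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0))
    }
    stop("paired t-test undefined: differences have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}
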