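#' Remove statistical outliers from a recording
#'
#' Retains only the samples inside the closed band \[mu - 3 sigma,
#' mu + 3 sigma\], where mu and sigma are the mean and standard deviation of
#' the input series. For normally distributed data this band captures about
#' 99.7% of the samples, so roughly 0.3% are removed. Removed points are
#' omitted, never imputed.
#'
#' @param rec An [fhr_recording()].
#' @return A list with elements `recording` (the filtered [fhr_recording()])
#'   and `report` (a `cleaning_report`: `mu`, `sigma`, `n_outliers_removed`,
#'   `n_noise_samples_removed`, `n_retained`).
#' @examples
#' rec <- fhr_recording(bpm = c(rep(140, 99), 250))
#' out <- remove_outliers(rec)
#' out$report$n_outliers_removed
#' @export
remove_outliers <- function(rec) {
  stopifnot(inherits(rec, "fhr_recording"))
  if (length(rec$bpm) < 2) {
    stop("need at least 2 samples to estimate the outlier band", call. = FALSE)
  }
  mu <- mean(rec$bpm)
  sigma <- stats::sd(rec$bpm)
  keep <- rec$bpm >= mu - 3 * sigma & rec$bpm <= mu + 3 * sigma
  rep <- cleaning_report(mu = mu, sigma = sigma,
                         n_outliers_removed = sum(!keep),
                         n_noise_samples_removed = 0L,
                         n_retained = sum(keep))
  list(recording = subset_recording(rec, keep), report = rep)
}

#' Remove post-delivery noise runs from a recording
#'
#' After delivery the scalp electrode is detached but the monitor keeps
#' recording, producing runs of implausibly low values. Every maximal run of
#' consecutive samples strictly below `cut` bpm whose length is at least
#' `run_len` is removed in full; shorter dips are physiological and retained.
#'
#' @param rec An [fhr_recording()].
#' @param run_len Minimum qualifying run length (default 5).
#' @param cut bpm cutoff, strict (default 100).
#' @return As [remove_outliers()]: a list with `recording` and `report`.
#' @export
remove_noise_runs <- function(rec, run_len = 5L, cut = 100) {
  stopifnot(inherits(rec, "fhr_recording"))
  low <- rec$bpm < cut
  r <- rle(low)
  drop_run <- r$values & r$lengths >= run_len
  keep <- rep.int(!drop_run, r$lengths)
  rep <- cleaning_report(mu = NA_real_, sigma = NA_real_,
                         n_outliers_removed = 0L,
                         n_noise_samples_removed = sum(!keep),
                         n_retained = sum(keep))
  list(recording = subset_recording(rec, keep), report = rep)
}

#' Clean a recording
#'
#' Composite preprocessing: noise runs are removed first, so that the
#' post-delivery artifact tail cannot distort the mean and standard deviation
#' used by the outlier band, then [remove_outliers()] is applied. Retained
#' samples are never modified, only dropped.
#'
#' @inheritParams remove_noise_runs
#' @return A list with `recording` and a merged `report` whose `mu`/`sigma`
#'   come from the outlier stage.
#' @examples
#' rec <- fhr_recording(bpm = c(rep(135, 50), rep(90, 6)))
#' clean_recording(rec)$report$n_noise_samples_removed
#' @export
clean_recording <- function(rec, run_len = 5L, cut = 100) {
  s1 <- remove_noise_runs(rec, run_len = run_len, cut = cut)
  if (length(s1$recording$bpm) < 2) {
    stop("fewer than 2 samples remain after noise-run removal", call. = FALSE)
  }
  s2 <- remove_outliers(s1$recording)
  rep <- cleaning_report(
    mu = s2$report$mu, sigma = s2$report$sigma,
    n_outliers_removed = s2$report$n_outliers_removed,
    n_noise_samples_removed = s1$report$n_noise_samples_removed,
    n_retained = s2$report$n_retained
  )
  list(recording = s2$recording, report = rep)
}

cleaning_report <- function(mu, sigma, n_outliers_removed,
                            n_noise_samples_removed, n_retained) {
  structure(
    list(mu = mu, sigma = sigma,
         n_outliers_removed = as.integer(n_outliers_removed),
         n_noise_samples_removed = as.integer(n_noise_samples_removed),
         n_retained = as.integer(n_retained)),
    class = "cleaning_report"
  )
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> retained %d | outliers removed %d | noise samples removed %d\n",
    x$n_retained, x$n_outliers_removed, x$n_noise_samples_removed))
  if (!is.na(x$mu)) cat(sprintf("  band: %.2f +/- 3 x %.2f bpm\n", x$mu, x$sigma))
  invisible(x)
}

# keep a logical subset of samples; an all-FALSE subset yields a degenerate
# 0/1-sample object kept out of fhr_recording() validation on purpose
subset_recording <- function(rec, keep) {
  if (sum(keep) >= 2) {
    fhr_recording(bpm = rec$bpm[keep], t = rec$t[keep],
                  record_id = rec$record_id, panel = rec$panel)
  } else {
    structure(list(record_id = rec$record_id, t = rec$t[keep],
                   bpm = rec$bpm[keep], panel = rec$panel),
              class = "fhr_recording")
  }
}
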