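#' Partition beats into downward and non-downward components
#'
#' Labels each consecutive-beat transition: the transition into beat `i + 1`
#' is *downward* (parasympathetic activation) when
#' `bpm[i + 1] <= bpm[i] - threshold`, and *non-downward* (sympathetic)
#' otherwise. The sample at the end of each transition carries the label, so
#' every sample after the first belongs to exactly one branch and the two
#' branch series together partition samples `2..N`.
#'
#' @param rec An [fhr_recording()] or a bare numeric bpm vector.
#' @param threshold Drop in bpm (inclusive) that defines a downward beat;
#'   default 5, from clinical assessments of parasympathetic slowing.
#' @return An object of class `beat_partition`: a list with
#'   `labels` (character vector of length N-1, `"downward"`/`"non-downward"`),
#'   `downward_series` and `nondownward_series` (bpm values at the transition
#'   endpoints), and the matching endpoint indices.
#' @examples
#' p <- detect_downward(c(140, 135, 136, 130))
#' p$labels
#' @export
detect_downward <- function(rec, threshold = 5) {
  bpm <- if (inherits(rec, "fhr_recording")) rec$bpm else as.numeric(rec)
  if (length(bpm) < 2) {
    stop("need at least 2 samples to classify beat transitions", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be a positive number of bpm", call. = FALSE)
  }
  d <- diff(bpm)
  down <- d <= -threshold
  endpoints <- seq_along(d) + 1L
  structure(
    list(
      labels = ifelse(down, "downward", "non-downward"),
      downward_series = bpm[endpoints[down]],
      nondownward_series = bpm[endpoints[!down]],
      downward_idx = endpoints[down],
      nondownward_idx = endpoints[!down],
      threshold = threshold
    ),
    class = "beat_partition"
  )
}

#' @export
print.beat_partition <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<beat_partition> %d transitions: %d downward (%.1f%%), threshold %g bpm\n",
              n, length(x$downward_series),
              100 * length(x$downward_series) / n, x$threshold))
  invisible(x)
}
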