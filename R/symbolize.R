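#' Map umbilical-cord pH to a hidden acid-base class
#'
#' Four clinically defined cord-pH intervals in 0.05-unit steps:
#' H1: pH < 7.2 (acidosis); H2: 7.2 <= pH < 7.25; H3: 7.25 <= pH < 7.3;
#' H4: pH >= 7.3 (normal). Lower bounds are inclusive.
#'
#' @param pH Numeric vector of pH values.
#' @return Integer vector of classes in 1..4 (H1..H4).
#' @examples
#' ph_to_state(c(7.19, 7.2, 7.25, 7.3))
#' @export
ph_to_state <- function(pH) {
  pH <- as.numeric(pH)
  if (anyNA(pH) || any(!is.finite(pH))) {
    stop("pH must be finite", call. = FALSE)
  }
  ifelse(pH < 7.2, 1L,
         ifelse(pH < 7.25, 2L,
                ifelse(pH < 7.3, 3L, 4L)))
}

#' @rdname ph_to_state
#' @export
state_labels <- function() c("H1", "H2", "H3", "H4")

#' Symbol labels of the eight-letter observation alphabet
#' @return Character vector `O1..O8`.
#' @export
symbol_labels <- function() paste0("O", 1:8)

#' Categorize consecutive-beat differences
#'
#' The beat-to-beat difference `d = bpm[i+1] - bpm[i]` falls into one of three
#' primary categories: Decrease (`D`, `d <= -halfwidth`), Stable (`S`,
#' `-halfwidth < d < halfwidth`), Increase (`I`, `d >= halfwidth`).
#'
#' @param series Numeric bpm vector of length >= 2, or an [fhr_recording()].
#' @param halfwidth Stable-band half-width in bpm, default 2.
#' @return List with `diffs` (numeric, length N-1) and `category` (character,
#'   `"D"`/`"S"`/`"I"`).
#' @examples
#' categorize_diffs(c(140, 138, 138.5, 141))$category
#' @export
categorize_diffs <- function(series, halfwidth = 2) {
  bpm <- if (inherits(series, "fhr_recording")) series$bpm else as.numeric(series)
  if (length(bpm) < 2) {
    stop("need at least 2 samples to form differences", call. = FALSE)
  }
  d <- diff(bpm)
  cat <- ifelse(d <= -halfwidth, "D", ifelse(d >= halfwidth, "I", "S"))
  list(diffs = d, category = cat)
}

#' Split difference categories into mild and strong subgroups
#'
#' Each primary category is subdivided at the midpoint of its observed range
#' within the recording: `midpoint = (min + max) / 2` of the differences in
#' that category. Subgroup 1 holds the values on the side of the midpoint
#' nearer zero (the milder changes), subgroup 2 the other side; a value
#' exactly at the midpoint goes to subgroup 1. A category with no
#' observations contributes no subgroups.
#'
#' @param diffs Numeric vector of beat-to-beat differences.
#' @param category Matching character vector of primary categories
#'   (`"D"`/`"S"`/`"I"`), as from [categorize_diffs()].
#' @return List with `subgroup` (integer 1/2 per difference) and `midpoints`
#'   (named numeric, `NA` for empty categories).
#' @export
split_subgroups <- function(diffs, category) {
  if (length(diffs) != length(category)) {
    stop("`diffs` and `category` must have equal length", call. = FALSE)
  }
  midpoints <- c(D = NA_real_, S = NA_real_, I = NA_real_)
  subgroup <- integer(length(diffs))
  for (cc in c("D", "S", "I")) {
    sel <- category == cc
    if (!any(sel)) next
    mid <- (min(diffs[sel]) + max(diffs[sel])) / 2
    midpoints[[cc]] <- mid
    # subgroup 1 = the side of the midpoint containing zero (milder change)
    subgroup[sel] <- if (mid >= 0) ifelse(diffs[sel] <= mid, 1L, 2L)
                     else           ifelse(diffs[sel] >= mid, 1L, 2L)
  }
  list(subgroup = subgroup, midpoints = midpoints)
}

#' Encode a bpm series into the eight-symbol observation alphabet
#'
#' Beat-to-beat differences are categorized (D/S/I), each category is split
#' into mild/strong subgroups at its per-recording range midpoint, and the
#' differences are windowed. Within each window the dominant subgroup of each
#' category (the subgroup with the larger within-category count; ties and
#' absent categories resolve to subgroup 1) yields a triple
#' `(D*, S*, I*)`, mapped to `O1..O8` in lexicographic order:
#' `(D1,S1,I1) -> O1`, `(D1,S1,I2) -> O2`, `(D1,S2,I1) -> O3`,
#' `(D1,S2,I2) -> O4`, `(D2,S1,I1) -> O5`, ..., `(D2,S2,I2) -> O8`.
#'
#' @param series Numeric bpm vector (length >= 2) or an [fhr_recording()].
#' @param window_len Number of consecutive differences per window (default 60).
#' @param window_step Step between window starts in differences (default 60,
#'   i.e. non-overlapping windows).
#' @param halfwidth Stable-band half-width in bpm (default 2).
#' @return An object of class `symbol_sequence`: list with `symbols` (integer
#'   codes 1..8, one per complete window), `window_len`, `window_step`,
#'   `halfwidth`, `midpoints` (the per-recording category midpoints used), and
#'   `n_diffs`.
#' @examples
#' set.seed(1)
#' s <- symbolize(140 + cumsum(rnorm(400)), window_len = 30, window_step = 30)
#' s$symbols
#' @export
symbolize <- function(series, window_len = 60L, window_step = 60L,
                      halfwidth = 2) {
  cd <- categorize_diffs(series, halfwidth = halfwidth)
  sg <- split_subgroups(cd$diffs, cd$category)
  n <- length(cd$diffs)
  window_len <- as.integer(window_len)
  window_step <- as.integer(window_step)
  if (window_len < 1 || window_step < 1) {
    stop("window length and step must be positive", call. = FALSE)
  }
  if (n < window_len) {
    stop("no complete window: series too short for `window_len`", call. = FALSE)
  }
  starts <- seq(1L, n - window_len + 1L, by = window_step)
  symbols <- vapply(starts, function(s) {
    idx <- s:(s + window_len - 1L)
    dominant <- vapply(c("D", "S", "I"), function(cc) {
      sel <- cd$category[idx] == cc
      if (!any(sel)) return(1L)
      n1 <- sum(sg$subgroup[idx][sel] == 1L)
      n2 <- sum(sel) - n1
      if (n2 > n1) 2L else 1L
    }, integer(1))
    1L + 4L * (dominant[["D"]] - 1L) + 2L * (dominant[["S"]] - 1L) +
      (dominant[["I"]] - 1L)
  }, integer(1))
  structure(
    list(symbols = symbols, window_len = window_len, window_step = window_step,
         halfwidth = halfwidth, midpoints = sg$midpoints, n_diffs = n),
    class = "symbol_sequence"
  )
}

#' @export
print.symbol_sequence <- function(x, ...) {
  head_syms <- paste0("O", x$symbols[seq_len(min(12, length(x$symbols)))],
                      collapse = " ")
  if (length(x$symbols) > 12) head_syms <- paste(head_syms, "...")
  cat(sprintf("<symbol_sequence> %d windows of %d diffs (step %d): %s\n",
              length(x$symbols), x$window_len, x$window_step, head_syms))
  invisible(x)
}
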