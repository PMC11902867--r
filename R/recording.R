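#' Construct a fetal heart rate recording
#'
#' An `fhr_recording` holds one intrapartum beat-per-minute (bpm) series,
#' time-stamped in seconds, with an optional postnatal umbilical-cord blood
#' gas panel attached. Times must be strictly increasing and all bpm values
#' finite and positive; at least two samples are required for any downstream
#' analysis.
#'
#' @param t Numeric vector of sample times in seconds (strictly increasing,
#'   non-negative). May be `NULL`, in which case samples are indexed
#'   `0, 1, 2, ...` at an assumed uniform interval.
#' @param bpm Numeric vector of heart rates in beats per minute (finite, > 0).
#' @param record_id Opaque identifier string.
#' @param panel Optional [blood_gas_panel()].
#' @return An object of class `fhr_recording`: a list with elements
#'   `record_id`, `t`, `bpm` and `panel`.
#' @examples
#' rec <- fhr_recording(bpm = c(140, 141, 138), record_id = "demo")
#' length(rec$bpm)
#' @export
fhr_recording <- function(bpm, t = NULL, record_id = "rec", panel = NULL) {
  bpm <- as.numeric(bpm)
  if (is.null(t)) t <- seq_along(bpm) - 1
  t <- as.numeric(t)
  if (length(t) != length(bpm)) {
    stop("`t` and `bpm` must have the same length", call. = FALSE)
  }
  if (length(bpm) < 2) {
    stop("a recording needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(bpm) || any(!is.finite(bpm)) || any(bpm <= 0)) {
    stop("all bpm values must be finite and > 0", call. = FALSE)
  }
  if (anyNA(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("all times must be finite and >= 0", call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (!is.null(panel) && !inherits(panel, "blood_gas_panel")) {
    stop("`panel` must be a blood_gas_panel", call. = FALSE)
  }
  structure(
    list(record_id = as.character(record_id)[1], t = t, bpm = bpm, panel = panel),
    class = "fhr_recording"
  )
}

#' Umbilical-cord blood gas panel
#'
#' Postnatal arterial measurements indicating fetal acid-base status. Only pH
#' is mandatory when the recording is used as a labelled example; the other
#' parameters are optional.
#'
#' @param pH Unitless arterial pH (plausible range 6.8--7.6).
#' @param PCO2 Carbon dioxide partial pressure, mmHg.
#' @param PO2 Oxygen partial pressure, mmHg.
#' @param HCO3 Bicarbonate, mmol/L.
#' @param BE Base excess, mmol/L.
#' @return An object of class `blood_gas_panel`.
#' @examples
#' blood_gas_panel(pH = 7.28, BE = -4.2)
#' @export
blood_gas_panel <- function(pH = NA_real_, PCO2 = NA_real_, PO2 = NA_real_,
                            HCO3 = NA_real_, BE = NA_real_) {
  pH <- as.numeric(pH)[1]
  if (!is.na(pH) && (!is.finite(pH) || pH < 6.5 || pH > 8)) {
    stop("pH outside plausible range", call. = FALSE)
  }
  structure(
    list(pH = pH, PCO2 = as.numeric(PCO2)[1], PO2 = as.numeric(PO2)[1],
         HCO3 = as.numeric(HCO3)[1], BE = as.numeric(BE)[1]),
    class = "blood_gas_panel"
  )
}

#' @export
print.fhr_recording <- function(x, ...) {
  cat(sprintf("<fhr_recording '%s'> %d samples, t in [%g, %g] s, bpm in [%g, %g]\n",
              x$record_id, length(x$bpm), min(x$t), max(x$t),
              min(x$bpm), max(x$bpm)))
  if (!is.null(x$panel) && !is.na(x$panel$pH)) {
    cat(sprintf("  cord pH %.2f\n", x$panel$pH))
  }
  invisible(x)
}

#' @export
length.fhr_recording <- function(x) length(x$bpm)

#' Run configuration
#'
#' Bundles every tunable parameter of the analysis pipeline with its default.
#' All values are positive; window steps never exceed their window lengths.
#'
#' @param apen_m Approximate-entropy embedding dimension (default 2).
#' @param apen_r_frac ApEn tolerance as a fraction of the series SD (default 0.20).
#' @param apen_window_len,apen_window_step Window length/step (samples) for the
#'   windowed ApEn time course.
#' @param downward_threshold Beat-to-beat drop (bpm) that marks a downward
#'   (parasympathetic) beat; default 5.
#' @param noise_run_len Minimum run length of sub-cutoff samples treated as
#'   post-delivery noise; default 5.
#' @param noise_bpm_cut Noise cutoff in bpm (strictly below); default 100.
#' @param diff_stable_halfwidth Half-width (bpm) of the "stable" band of
#'   beat-to-beat differences used by the symbol encoder; default 2.
#' @param symbol_window_len,symbol_window_step Number of consecutive-beat
#'   differences per symbol window and the step between windows; defaults 60/60
#'   (non-overlapping, one symbol per minute at 1 Hz).
#' @param bw_tol Convergence tolerance on the Baum-Welch log-likelihood delta.
#' @param bw_max_iter Maximum Baum-Welch iterations.
#' @param rng_seed Integer seed for all stochastic stages.
#' @return An object of class `fetalph_config` (a named list).
#' @export
run_config <- function(apen_m = 2L, apen_r_frac = 0.2,
                       apen_window_len = 256L, apen_window_step = 128L,
                       downward_threshold = 5, noise_run_len = 5L,
                       noise_bpm_cut = 100, diff_stable_halfwidth = 2,
                       symbol_window_len = 60L, symbol_window_step = 60L,
                       bw_tol = 1e-6, bw_max_iter = 500L, rng_seed = 1L) {
  cfg <- list(
    apen_m = as.integer(apen_m), apen_r_frac = apen_r_frac,
    apen_window_len = as.integer(apen_window_len),
    apen_window_step = as.integer(apen_window_step),
    downward_threshold = downward_threshold,
    noise_run_len = as.integer(noise_run_len),
    noise_bpm_cut = noise_bpm_cut,
    diff_stable_halfwidth = diff_stable_halfwidth,
    symbol_window_len = as.integer(symbol_window_len),
    symbol_window_step = as.integer(symbol_window_step),
    bw_tol = bw_tol, bw_max_iter = as.integer(bw_max_iter),
    rng_seed = as.integer(rng_seed)
  )
  num <- vapply(cfg, function(v) as.numeric(v)[1], numeric(1))
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all configuration values must be positive", call. = FALSE)
  }
  if (cfg$apen_window_step > cfg$apen_window_len ||
      cfg$symbol_window_step > cfg$symbol_window_len) {
    stop("window step must not exceed window length", call. = FALSE)
  }
  structure(cfg, class = "fetalph_config")
}
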