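#' Specification of a synthetic intrapartum cohort
#'
#' Defines the generative parameters for class-conditioned synthetic fetal
#' heart rate traces standing in for private clinical data. Each acid-base
#' class has a characteristic event signature on top of a wandering baseline
#' with autoregressive beat-scale jitter:
#'
#' * **H1** (severe acidosis): frequent deep decelerations with steep descent
#'   *and* steep recovery;
#' * **H2**: frequent deep decelerations with slow, creeping recovery;
#' * **H3**: frequent accelerations (steep ascent, slow return), a sign of a
#'   responsive fetus;
#' * **H4** (normal): no large events, just relatively irregular jitter.
#'
#' All classes additionally receive sporadic mild dips, occasional deep
#' single-beat drops (>= 5 bpm, so every class shows some downward beats),
#' rare upward jumps, outlier spikes, and a post-delivery noise tail of
#' consecutive sub-100 bpm samples. Jitter persistence decreases and jitter
#' scale increases from H1 to H4, so heart-rate complexity (ApEn) rises with
#' pH -- the positive ApEn--pH coupling seen clinically.
#'
#' @param n_per_class Recordings per class H1..H4; default the imbalanced
#'   clinical distribution `c(21, 50, 146, 252)` (469 in all). Use
#'   `rep(21, 4)` for a balanced cohort.
#' @param trace_len Samples per trace before the noise tail; default 3600
#'   (nominal one hour at 1 Hz, matching the longer-than-one-hour inclusion
#'   rule).
#' @param baseline_range bpm range the per-recording baseline is drawn from.
#' @param jitter_sd AR(1) innovation SD per class (bpm).
#' @param jitter_phi AR(1) persistence per class.
#' @param event_prob Per-50-sample-block probability of the class's
#'   characteristic event (decel/accel), per class.
#' @param decel_depth Mean deceleration depth (bpm, >= 5); the per-recording
#'   depth is `decel_depth * runif(0.95, 1.05)`, drawn once and shared by all
#'   of that recording's decelerations (stereotyped recurrent decelerations).
#' @param accel_amp Mean acceleration amplitude (bpm), per-recording like
#'   `decel_depth`.
#' @param dip_rate,drop_rate,jump_rate Sporadic event rates per 100 samples
#'   (mild dips ~2.4 bpm, deep single-beat drops ~6 bpm, upward jumps
#'   ~4.5 bpm). `drop_rate` may be a per-class vector; the default gives the
#'   healthier classes more sporadic variable drops, so every class shows
#'   downward beats. H3/H4 recordings additionally contain 2-3 prolonged
#'   ~12 bpm drops with slow recovery.
#' @param outlier_rate Per-sample probability of an artifact spike.
#' @param noise_tail_len Length of the appended post-delivery tail
#'   (consecutive values < 100 bpm; >= 5 so the noise rule removes it).
#' @param ph_ranges 4x2 matrix of per-class pH sampling intervals.
#' @param seed Base integer seed; fixes the whole cohort.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_per_class = c(21L, 50L, 146L, 252L),
                                  trace_len = 3600L,
                                  baseline_range = c(130, 150),
                                  jitter_sd = c(0.45, 0.50, 0.50, 1.10),
                                  jitter_phi = c(0.92, 0.86, 0.80, 0.65),
                                  event_prob = c(0.75, 0.75, 0.75, 0),
                                  decel_depth = 25,
                                  accel_amp = 24,
                                  dip_rate = 1.0,
                                  drop_rate = c(0.3, 0.3, 3.0, 4.5),
                                  jump_rate = 0.15,
                                  outlier_rate = 8e-4,
                                  noise_tail_len = 30L,
                                  ph_ranges = rbind(c(7.05, 7.195),
                                                    c(7.20, 7.245),
                                                    c(7.25, 7.295),
                                                    c(7.30, 7.42)),
                                  seed = 1L) {
  spec <- structure(
    list(n_per_class = as.integer(n_per_class), trace_len = as.integer(trace_len),
         baseline_range = baseline_range, jitter_sd = jitter_sd,
         jitter_phi = jitter_phi, event_prob = event_prob,
         decel_depth = decel_depth, accel_amp = accel_amp,
         dip_rate = dip_rate, drop_rate = drop_rate, jump_rate = jump_rate,
         outlier_rate = outlier_rate, noise_tail_len = as.integer(noise_tail_len),
         ph_ranges = ph_ranges, seed = as.integer(seed)),
    class = "synthetic_cohort_spec"
  )
  if (length(spec$n_per_class) != 4 || any(spec$n_per_class < 0)) {
    stop("`n_per_class` must be 4 non-negative counts", call. = FALSE)
  }
  if (spec$decel_depth < 5) stop("deceleration depth must be >= 5 bpm", call. = FALSE)
  if (any(c(spec$dip_rate, spec$drop_rate, spec$jump_rate,
            spec$outlier_rate) < 0)) {
    stop("event rates must be >= 0", call. = FALSE)
  }
  if (spec$noise_tail_len < 5) {
    stop("`noise_tail_len` must be >= 5 so the tail qualifies as noise",
         call. = FALSE)
  }
  spec
}

#' Generate one synthetic intrapartum FHR trace
#'
#' Builds the class-conditioned trace described in
#' [synthetic_cohort_spec()]: baseline + AR(1) jitter + block-scheduled
#' characteristic events + sporadic dips/drops/jumps + outlier spikes +
#' post-delivery noise tail, with a blood gas panel whose pH is drawn
#' uniformly from the class's interval (and PCO2/PO2/HCO3/BE coupled to it).
#'
#' @param class Hidden class 1..4 (H1..H4).
#' @param spec A [synthetic_cohort_spec()].
#' @param seed Integer seed; the same seed reproduces the trace exactly.
#' @param record_id Identifier for the recording.
#' @return An [fhr_recording()] with panel attached.
#' @export
generate_trace <- function(class, spec = synthetic_cohort_spec(), seed = 1L,
                           record_id = sprintf("S%d_%06d", class, seed %% 1e6)) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  class <- as.integer(class)
  if (class < 1 || class > 4) stop("`class` must be in 1..4", call. = FALSE)
  n <- spec$trace_len
  with_seed(seed, {
    base <- stats::runif(1, spec$baseline_range[1], spec$baseline_range[2])
    # AR(1) beat-scale jitter, stationary start
    phi <- spec$jitter_phi[class]
    s <- spec$jitter_sd[class]
    innov <- stats::rnorm(n, 0, s)
    j0 <- stats::rnorm(1, 0, s / sqrt(1 - phi^2))
    jitter <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                       init = j0))
    dev <- numeric(n)
    # free[i]: no event occupies sample i yet; events never stack, so the
    # per-recording difference ranges (which anchor the subgroup midpoints)
    # stay where the event shapes put them
    free <- rep(TRUE, n)
    # recurrent decelerations/accelerations are stereotyped within a labour:
    # the event amplitude is drawn once per recording, so the deep
    # beat-to-beat steps form a tight cluster well separated from the mild
    # (~2 bpm) anchors in the per-recording difference range
    depth <- spec$decel_depth * stats::runif(1, 0.95, 1.05)
    amp <- spec$accel_amp * stats::runif(1, 0.95, 1.05)
    # characteristic events, at most one per 50-sample block
    block <- 50L
    for (b0 in seq(1L, n - block + 1L, by = block)) {
      if (stats::runif(1) >= spec$event_prob[class]) next
      if (class %in% c(1L, 2L)) {
        # steep 3-step descent; H1 also recovers steeply, H2 creeps back
        rec_len <- if (class == 1L) 3L else 28L
        shape <- c(seq(-depth / 3, -depth, length.out = 3), rep(-depth, 6),
                   seq(-depth + depth / rec_len, 0, length.out = rec_len))
      } else if (class == 3L) {
        # steep 3-step ascent, slow return
        shape <- c(seq(amp / 3, amp, length.out = 3), rep(amp, 4),
                   seq(amp - amp / 30, 0, length.out = 30))
      } else {
        next
      }
      off <- sample.int(block - length(shape) + 1L, 1) - 1L
      idx <- (b0 + off):(b0 + off + length(shape) - 1L)
      dev[idx] <- dev[idx] + shape
      free[max(1L, idx[1] - 2L):min(n, idx[length(idx)] + 2L)] <- FALSE
    }
    # sporadic small-scale events, all classes, placed in event-free gaps
    drop_rate <- rep_len(spec$drop_rate, 4)[class]
    sp <- list(
      list(k = stats::rpois(1, spec$dip_rate * n / 100),
           fn = function() -stats::runif(1, 2.2, 2.8)),
      list(k = stats::rpois(1, drop_rate * n / 100), fn = function() {
        d <- -stats::runif(1, 5.5, 6.5)          # deep single-beat drop
        d * seq(1, 1 / 6, length.out = 6)        # gentle 1-bpm-step recovery
      }),
      list(k = stats::rpois(1, spec$jump_rate * n / 100), fn = function() {
        c(stats::runif(1, 4.3, 4.7), 3, 1.5)     # upward jump, gentle decay
      })
    )
    if (class >= 3L) {
      # prolonged deep drops: anchor the recording's D-difference range so
      # the ordinary ~6 bpm drops stay on the mild side of its midpoint
      sp <- c(sp, list(list(k = 2L + stats::rpois(1, 0.3), fn = function() {
        d <- -12 * stats::runif(1, 0.95, 1.05)
        d * seq(1, 1 / 12, length.out = 12)
      })))
    }
    for (ev in sp) {
      for (kk in seq_len(ev$k)) {
        shape <- ev$fn()
        slots <- which(free[seq_len(n - length(shape))])
        if (length(slots) == 0) break
        p <- slots[sample.int(length(slots), 1)]
        idx <- p:(p + length(shape) - 1L)
        dev[idx] <- dev[idx] + shape
        free[max(1L, p - 2L):min(n, idx[length(idx)] + 2L)] <- FALSE
      }
    }
    bpm <- base + jitter + dev
    # artifact spikes (the 3-sigma rule's target), on baseline samples where
    # they stand clear of the band regardless of event excursions
    n_spike <- stats::rpois(1, spec$outlier_rate * n)
    slots <- which(free)
    if (n_spike > 0 && length(slots) > 0) {
      at <- slots[sample.int(length(slots), min(n_spike, length(slots)))]
      bpm[at] <- bpm[at] + sample(c(-1, 1), length(at), replace = TRUE) *
        stats::runif(length(at), 40, 70)
    }
    bpm <- pmax(bpm, 30)
    # post-delivery noise tail: >= 5 consecutive values < 100 bpm
    tail_vals <- stats::runif(spec$noise_tail_len, 55, 95)
    bpm <- c(bpm, tail_vals)
    pH <- stats::runif(1, spec$ph_ranges[class, 1], spec$ph_ranges[class, 2])
    panel <- blood_gas_panel(
      pH = pH,
      PCO2 = 50 + 120 * (7.3 - pH) + stats::rnorm(1, 0, 3),
      PO2 = max(5, 18 + 40 * (pH - 7.2) + stats::rnorm(1, 0, 2)),
      HCO3 = 22 + 30 * (pH - 7.3) + stats::rnorm(1, 0, 1),
      BE = -4 + 40 * (pH - 7.3) + stats::rnorm(1, 0, 1.5)
    )
    fhr_recording(bpm = bpm, record_id = record_id, panel = panel)
  })
}

#' Generate a labelled synthetic cohort with blood gas panels
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return List with `recordings` (list of [fhr_recording()], panels
#'   attached), `classes` (integer vector 1..4), and `panels` (named list of
#'   [blood_gas_panel()] keyed by record id).
#' @examples
#' coh <- generate_cohort(synthetic_cohort_spec(n_per_class = rep(2, 4),
#'                                              trace_len = 600))
#' table(coh$classes)
#' @export
generate_cohort <- function(spec = synthetic_cohort_spec()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  recordings <- list()
  classes <- integer(0)
  idx <- 0L
  for (j in 1:4) {
    for (i in seq_len(spec$n_per_class[j])) {
      idx <- idx + 1L
      seed_i <- (spec$seed + 7919L * j + i) %% 2147483647L
      rec <- generate_trace(j, spec, seed = seed_i,
                            record_id = sprintf("S%d_%03d", j, i))
      recordings[[rec$record_id]] <- rec
      classes <- c(classes, j)
    }
  }
  panels <- lapply(recordings, function(r) r$panel)
  list(recordings = recordings, classes = classes, panels = panels)
}

#' A well-separated ground-truth HMM for recovery experiments
#'
#' Transition matrix with dominant self-transitions and an emission matrix in
#' which each hidden state concentrates on its own pair of symbols; the
#' minimum inter-row total-variation distance of `B` is reported so tests can
#' assert the separation the recovery guarantee relies on.
#'
#' @param self Transition self-probability (default 0.85).
#' @param conc Emission mass on each of the state's two preferred symbols
#'   (default 0.44).
#' @return List with `params` ([hmm_params()]) and `min_row_tv` (minimum
#'   pairwise total-variation distance between emission rows).
#' @export
ground_truth_hmm <- function(self = 0.85, conc = 0.44) {
  A <- matrix((1 - self) / 3, 4, 4)
  diag(A) <- self
  B <- matrix((1 - 2 * conc) / 6, 4, 8)
  for (j in 1:4) B[j, c(2 * j - 1, 2 * j)] <- conc
  params <- hmm_params(pi = rep(0.25, 4), A = A, B = B)
  tv <- Inf
  for (i in 1:3) for (j in (i + 1):4) {
    tv <- min(tv, 0.5 * sum(abs(B[i, ] - B[j, ])))
  }
  list(params = params, min_row_tv = tv)
}

#' Sample symbol sequences from a known HMM
#'
#' Exact ancestral sampling from `(pi, A, B)`; the hidden paths are returned
#' alongside the symbols so tests can verify decoders against the truth.
#'
#' @param params An [hmm_params()] (e.g. `ground_truth_hmm()$params`).
#' @param n_seq Number of sequences.
#' @param len Length of each sequence.
#' @param seed Integer seed.
#' @return List with `symbols` (n_seq x len integer matrix, codes 1..8) and
#'   `states` (n_seq x len integer matrix, 1..4).
#' @export
generate_hmm_sequences <- function(params, n_seq, len, seed = 1L) {
  validate_hmm_params(params)
  n_seq <- as.integer(n_seq); len <- as.integer(len)
  cumA <- t(apply(params$A, 1, cumsum))
  cumB <- t(apply(params$B, 1, cumsum))
  with_seed(seed, {
    states <- matrix(0L, n_seq, len)
    symbols <- matrix(0L, n_seq, len)
    states[, 1] <- sample.int(4, n_seq, replace = TRUE, prob = params$pi)
    for (t in seq_len(len)) {
      if (t > 1) {
        u <- stats::runif(n_seq)
        states[, t] <- 1L + rowSums(u > cumA[states[, t - 1], , drop = FALSE])
      }
      u <- stats::runif(n_seq)
      symbols[, t] <- 1L + rowSums(u > cumB[states[, t], , drop = FALSE])
    }
    list(symbols = symbols, states = states)
  })
}
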