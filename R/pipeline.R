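#' Run the end-to-end prediction pipeline
#'
#' Orchestrates the full workflow on a labelled cohort: clean each recording
#' (noise runs, then the 3-sigma band), partition beats and compute
#' branch-level approximate entropy and its cohort correlations with the
#' blood gas panel, symbolize each cleaned series, draw a balanced
#' stratified train/test split, estimate initial HMM parameters from the
#' training labels, refine them with Baum-Welch, and evaluate Viterbi-based
#' classification on the held-out test set.
#'
#' When no cohort is supplied, a balanced synthetic cohort (21 recordings
#' per class) is generated. Every stochastic stage derives its seed from the
#' single `seed` argument, so a run is fully reproducible.
#'
#' @param cohort Optional list with `recordings` and `classes` as returned by
#'   [generate_cohort()]; recordings must carry blood gas panels with pH.
#' @param config A [run_config()].
#' @param spec A [synthetic_cohort_spec()] used only when `cohort` is `NULL`
#'   (its `n_per_class` defaults to balanced 21 per class here).
#' @param per_class,train,test Balanced-split sizes (defaults 21/15/6).
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, the confusion matrix
#'   (CSV), metrics (JSON), model (JSON) and config snapshot (YAML) are
#'   written there.
#' @return An object of class `pipeline_run`: list with `cleaning` (per-
#'   recording reports), `correlation` (downward and non-downward
#'   [cohort_correlation()] tables), `apen_t_test` (paired branch
#'   comparison), `split`, `init_params`, `params`, `loglik`, `evaluation`
#'   (confusion + metrics), `train_evaluation`, `seed`, `config`, `timing`.
#' @export
run_pipeline <- function(cohort = NULL, config = run_config(),
                         spec = NULL, per_class = 21L, train = 15L, test = 6L,
                         seed = 1L, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  if (is.null(cohort)) {
    if (is.null(spec)) {
      spec <- synthetic_cohort_spec(n_per_class = rep(as.integer(per_class), 4),
                                    seed = stage_seed(seed, "simulate"))
    }
    cohort <- generate_cohort(spec)
  }
  tick("simulate")
  recs <- cohort$recordings
  classes <- as.integer(cohort$classes)
  if (length(recs) == 0) stop("pipeline aborted at stage 'ingest': empty cohort",
                              call. = FALSE)

  cleaned <- vector("list", length(recs))
  reports <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    out <- clean_recording(recs[[i]], run_len = config$noise_run_len,
                           cut = config$noise_bpm_cut)
    cleaned[[i]] <- out$recording
    reports[[i]] <- out$report
  }
  names(cleaned) <- names(recs)
  tick("clean")

  corr_down <- cohort_correlation(cleaned, "downward",
                                  threshold = config$downward_threshold,
                                  m = config$apen_m, r_frac = config$apen_r_frac)
  corr_nond <- cohort_correlation(cleaned, "non-downward",
                                  threshold = config$downward_threshold,
                                  m = config$apen_m, r_frac = config$apen_r_frac)
  a_down <- attr(corr_down, "apen")
  a_nond <- attr(corr_nond, "apen")
  ok <- !is.na(a_down) & !is.na(a_nond)
  apen_t <- if (sum(ok) >= 2 && stats::sd(a_down[ok] - a_nond[ok]) > 0) {
    paired_t_test(a_down[ok], a_nond[ok])
  } else NULL
  tick("complexity")

  sequences <- lapply(cleaned, function(r) {
    symbolize(r, window_len = config$symbol_window_len,
              window_step = config$symbol_window_step,
              halfwidth = config$diff_stable_halfwidth)
  })
  tick("symbolize")

  split <- balance_cohort(classes, per_class = per_class, train = train,
                          test = test, seed = stage_seed(seed, "split"))
  tr_seq <- sequences[split$train]
  tr_cls <- classes[split$train]
  B0 <- estimate_emissions(tr_seq, tr_cls)
  A0 <- init_transitions(tr_cls, vapply(tr_seq, function(s) length(s$symbols),
                                        integer(1)))
  init <- hmm_params(pi = rep(0.25, 4), A = A0, B = B0)
  fit <- baum_welch(tr_seq, init = init, tol = config$bw_tol,
                    max_iter = config$bw_max_iter)
  tick("train")

  ev_test <- evaluate_model(fit$params, sequences[split$test],
                            classes[split$test])
  ev_train <- evaluate_model(fit$params, tr_seq, tr_cls)
  tick("evaluate")

  run <- structure(
    list(cleaning = reports,
         correlation = list(downward = corr_down, `non-downward` = corr_nond),
         apen_t_test = apen_t,
         sequences = sequences, classes = classes, split = split,
         init_params = init, params = fit$params, loglik = fit$loglik,
         evaluation = ev_test, train_evaluation = ev_train,
         seed = as.integer(seed), config = config, timing = timing),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(unclass(ev_test$confusion)),
                     file.path(out_dir, "confusion_test.csv"))
    jsonlite::write_json(
      list(overall_accuracy = ev_test$metrics$overall_accuracy,
           per_class = ev_test$metrics$per_class,
           train_overall_accuracy = ev_train$metrics$overall_accuracy,
           seed = run$seed),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    write_model(fit$params, file.path(out_dir, "model.json"))
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d recordings, seed %d\n",
              length(x$classes), x$seed))
  cat(sprintf("  test accuracy %.3f | train accuracy %.3f | %d EM iterations\n",
              x$evaluation$metrics$overall_accuracy,
              x$train_evaluation$metrics$overall_accuracy,
              length(x$loglik)))
  invisible(x)
}

# derive a per-stage seed from the master seed and the stage name; stable
# across sessions (no hashing libraries), always < 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

#' Reference confusion matrices from the original clinical study
#'
#' Loads the four published confusion matrices (training/testing on the
#' imbalanced 469-recording cohort and on the balanced 21-per-class cohort)
#' that ship with the package as plain-text fixtures, so their metrics can be
#' recomputed with [class_metrics()].
#'
#' @param which One of `"train_imbalanced"`, `"test_imbalanced"`,
#'   `"train_balanced"`, `"test_balanced"`.
#' @return A 4x4 integer `confusion_matrix4`.
#' @examples
#' cm <- reported_confusion("train_balanced")
#' class_metrics(cm)$overall_accuracy
#' @export
reported_confusion <- function(which = c("train_imbalanced", "test_imbalanced",
                                         "train_balanced", "test_balanced")) {
  which <- match.arg(which)
  path <- system.file("extdata", "reported",
                      paste0("confusion_", which, ".csv"),
                      package = "fetalph", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1)
  cm <- as.matrix(df)
  dimnames(cm) <- list(actual = state_labels(), predicted = state_labels())
  structure(matrix(as.integer(cm), 4, 4, dimnames = dimnames(cm)),
            class = c("confusion_matrix4", "matrix", "array"))
}
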