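#' Confusion matrix over the four acid-base classes
#'
#' Entry (i, j) counts recordings whose actual class is `H_i` and predicted
#' class `H_j`.
#'
#' @param actual,predicted Integer vectors (1..4) or labels `"H1".."H4"` of
#'   equal length >= 1.
#' @return A 4x4 integer matrix with `H1..H4` dimnames, class
#'   `confusion_matrix4`.
#' @examples
#' confusion_matrix(c(1, 1, 3), c(1, 3, 3))
#' @export
confusion_matrix <- function(actual, predicted) {
  a <- coerce_classes(actual)
  p <- coerce_classes(predicted)
  if (length(a) != length(p)) {
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(a) < 1) stop("need at least one pair", call. = FALSE)
  cm <- matrix(0L, 4, 4, dimnames = list(actual = state_labels(),
                                         predicted = state_labels()))
  for (k in seq_along(a)) cm[a[k], p[k]] <- cm[a[k], p[k]] + 1L
  structure(cm, class = c("confusion_matrix4", "matrix", "array"))
}

#' @export
print.confusion_matrix4 <- function(x, ...) {
  print(matrix(as.integer(x), 4, 4, dimnames = dimnames(x)))
  invisible(x)
}

coerce_classes <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- match(as.character(x), state_labels())
  }
  x <- as.integer(x)
  if (anyNA(x) || any(x < 1L | x > 4L)) {
    stop("class labels must be H1..H4 (or integers 1..4)", call. = FALSE)
  }
  x
}

#' Per-class and overall metrics from a confusion matrix
#'
#' One-vs-rest metrics for each class: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` (defined as 0, with a flag, when the
#' class is never predicted, so F1 is always defined), F1 (harmonic mean of
#' precision and sensitivity), and binary accuracy `(TP+TN)/total`. Overall
#' accuracy is `trace/total`.
#'
#' @param cm A 4x4 confusion matrix (counts; rows actual, columns predicted).
#' @return An object of class `class_metrics`: list with `per_class` (data
#'   frame: class, sensitivity, specificity, precision, f1, accuracy,
#'   empty_prediction flag) and `overall_accuracy`.
#' @examples
#' cm <- confusion_matrix(rep(1:4, each = 10), rep(1:4, each = 10))
#' class_metrics(cm)$overall_accuracy
#' @export
class_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (!all(dim(cm) == c(4, 4)) || any(cm < 0)) {
    stop("expected a 4x4 non-negative count matrix", call. = FALSE)
  }
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  rows <- lapply(1:4, function(i) {
    TP <- cm[i, i]
    FN <- sum(cm[i, ]) - TP
    FP <- sum(cm[, i]) - TP
    TN <- total - TP - FN - FP
    sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    empty <- (TP + FP) == 0
    prec <- if (!empty) TP / (TP + FP) else 0
    f1 <- if (!is.na(sens) && (prec + sens) > 0) 2 * prec * sens / (prec + sens) else 0
    data.frame(class = state_labels()[i], sensitivity = sens,
               specificity = spec, precision = prec, f1 = f1,
               accuracy = (TP + TN) / total, empty_prediction = empty,
               stringsAsFactors = FALSE)
  })
  structure(
    list(per_class = do.call(rbind, rows),
         overall_accuracy = sum(diag(cm)) / total,
         total = total),
    class = "class_metrics"
  )
}

#' @export
print.class_metrics <- function(x, ...) {
  df <- x$per_class
  df[2:6] <- lapply(df[2:6], round2)
  print(df[, 1:6], row.names = FALSE)
  cat(sprintf("Overall accuracy %d%%\n", round(100 * x$overall_accuracy)))
  invisible(x)
}

#' Round half away from zero
#'
#' Two-decimal reporting convention for the metric tables (base R's `round()`
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places, default 2.
#' @return Rounded vector.
#' @export
round2 <- function(x, digits = 2) {
  # tiny epsilon so ratios whose decimal value is exactly .xx5 but whose
  # double representation falls a hair short still round up
  sign(x) * floor(abs(x) * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' Balanced stratified train/test split
#'
#' Draws `per_class` recordings per class uniformly without replacement
#' (seeded), assigning `train` of them to the training set and `test` to the
#' test set. Classes with fewer than `per_class` members raise an error
#' naming the class.
#'
#' @param classes Integer vector (1..4) of cohort class labels.
#' @param per_class Samples drawn per class (default 21).
#' @param train,test Per-class training/test counts (defaults 15/6;
#'   `train + test` must equal `per_class`).
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with integer index vectors `train` and `test` (disjoint).
#' @export
balance_cohort <- function(classes, per_class = 21L, train = 15L, test = 6L,
                           seed = 1L) {
  classes <- coerce_classes(classes)
  per_class <- as.integer(per_class)
  if (train + test != per_class) {
    stop("`train` + `test` must equal `per_class`", call. = FALSE)
  }
  counts <- tabulate(classes, nbins = 4)
  short <- which(counts < per_class)
  if (length(short) > 0) {
    stop(sprintf("class %s has only %d members (< %d required)",
                 state_labels()[short[1]], counts[short[1]], per_class),
         call. = FALSE)
  }
  tr <- integer(0); te <- integer(0)
  with_seed(seed, {
    for (j in 1:4) {
      pool <- which(classes == j)
      pick <- sample(pool, per_class)
      tr <- c(tr, pick[seq_len(train)])
      te <- c(te, pick[train + seq_len(test)])
    }
  })
  list(train = tr, test = te)
}

#' Evaluate a trained model on a labelled test set
#'
#' Classifies each test sequence with [classify_recording()] and tabulates
#' predictions against the true classes.
#'
#' @param params A trained [hmm_params()].
#' @param sequences List of [symbolize()] results or integer vectors, the
#'   test set.
#' @param classes True classes (1..4), one per sequence.
#' @param rule Classification rule, see [classify_recording()].
#' @return List with `confusion` ([confusion_matrix()]) and `metrics`
#'   ([class_metrics()]).
#' @export
evaluate_model <- function(params, sequences, classes,
                           rule = c("final", "majority")) {
  rule <- match.arg(rule)
  if (length(sequences) == 0) stop("empty test set", call. = FALSE)
  preds <- vapply(sequences, classify_recording, integer(1),
                  params = params, rule = rule)
  cm <- confusion_matrix(classes, preds)
  list(confusion = cm, metrics = class_metrics(cm), predicted = preds)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
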