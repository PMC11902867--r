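#' Read FHR recordings from delimited text
#'
#' Accepts either a single-recording file with columns (`t?`, `bpm`) or a
#' long-format file keyed by `record_id` with columns
#' (`record_id`, `t?`, `bpm`). The time column is optional; when absent,
#' samples are indexed 0, 1, 2, ... at an assumed uniform interval. Rows with
#' non-positive or non-finite bpm, or with a time that does not strictly
#' increase within its recording, are dropped and counted in the attached
#' report.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param schema Optional named character vector remapping column names, e.g.
#'   `c(bpm = "FHR", t = "time_s")`.
#' @return A list of [fhr_recording()] objects with attribute `"report"`: a
#'   data frame of per-recording dropped-row counts.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(t = 0:3, bpm = c(140, 141, 139, 142)), f, row.names = FALSE)
#' recs <- read_recordings(f)
#' length(recs[[1]]$bpm)
#' @export
read_recordings <- function(path, schema = NULL) {
  df <- read_delimited(path)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      names(df)[names(df) == schema[[std]]] <- std
    }
  }
  if (!"bpm" %in% names(df)) {
    stop("input is missing a 'bpm' column", call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop("input file contains no data rows", call. = FALSE)
  }
  ids <- if ("record_id" %in% names(df)) as.character(df$record_id) else
    rep("rec", nrow(df))
  recs <- list()
  report <- list()
  for (id in unique(ids)) {
    sub <- df[ids == id, , drop = FALSE]
    bpm <- suppressWarnings(as.numeric(sub$bpm))
    tt <- if ("t" %in% names(sub)) suppressWarnings(as.numeric(sub$t)) else
      seq_len(nrow(sub)) - 1
    bad_bpm <- is.na(bpm) | !is.finite(bpm) | bpm <= 0
    bad_t <- is.na(tt) | !is.finite(tt) | tt < 0
    keep <- !(bad_bpm | bad_t)
    # enforce strictly increasing time: drop any row not above the running max
    n_nonmono <- 0L
    if (any(keep)) {
      idx <- which(keep)
      run_max <- -Inf
      for (i in idx) {
        if (tt[i] <= run_max) {
          keep[i] <- FALSE
          n_nonmono <- n_nonmono + 1L
        } else {
          run_max <- tt[i]
        }
      }
    }
    report[[id]] <- data.frame(
      record_id = id,
      n_rows = nrow(sub),
      n_dropped_bpm = sum(bad_bpm),
      n_dropped_time = sum(bad_t & !bad_bpm) + n_nonmono,
      n_kept = sum(keep),
      stringsAsFactors = FALSE
    )
    if (sum(keep) >= 2) {
      recs[[id]] <- fhr_recording(bpm = bpm[keep], t = tt[keep], record_id = id)
    }
  }
  if (length(recs) == 0) {
    stop("no recording with >= 2 valid samples found in ", path, call. = FALSE)
  }
  structure(recs, report = do.call(rbind, unname(report)))
}

#' Write FHR recordings to CSV
#'
#' Long format with columns `record_id`, `t`, `bpm`; full double precision so
#' that [read_recordings()] reproduces the samples bit-exactly.
#'
#' @param recs A list of [fhr_recording()] objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recordings <- function(recs, path) {
  if (inherits(recs, "fhr_recording")) recs <- list(recs)
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(record_id = r$record_id, t = format_full(r$t),
               bpm = format_full(r$bpm), stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read blood gas panels from CSV
#'
#' Expects columns `record_id`, `pH` and optionally `PCO2`, `PO2`, `HCO3`,
#' `BE`.
#'
#' @param path CSV path.
#' @return Named list of [blood_gas_panel()] objects keyed by `record_id`.
#' @export
read_panels <- function(path) {
  df <- read_delimited(path)
  need <- c("record_id", "pH")
  if (!all(need %in% names(df))) {
    stop("panel file must contain columns 'record_id' and 'pH'", call. = FALSE)
  }
  get <- function(col, i) if (col %in% names(df)) as.numeric(df[[col]][i]) else NA_real_
  out <- list()
  for (i in seq_len(nrow(df))) {
    out[[as.character(df$record_id[i])]] <- blood_gas_panel(
      pH = as.numeric(df$pH[i]), PCO2 = get("PCO2", i), PO2 = get("PO2", i),
      HCO3 = get("HCO3", i), BE = get("BE", i)
    )
  }
  out
}

#' Write blood gas panels to CSV
#'
#' @param panels Named list of [blood_gas_panel()] objects keyed by record id.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panels <- function(panels, path) {
  df <- do.call(rbind, lapply(names(panels), function(id) {
    p <- panels[[id]]
    data.frame(record_id = id, pH = p$pH, PCO2 = p$PCO2, PO2 = p$PO2,
               HCO3 = p$HCO3, BE = p$BE, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write HMM parameters to JSON / read them back
#'
#' The model document stores `pi` (length 4), `A` (4x4 row-stochastic
#' transition matrix), `B` (4x8 row-stochastic emission matrix) and the state
#' and symbol labels, at full double precision so a write/read round trip is
#' exact. Reading validates stochasticity and rejects non-stochastic input.
#'
#' @param params An [hmm_params()] object.
#' @param path JSON path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns an
#'   [hmm_params()] object.
#' @examples
#' p <- hmm_params()
#' f <- tempfile(fileext = ".json")
#' write_model(p, f)
#' identical(read_model(f)$A, p$A)
#' @export
write_model <- function(params, path) {
  validate_hmm_params(params)
  doc <- list(
    pi = params$pi,
    A = apply(params$A, 1, identity, simplify = FALSE),
    B = apply(params$B, 1, identity, simplify = FALSE),
    state_labels = state_labels(),
    symbol_labels = symbol_labels()
  )
  # I(17): 17 significant digits, enough to reproduce any double exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- doc$A
  B <- doc$B
  if (is.list(A)) A <- do.call(rbind, A)
  if (is.list(B)) B <- do.call(rbind, B)
  params <- hmm_params(pi = as.numeric(doc$pi), A = A, B = B)
  params
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML path.
#' @param cfg A [run_config()] object.
#' @return `read_run_config()` returns a [run_config()]; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# -- internal helpers ---------------------------------------------------------

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("input file is empty: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  df
}

# full round-trip precision for doubles written as text
format_full <- function(x) formatC(x, digits = 17, format = "g")
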