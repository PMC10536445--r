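# Reading, cleaning, normalizing and windowing 1 Hz SpO2 records.

#' Construct a patient oximetry record
#'
#' A patient record holds one overnight SpO2 series sampled at 1 Hz together
#' with an aligned per-second binary apnea label (0 = normal, 1 = apnea) and,
#' optionally, the event annotations the labels were derived from.
#'
#' @param patient_id Character scalar identifying the patient.
#' @param spo2 Numeric vector of SpO2 percentages in `[0, 100]`; `NA` marks a
#'   missing sample.
#' @param labels Integer vector of the same length as `spo2`, each element
#'   0 (normal) or 1 (apnea).
#' @param events Optional data frame of event annotations with columns
#'   `start_s` (0-based second offset), `duration_s` and `kind`.
#' @param sampling_rate_hz Sampling rate; the pipeline assumes 1 Hz.
#' @param target_ahi Optional true apnea-hypopnea index (events/hour), kept
#'   as metadata by the simulator.
#'
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, spo2, labels, events = NULL,
                           sampling_rate_hz = 1, target_ahi = NULL) {
  spo2 <- as.numeric(spo2)
  labels <- as.integer(labels)
  if (length(spo2) != length(labels)) {
    stop("`spo2` and `labels` must have the same length", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must all be 0 or 1", call. = FALSE)
  }
  ok <- is.na(spo2) | (spo2 >= 0 & spo2 <= 100)
  if (!all(ok)) {
    stop("non-missing SpO2 values must lie in [0, 100]", call. = FALSE)
  }
  if (!is.null(events)) {
    events <- as.data.frame(events)
    stopifnot(all(c("start_s", "duration_s") %in% names(events)))
    if (nrow(events) > 0 &&
        (any(events$start_s < 0) ||
         any(events$start_s + events$duration_s > length(spo2)))) {
      stop("event annotations fall outside the record", call. = FALSE)
    }
    if (is.null(events$kind)) events$kind <- "apnea"
  }
  structure(
    list(patient_id = as.character(patient_id),
         sampling_rate_hz = sampling_rate_hz,
         spo2 = spo2, labels = labels, events = events,
         target_ahi = target_ahi),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  n <- length(x$spo2)
  cat(sprintf("<patient_record %s: %d s at %g Hz, %d apnea s (%.1f%%), %d missing>\n",
              x$patient_id, n, x$sampling_rate_hz, sum(x$labels),
              100 * mean(x$labels), sum(is.na(x$spo2))))
  if (!is.null(x$events)) cat(sprintf("  %d annotated events\n", nrow(x$events)))
  invisible(x)
}

#' Write a patient record to the per-patient CSV format
#'
#' Columns are `t_s` (integer seconds from 0, strictly increasing), `spo2`
#' (percent, formatted with 6 decimal places; empty cell for a missing
#' sample) and `label` (0/1). The filename stem is the patient id.
#'
#' @param record A [patient_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  spo2 <- ifelse(is.na(record$spo2), "", sprintf("%.6f", record$spo2))
  df <- data.frame(t_s = seq_along(record$spo2) - 1L,
                   spo2 = spo2, label = record$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_one_record <- function(file) {
  df <- utils::read.csv(file, colClasses = "character", strip.white = TRUE)
  need <- c("t_s", "spo2", "label")
  if (!all(need %in% names(df))) {
    stop(sprintf("structural error in %s: expected columns %s",
                 file, paste(need, collapse = ", ")), call. = FALSE)
  }
  t_s <- suppressWarnings(as.integer(df$t_s))
  if (anyNA(t_s) || any(diff(t_s) <= 0)) {
    stop(sprintf("structural error in %s: t_s must be strictly increasing integers",
                 file), call. = FALSE)
  }
  spo2 <- suppressWarnings(as.numeric(df$spo2))
  bad <- which(is.na(spo2) & nzchar(df$spo2))
  if (length(bad) > 0) {
    stop(sprintf("parse error in %s, line %d: non-numeric spo2 value '%s'",
                 file, bad[1] + 1L, df$spo2[bad[1]]), call. = FALSE)
  }
  lab <- suppressWarnings(as.integer(df$label))
  bad <- which(is.na(lab) | !(lab %in% c(0L, 1L)))
  if (length(bad) > 0) {
    stop(sprintf("parse error in %s, line %d: label '%s' is not 0 or 1",
                 file, bad[1] + 1L, df$label[bad[1]]), call. = FALSE)
  }
  patient_record(sub("\\.csv$", "", basename(file)), spo2, lab)
}

#' Read patient records from CSV files
#'
#' @param path A directory of per-patient CSV files, a single record CSV, or
#'   a plain-text manifest listing one record path per line.
#' @param dialect `"auto"` (default) infers from `path`; `"dir"`, `"file"`
#'   and `"manifest"` force an interpretation.
#'
#' @return A list of [patient_record()] objects.
#' @export
read_records <- function(path, dialect = c("auto", "dir", "file", "manifest")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("path '%s' does not exist", path), call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (dir.exists(path)) "dir"
      else if (grepl("\\.csv$", path, ignore.case = TRUE)) "file"
      else "manifest"
  }
  files <- switch(dialect,
    dir = sort(list.files(path, pattern = "\\.csv$", full.names = TRUE)),
    file = path,
    manifest = {
      p <- trimws(readLines(path, warn = FALSE))
      p[nzchar(p)]
    })
  if (length(files) == 0) stop("no record files found", call. = FALSE)
  lapply(files, read_one_record)
}

#' Drop missing SpO2 samples from a record
#'
#' Removes every missing (`NA`) SpO2 sample together with its aligned label,
#' preserving the relative order of the surviving samples. Because removal
#' shifts absolute second offsets, event annotations (if any) are dropped
#' alongside. The number of removed samples is attached as attribute
#' `"removed"`.
#'
#' @param record A [patient_record()].
#' @return A cleaned `patient_record` with attribute `removed`.
#' @export
drop_missing <- function(record) {
  miss <- is.na(record$spo2)
  removed <- sum(miss)
  if (removed == length(record$spo2)) {
    stop("record is empty after dropping missing samples", call. = FALSE)
  }
  out <- patient_record(record$patient_id,
                        record$spo2[!miss], record$labels[!miss],
                        events = if (removed == 0) record$events else NULL,
                        sampling_rate_hz = record$sampling_rate_hz,
                        target_ahi = record$target_ahi)
  attr(out, "removed") <- removed
  out
}

#' Min-max normalize a numeric sequence to `[0, 1]`
#'
#' `out_i = (v_i - min(v)) / (max(v) - min(v))`. A constant input maps to all
#' zeros so that flat SpO2 windows, which do occur in real recordings, pass
#' through the pipeline rather than erroring.
#'
#' @param values Non-empty numeric vector without missing values.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("missing values: run drop_missing() first", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Cut a record into fixed-length model-ready segments
#'
#' Windows start at offsets `0, stride_s, 2 * stride_s, ...`; a trailing
#' remainder shorter than `length_s` is discarded. Each segment's values are
#' min-max normalized independently (the model's input convention) unless
#' `normalize = FALSE` or `normalize = "record"` (one rescaling for the whole
#' record).
#'
#' @param record A clean [patient_record()] (no missing samples).
#' @param length_s Window length in seconds (the model sequence length).
#' @param stride_s Hop between window starts; defaults to `length_s`
#'   (non-overlapping).
#' @param normalize `TRUE` (per segment), `FALSE` (raw values), or
#'   `"record"`.
#' @return A list of segments, each a list with `values`, `labels`,
#'   `patient_id`, `start_s`, `length_s`.
#' @export
window_record <- function(record, length_s, stride_s = length_s,
                          normalize = TRUE) {
  if (anyNA(record$spo2)) stop("record has missing samples: run drop_missing() first", call. = FALSE)
  n <- length(record$spo2)
  stopifnot(length_s >= 1, stride_s >= 1)
  if (length_s > n) {
    warning(sprintf("record %s (%d s) is shorter than one %d s window",
                    record$patient_id, n, length_s))
    return(list())
  }
  vals <- record$spo2
  if (identical(normalize, "record")) vals <- minmax_normalize(vals)
  starts <- as.integer(seq(0L, n - length_s, by = stride_s))
  lapply(starts, function(s0) {
    idx <- (s0 + 1L):(s0 + length_s)
    v <- vals[idx]
    if (isTRUE(normalize)) v <- minmax_normalize(v)
    list(values = v, labels = record$labels[idx],
         patient_id = record$patient_id, start_s = s0, length_s = length_s)
  })
}

#' Split records or segments into train and test sets
#'
#' @param x A list of items: patient records (for `mode = "patient"`) or
#'   segments/records (for `mode = "segment"`, plain random split).
#' @param test_fraction Fraction held out, in (0, 1).
#' @param mode `"segment"` splits items at random; `"patient"` groups by
#'   `patient_id` so no patient contributes to both sides.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with elements `train` and `test`.
#' @export
split_holdout <- function(x, test_fraction, mode = c("segment", "patient"),
                          seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(test_fraction > 0, test_fraction < 1)
  with_seed(seed, {
    if (mode == "patient") {
      ids <- vapply(x, function(r) r$patient_id, character(1))
      uniq <- unique(ids)
      if (length(uniq) < 2) stop("patient-grouped split needs at least 2 patients", call. = FALSE)
      n_test <- max(1L, round(test_fraction * length(uniq)))
      test_ids <- sample(uniq, n_test)
      list(train = x[!(ids %in% test_ids)], test = x[ids %in% test_ids])
    } else {
      n <- length(x)
      if (n < 2) stop("need at least 2 items to split", call. = FALSE)
      n_test <- max(1L, round(test_fraction * n))
      test_idx <- sample(n, n_test)
      list(train = x[-test_idx], test = x[test_idx])
    }
  })
}

# Stack a list of segments into an (n x length_s) value matrix plus label
# matrix; used by the training and prediction paths.
segments_to_matrices <- function(segments) {
  stopifnot(length(segments) > 0)
  lens <- vapply(segments, function(s) length(s$values), integer(1))
  if (length(unique(lens)) != 1) stop("segments have mixed lengths", call. = FALSE)
  list(X = do.call(rbind, lapply(segments, function(s) s$values)),
       Y = do.call(rbind, lapply(segments, function(s) s$labels)))
}
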