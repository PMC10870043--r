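#' Multichannel EMG recording
#'
#' An `emg_recording` holds a channels-by-time matrix of surface EMG samples
#' in microvolts together with its sampling rate and channel labels. All
#' downstream stages (filtering, segmentation, covariance features) operate
#' on this container, so file formats never leak past the I/O layer.
#'
#' @param samples Numeric matrix, channels x time, microvolts.
#' @param rate Sampling frequency in Hz (scalar, > 0).
#' @param channel_names Optional character vector of channel identifiers;
#'   defaults to `ch1..chC`.
#' @param t0 Time of the first sample in seconds from recording start.
#'
#' @return An object of class `emg_recording` with fields `samples`, `rate`,
#'   `channel_names`, `t0`.
#'
#' @details Invariants enforced at construction: `rate > 0`, at least two
#'   channels (spatial covariance needs a cross-term), equal channel lengths
#'   (guaranteed by the matrix carrier), and no non-finite sample values.
#'   Units are fixed to microvolts; no automatic rescaling is ever applied.
#'
#' @examples
#' rec <- emg_recording(matrix(rnorm(200), nrow = 2), rate = 2000)
#' rec
#' @export
emg_recording <- function(samples, rate, channel_names = NULL, t0 = 0) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop_emg("invalid_samples", "`samples` must be a numeric matrix (channels x time)")
  }
  if (nrow(samples) < 2) {
    stop_emg("too_few_channels", "at least 2 channels are required, got ", nrow(samples))
  }
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop_emg("invalid_rate", "`rate` must be a single positive number")
  }
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop_emg("nonfinite_samples", "recording contains non-finite sample values")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(samples) || anyDuplicated(channel_names)) {
    stop_emg("invalid_channel_names", "`channel_names` must be unique, one per channel")
  }
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, rate = as.numeric(rate),
         channel_names = channel_names, t0 = as.numeric(t0)),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              n_channels(x), n_samples(x), x$rate, n_samples(x) / x$rate))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname emg_recording
#' @param x Object to test or query.
#' @export
is_emg_recording <- function(x) inherits(x, "emg_recording")

#' @rdname emg_recording
#' @export
n_channels <- function(x) nrow(x$samples)

#' @rdname emg_recording
#' @export
n_samples <- function(x) ncol(x$samples)

#' Convert a recording to a long tibble
#'
#' One row per (channel, sample): columns `time`, `channel`, `value`.
#' Convenient for ggplot2 display of short excerpts; the matrix carrier
#' remains the computational representation.
#'
#' @param x An `emg_recording`.
#' @param ... Unused.
#' @return A tibble with columns `time` (s), `channel`, `value` (uV).
#' @method as_tibble emg_recording
#' @export
as_tibble.emg_recording <- function(x, ...) {
  tibble::tibble(
    time = rep(x$t0 + (seq_len(n_samples(x)) - 1) / x$rate, each = n_channels(x)),
    channel = rep(x$channel_names, times = n_samples(x)),
    value = as.vector(x$samples)
  )
}

#' Gesture cue schedule
#'
#' Ordered gesture cues: each cue marks the onset (in recording time,
#' seconds) of an instructed gesture, its label, and the trial it belongs
#' to. Cue-relative windows (e.g. a -3..-1 s rest window) are obtained by
#' subtraction from `onset_s`, so the schedule itself stays in absolute
#' recording time.
#'
#' @param cues A data frame with columns `onset_s` (numeric, strictly
#'   increasing), `label` (character), `trial` (non-negative integer).
#' @param label_set Character vector: the gesture vocabulary. Defaults to
#'   the unique labels present, in order of first appearance.
#' @return An object of class `cue_schedule`: a tibble with attribute
#'   `label_set`.
#' @examples
#' cs <- cue_schedule(data.frame(onset_s = c(3, 9), label = c("I", "F"), trial = 0L))
#' @export
cue_schedule <- function(cues, label_set = NULL) {
  cues <- as.data.frame(cues)
  req <- c("onset_s", "label", "trial")
  if (!all(req %in% names(cues))) {
    stop_emg("malformed_cues", "cue table must have columns onset_s, label, trial")
  }
  cues$label <- as.character(cues$label)
  cues$trial <- as.integer(cues$trial)
  if (anyNA(cues$onset_s) || anyNA(cues$label) || anyNA(cues$trial)) {
    stop_emg("malformed_cues", "cue table contains missing values")
  }
  if (nrow(cues) > 1 && any(diff(cues$onset_s) <= 0)) {
    stop_emg("nonincreasing_onsets", "cue onsets must be strictly increasing")
  }
  if (any(cues$trial < 0)) {
    stop_emg("malformed_cues", "trial indices must be >= 0")
  }
  if (is.null(label_set)) label_set <- unique(cues$label)
  unknown <- setdiff(cues$label, label_set)
  if (length(unknown) > 0) {
    stop_emg("unknown_label", "labels not in label_set: ", paste(unknown, collapse = ", "))
  }
  out <- tibble::as_tibble(cues[, req])
  attr(out, "label_set") <- as.character(label_set)
  class(out) <- c("cue_schedule", class(out))
  out
}

#' @rdname cue_schedule
#' @param x Object to query.
#' @export
label_set <- function(x) attr(x, "label_set")

#' Gesture vocabulary used throughout the package
#'
#' The ten hand/wrist gesture labels: idle, left, right, up, down, fist,
#' spread, index, ring, pointing.
#' @return Character vector of length 10.
#' @export
gesture_labels <- function() {
  c("I", "L", "R", "U", "D", "F", "S", "IN", "RN", "P")
}

# ---- file formats ----------------------------------------------------------

#' Read and write EMG recordings
#'
#' Two on-disk formats are supported. `"csv"` is a text pair: a CSV with one
#' column per channel (samples as rows) plus a JSON sidecar `<path>.json`
#' carrying `rate`, `channel_names` and `t0`; values are written with 6
#' significant decimals, so a text round trip is exact to ~5e-7 relative.
#' `"rds"` is a single-file binary archive (R serialization) and round-trips
#' losslessly; use it for full-length sessions.
#'
#' @param path File path.
#' @param format `"csv"` or `"rds"`. `read_recording()` infers it from the
#'   extension when omitted.
#' @return `read_recording()` returns an `emg_recording`;
#'   `write_recording()` returns `path` invisibly.
#' @examples
#' rec <- emg_recording(matrix(rnorm(40), nrow = 2), rate = 2000)
#' p <- tempfile(fileext = ".rds")
#' write_recording(rec, p)
#' rec2 <- read_recording(p)
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop_emg("missing_file", "no such file: ", path)
  format <- format %||% infer_format(path)
  if (format == "rds") {
    obj <- readRDS(path)
    if (!is.list(obj) || !all(c("samples", "rate", "channel_names") %in% names(obj))) {
      stop_emg("malformed_header", "file is not an emg_recording archive")
    }
    # revalidate: stored files must satisfy the same invariants as fresh ones
    return(emg_recording(obj$samples, obj$rate, obj$channel_names, obj$t0))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop_emg("malformed_header", "missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$rate) || is.null(meta$channel_names)) {
    stop_emg("malformed_header", "sidecar must declare rate and channel_names")
  }
  first <- readLines(path, n = 1L)
  ncol_file <- length(strsplit(first, ",", fixed = TRUE)[[1]])
  if (ncol_file != length(meta$channel_names)) {
    stop_emg("ragged_channels", "column count (", ncol_file,
             ") does not match declared channels (", length(meta$channel_names), ")")
  }
  dat <- tryCatch(
    utils::read.csv(path, header = TRUE, colClasses = "numeric"),
    warning = function(w) stop_emg("ragged_channels", "ragged or malformed channel columns: ",
                                   conditionMessage(w)),
    error = function(e) stop_emg("ragged_channels", "ragged or malformed channel columns: ",
                                 conditionMessage(e))
  )
  samples <- t(as.matrix(dat))
  if (anyNA(samples)) {
    stop_emg("ragged_channels", "channels have unequal lengths (missing values on read)")
  }
  if (!all(is.finite(samples))) {
    stop_emg("nonfinite_samples", "file contains non-finite sample values")
  }
  emg_recording(samples, rate = meta$rate, channel_names = meta$channel_names,
                t0 = meta$t0 %||% 0)
}

#' @rdname read_recording
#' @param rec An `emg_recording`.
#' @export
write_recording <- function(rec, path, format = NULL) {
  if (!is_emg_recording(rec)) stop_emg("invalid_samples", "`rec` must be an emg_recording")
  format <- format %||% infer_format(path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_emg("unwritable_path", "directory does not exist: ", dir)
  if (format == "rds") {
    saveRDS(unclass(rec), path)
  } else {
    dat <- as.data.frame(t(rec$samples))
    names(dat) <- rec$channel_names
    dat[] <- lapply(dat, formatC, format = "f", digits = 6)  # fixed 6 decimals
    utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(rate = rec$rate, channel_names = rec$channel_names, t0 = rec$t0),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("rds")) "rds" else if (ext %in% c("csv", "txt")) "csv"
  else stop_emg("malformed_header", "cannot infer format from extension: .", ext)
}

#' Read and write cue schedules
#'
#' Cue schedules are CSV files with columns `onset_s,label,trial`. The label
#' vocabulary may be declared in an optional JSON sidecar `<path>.json`
#' (field `label_set`); otherwise it is taken from the labels present.
#'
#' @param path CSV file path.
#' @return `read_cue_schedule()` returns a `cue_schedule`.
#' @export
read_cue_schedule <- function(path) {
  if (!file.exists(path)) stop_emg("missing_file", "no such file: ", path)
  dat <- utils::read.csv(path, header = TRUE)
  labs <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    labs <- jsonlite::read_json(sidecar, simplifyVector = TRUE)$label_set
  }
  cue_schedule(dat, label_set = labs)
}

#' @rdname read_cue_schedule
#' @param cues A `cue_schedule`.
#' @export
write_cue_schedule <- function(cues, path) {
  utils::write.csv(as.data.frame(cues), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(label_set = label_set(cues)), paste0(path, ".json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# ---- error helper ----------------------------------------------------------

# All package errors carry a machine-readable subclass `emg_<code>` so tests
# and callers can discriminate failure modes without string matching.
stop_emg <- function(code, ...) {
  stop(structure(
    class = c(paste0("emg_", code), "emg_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
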