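# Reading and cataloguing Bonn-format single-channel EEG.
#
# The Bonn corpus distributes five sets (A-E) of 100 plain-text ASCII files,
# one amplitude per line, 4096 samples per file at 173.61 Hz. Sets A/B are
# scalp EEG from healthy volunteers (eyes open / closed), C/D interictal
# intracranial EEG (contralateral hippocampus / epileptogenic focus), and E
# ictal recordings from the seizure onset zone. Amplitudes are kept in raw
# ADC units: the recordings are already band-passed at acquisition, so no
# filtering or re-referencing happens on read.

BONN_FS <- 173.61
BONN_FILE_LEN <- 4096L

#' Construct a single-channel EEG recording
#'
#' @param samples numeric vector of amplitudes (raw ADC units).
#' @param fs sampling rate in Hz (Bonn default 173.61).
#' @param set_label set membership: one of "A".."E", or a synthetic class tag.
#' @param source_id file identifier string.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs = BONN_FS, set_label = NA_character_,
                          source_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stopf("a recording needs at least one sample")
  if (!is.finite(fs) || fs <= 0) stopf("sampling rate must be > 0, got %s", fs)
  structure(list(samples = samples, fs = fs,
                 set_label = as.character(set_label),
                 source_id = as.character(source_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [set %s]: %d samples @ %.2f Hz (%.1f s)\n",
              x$source_id, x$set_label, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Read one Bonn ASCII EEG file
#'
#' Parses a plain-text file with one numeric amplitude per line (surrounding
#' whitespace tolerated). Some distributed copies of the corpus carry one
#' extra trailing line; a file of `expected_len + 1` lines is truncated to
#' `expected_len` with a warning. Any larger deviation is an error, as is any
#' non-numeric line (reported with its line number). The set label is
#' configuration, never inferred from file content.
#'
#' @param path file path.
#' @param expected_len expected number of samples (default 4096).
#' @param set_label set label to attach (configuration, e.g. "A").
#' @param fs sampling rate in Hz.
#' @return an [eeg_recording].
#' @export
read_bonn_file <- function(path, expected_len = BONN_FILE_LEN,
                           set_label = NA_character_, fs = BONN_FS) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  # blank trailing lines are a file-ending artefact, not data
  if (length(keep) && !all(keep)) {
    last_data <- max(which(keep), 0L)
    if (any(!keep[seq_len(last_data)]))
      stopf("%s: blank line inside data at line %d", path,
            which(!keep[seq_len(last_data)])[1L])
    lines <- lines[seq_len(last_data)]
  }
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals))
    stopf("%s: non-numeric value %s at line %d", path,
          dQuote(lines[which(is.na(vals))[1L]]), which(is.na(vals))[1L])
  n <- length(vals)
  if (abs(n - expected_len) > 1L)
    stopf("%s: %d samples, expected %d (deviation > 1 line)",
          path, n, expected_len)
  if (n == expected_len + 1L) {
    warnf("%s: %d lines, dropping the trailing sample (known Bonn dialect)",
          path, n)
    vals <- vals[seq_len(expected_len)]
  }
  eeg_recording(vals, fs = fs, set_label = set_label,
                source_id = basename(path))
}

#' Write samples in the Bonn ASCII dialect (one value per line)
#'
#' @param samples numeric vector or an [eeg_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bonn_file <- function(samples, path) {
  if (inherits(samples, "eeg_recording")) samples <- samples$samples
  writeLines(format(samples, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Load every file of one Bonn set from a directory
#'
#' Files are read in sorted filename order and each recording is tagged with
#' `set_label`. The file count is logged but not enforced (the canonical
#' corpus has 100 per set).
#'
#' @param dir directory holding the set's ASCII files.
#' @param set_label label to attach to every recording.
#' @param expected_len,fs passed to [read_bonn_file()].
#' @param pattern filename filter (default: all regular files).
#' @return a list of [eeg_recording] objects.
#' @export
load_set <- function(dir, set_label, expected_len = BONN_FILE_LEN,
                     fs = BONN_FS, pattern = NULL) {
  if (!dir.exists(dir)) stopf("directory not found: %s", dir)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stopf("no files in %s for set %s", dir, set_label)
  recs <- vector("list", length(files))
  for (k in seq_along(files)) {
    recs[[k]] <- tryCatch(
      read_bonn_file(files[k], expected_len = expected_len,
                     set_label = set_label, fs = fs),
      error = function(e) stopf("while reading %s: %s",
                                basename(files[k]), conditionMessage(e)))
  }
  log_msg("bonn_io", "set %s: %d files from %s", set_label, length(recs), dir)
  recs
}

#' Define a dataset case (set-to-class grouping)
#'
#' A case names an experiment-level grouping of Bonn sets into classes, e.g.
#' "AB_vs_E" pools sets A and B as class 0 (normal) against E as class 1
#' (ictal). Class indices are 0-based and must cover 0..K-1.
#'
#' @param name case identifier.
#' @param class_map named integer vector mapping set labels to class indices.
#' @param n_classes number of classes K (2 or 3 in the canonical cases).
#' @return an object of class `dataset_case`.
#' @export
dataset_case <- function(name, class_map, n_classes = length(unique(class_map))) {
  class_map <- vapply(class_map, as.integer, integer(1))
  if (is.null(names(class_map)) || any(!nzchar(names(class_map))))
    stopf("class_map must be a named vector (set label -> class index)")
  if (any(class_map < 0L) || any(class_map >= n_classes))
    stopf("case %s: class indices must lie in 0..%d", name, n_classes - 1L)
  if (length(unique(class_map)) != n_classes)
    stopf("case %s: n_classes = %d but %d distinct class indices present",
          name, n_classes, length(unique(class_map)))
  structure(list(name = name, class_map = class_map,
                 n_classes = as.integer(n_classes)),
            class = "dataset_case")
}

#' The canonical seizure-detection dataset cases
#'
#' AB vs E (normal vs ictal), C vs E and D vs E (interictal vs ictal), and
#' A vs C vs E (normal vs interictal vs ictal). The ictal set E is always
#' the highest class index, which the binary metrics treat as positive.
#'
#' @return named list of [dataset_case] objects.
#' @export
bonn_cases <- function() {
  list(
    AB_vs_E     = dataset_case("AB_vs_E", c(A = 0L, B = 0L, E = 1L), 2L),
    C_vs_E      = dataset_case("C_vs_E", c(C = 0L, E = 1L), 2L),
    D_vs_E      = dataset_case("D_vs_E", c(D = 0L, E = 1L), 2L),
    A_vs_C_vs_E = dataset_case("A_vs_C_vs_E", c(A = 0L, C = 1L, E = 2L), 3L)
  )
}

#' Assemble the labelled recordings of a dataset case
#'
#' Concatenates the recordings of every set named in the case's class map
#' (set order as listed in the map, filename order within a set) and attaches
#' the class index to each recording as `$class_idx`.
#'
#' @param recordings_by_set named list: set label -> list of [eeg_recording].
#' @param case a [dataset_case].
#' @return a list of labelled recordings.
#' @export
build_case <- function(recordings_by_set, case) {
  stopifnot(inherits(case, "dataset_case"))
  out <- list()
  for (set in names(case$class_map)) {
    if (is.null(recordings_by_set[[set]]))
      stopf("case %s needs set %s, which is not present", case$name, set)
    cls <- case$class_map[[set]]
    recs <- lapply(recordings_by_set[[set]], function(r) {
      r$class_idx <- cls
      r
    })
    out <- c(out, recs)
  }
  log_msg("bonn_io", "case %s: %d recordings over %d classes",
          case$name, length(out), case$n_classes)
  out
}
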