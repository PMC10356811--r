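#' Construct a single-lead ECG record
#'
#' @param record_id Record identifier.
#' @param patient_id Patient identifier (several records may share one).
#' @param samples Numeric amplitude vector (mV, arbitrary baseline).
#' @param fs Sampling frequency in Hz.
#' @param lead_name Lead label.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, patient_id, samples, fs, lead_name = "MLII") {
  if (length(samples) < 1) stop("record must contain at least one sample")
  if (fs <= 0) stop("fs must be positive")
  structure(list(record_id = record_id, patient_id = patient_id,
                 samples = as.numeric(samples), fs = fs,
                 lead_name = lead_name),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record %s (patient %s): %d samples @ %g Hz (%.1f s), lead %s\n",
              x$record_id, x$patient_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$lead_name))
  invisible(x)
}

#' @export
plot.ecg_record <- function(x, from_s = 0, to_s = min(10, length(x$samples) / x$fs),
                            ...) {
  idx <- max(1, floor(from_s * x$fs) + 1):min(length(x$samples), ceiling(to_s * x$fs))
  graphics::plot((idx - 1) / x$fs, x$samples[idx], type = "l",
                 xlab = "time (s)", ylab = "amplitude (mV)",
                 main = paste("record", x$record_id), ...)
  invisible(x)
}

#' Open an ECG dataset directory
#'
#' Two on-disk layouts are understood, mirroring the two annotation
#' categories:
#' \describe{
#'   \item{beat-level}{WFDB-style records (`.hea`/`.dat`/`.atr`), a
#'     `RECORDS` file enumerating record names and an optional
#'     `patients.csv` (`record_id,patient_id`; records default to being
#'     their own patient).}
#'   \item{recording-level}{WFDB-style signal files plus a `labels.csv`
#'     table with columns `record_id,patient_id,labels` (labels
#'     `;`-separated, first label used for single-label tasks).}
#' }
#'
#' @param root Dataset directory.
#' @param name Dataset name used for label-dictionary lookups; defaults to
#'   the directory basename.
#' @param lead Lead to extract from multi-lead records; `NULL` takes each
#'   record's first lead.
#' @return An object of class `ecg_dataset`.
#' @export
open_dataset <- function(root, name = basename(root), lead = NULL) {
  if (!dir.exists(root)) stop("dataset directory not found: ", root)
  labels_path <- file.path(root, "labels.csv")
  if (file.exists(labels_path)) {
    labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE,
                              colClasses = "character")
    if (!all(c("record_id", "patient_id", "labels") %in% names(labels))) {
      stop("labels.csv must have columns record_id,patient_id,labels")
    }
    if (!nrow(labels)) stop("empty dataset: no rows in labels.csv")
    if (anyDuplicated(labels$record_id)) {
      stop("duplicate record_id in labels.csv")
    }
    records <- labels[, c("record_id", "patient_id")]
    category <- "recording_level"
  } else {
    rec_path <- file.path(root, "RECORDS")
    if (file.exists(rec_path)) {
      ids <- readLines(rec_path, warn = FALSE)
      ids <- ids[nzchar(trimws(ids))]
    } else {
      ids <- sort(sub("\\.hea$", "", basename(
        list.files(root, pattern = "\\.hea$"))))
    }
    if (!length(ids)) stop("empty dataset: no records found in ", root)
    pat_path <- file.path(root, "patients.csv")
    if (file.exists(pat_path)) {
      pm <- utils::read.csv(pat_path, stringsAsFactors = FALSE,
                            colClasses = "character")
      pid <- pm$patient_id[match(ids, pm$record_id)]
      pid[is.na(pid)] <- ids[is.na(pid)]
    } else {
      pid <- ids
    }
    records <- data.frame(record_id = ids, patient_id = pid,
                          stringsAsFactors = FALSE)
    labels <- NULL
    category <- "beat_level"
  }
  structure(list(name = name, root = root, category = category,
                 records = records, lead = lead, labels = labels),
            class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("ECG dataset '%s' (%s): %d records, %d patients\n",
              x$name, x$category, nrow(x$records),
              length(unique(x$records$patient_id))))
  invisible(x)
}

#' Enumerate patients of a dataset
#'
#' @param handle An `ecg_dataset`.
#' @return Character vector of patient ids in stable (sorted) order.
#' @export
patients <- function(handle) {
  stopifnot(inherits(handle, "ecg_dataset"))
  sort(unique(handle$records$patient_id))
}

#' Enumerate the records of one patient
#'
#' @param handle An `ecg_dataset`.
#' @param patient_id Patient identifier.
#' @return Character vector of record ids in stable order.
#' @export
records_of <- function(handle, patient_id) {
  stopifnot(inherits(handle, "ecg_dataset"))
  if (!patient_id %in% handle$records$patient_id) {
    stop("unknown patient: ", patient_id)
  }
  sort(handle$records$record_id[handle$records$patient_id == patient_id])
}

#' Read one record with its annotations
#'
#' For beat-level datasets the annotation stream is split into beat
#' annotations (one row per heartbeat, anchored at the R-peak sample) and
#' rhythm episodes. Rhythm change-point markers are converted to half-open
#' episodes `[start, end)` (1-based start, exclusive end), the final
#' episode closing at the record end. For recording-level datasets only
#' the recording label is populated.
#'
#' @param handle An `ecg_dataset`.
#' @param record_id Record identifier.
#' @return List with elements `record` (an `ecg_record`), `beats`
#'   (data.frame `sample`, `symbol`), `episodes` (data.frame `start`,
#'   `end`, `symbol`), `rec_label` (character vector of recording-level
#'   symbols, or `NULL`).
#' @export
read_record <- function(handle, record_id) {
  stopifnot(inherits(handle, "ecg_dataset"))
  row <- match(record_id, handle$records$record_id)
  if (is.na(row)) stop("unknown record: ", record_id)
  sig <- wfdb_read_signal(handle$root, record_id, lead = handle$lead)
  rec <- ecg_record(record_id, handle$records$patient_id[row],
                    sig$samples, sig$fs, sig$lead_name)
  beats <- data.frame(sample = integer(0), symbol = character(0),
                      stringsAsFactors = FALSE)
  episodes <- data.frame(start = integer(0), end = integer(0),
                         symbol = character(0), stringsAsFactors = FALSE)
  rec_label <- NULL
  if (handle$category == "beat_level") {
    ann <- wfdb_read_annotations(handle$root, record_id)
    ann <- ann[order(ann$sample), , drop = FALSE]
    if (any(ann$sample < 1 | ann$sample > sig$n_samples)) {
      stop("annotation outside record bounds in record ", record_id)
    }
    is_rhythm <- ann$symbol == "+"
    b <- ann[!is_rhythm, , drop = FALSE]
    if (anyDuplicated(b$sample)) {
      stop("non-increasing beat annotation indices in record ", record_id)
    }
    beats <- data.frame(sample = b$sample, symbol = b$symbol,
                        stringsAsFactors = FALSE)
    r <- ann[is_rhythm, , drop = FALSE]
    if (nrow(r)) {
      sym <- sub("^\\(", "", r$aux)
      episodes <- data.frame(
        start = r$sample,
        end = c(r$sample[-1], sig$n_samples + 1L),
        symbol = sym, stringsAsFactors = FALSE)
      episodes <- episodes[episodes$end > episodes$start, , drop = FALSE]
      rownames(episodes) <- NULL
    }
  } else {
    raw <- handle$labels$labels[match(record_id, handle$labels$record_id)]
    rec_label <- trimws(strsplit(raw, ";", fixed = TRUE)[[1]])
    if (!length(rec_label)) stop("record ", record_id, " has an empty label")
  }
  list(record = rec, beats = beats, episodes = episodes, rec_label = rec_label)
}
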