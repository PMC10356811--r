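# Input-generation techniques and their label-assignment semantics:
# heartbeat windows centred on the R-peak, rhythm-episode spans, sliding
# windows with voting rules, whole-sequence inputs, and window-to-recording
# prediction aggregation.

#' Construct a segment set
#'
#' The common container for labelled ECG segments. Signals may have
#' different lengths (episode segmentation); all windowed transforms
#' produce uniform lengths.
#'
#' @param signals List of numeric vectors.
#' @param label Integer class labels in `1..C`.
#' @param record_id,patient_id,start Per-segment provenance (start is the
#'   1-based sample index of the segment in its source record).
#' @param fs Source sampling frequency shared by all segments.
#' @param transform_tag Transform notation tag (e.g. `"windows2.5s"`).
#' @param class_names Character vector naming the task classes.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(signals, label, record_id, patient_id, start, fs,
                        transform_tag, class_names) {
  n <- length(signals)
  stopifnot(length(label) == n, length(record_id) == n,
            length(patient_id) == n, length(start) == n)
  if (n && (anyNA(label) || any(label < 1 | label > length(class_names)))) {
    stop("segment labels must lie in 1..C")
  }
  structure(list(
    signals = signals,
    meta = data.frame(record_id = as.character(record_id),
                      patient_id = as.character(patient_id),
                      start = as.integer(start),
                      label = as.integer(label),
                      stringsAsFactors = FALSE),
    fs = fs, transform_tag = transform_tag, class_names = class_names),
    class = "segment_set")
}

#' @export
length.segment_set <- function(x) length(x$signals)

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set: %d segments (%s @ %g Hz), %d patients\n",
              length(x), x$transform_tag, x$fs,
              length(unique(x$meta$patient_id))))
  if (length(x)) {
    tab <- table(factor(x$meta$label, levels = seq_along(x$class_names),
                        labels = x$class_names))
    print(tab)
  }
  invisible(x)
}

#' @export
`[.segment_set` <- function(x, i) {
  idx <- seq_len(length(x))[i]
  segment_set(x$signals[idx], x$meta$label[idx], x$meta$record_id[idx],
              x$meta$patient_id[idx], x$meta$start[idx], x$fs,
              x$transform_tag, x$class_names)
}

#' Concatenate segment sets
#'
#' @param ... `segment_set` objects with identical `fs`, transform tag and
#'   class names.
#' @return A combined `segment_set`.
#' @export
bind_segments <- function(...) {
  sets <- Filter(Negate(is.null), list(...))
  if (!length(sets)) stop("nothing to bind")
  ref <- sets[[1]]
  for (s in sets[-1]) {
    stopifnot(identical(s$fs, ref$fs),
              identical(s$class_names, ref$class_names))
  }
  segment_set(
    do.call(c, lapply(sets, `[[`, "signals")),
    do.call(c, lapply(sets, function(s) s$meta$label)),
    do.call(c, lapply(sets, function(s) s$meta$record_id)),
    do.call(c, lapply(sets, function(s) s$meta$patient_id)),
    do.call(c, lapply(sets, function(s) s$meta$start)),
    ref$fs, ref$transform_tag, ref$class_names)
}

#' Export a segment table
#'
#' @param segs A `segment_set`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(segs, path) {
  stopifnot(inherits(segs, "segment_set"))
  df <- segs$meta
  df$transform <- segs$transform_tag
  df$label <- segs$class_names[df$label]
  utils::write.csv(df[, c("record_id", "patient_id", "start", "transform",
                          "label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.empty_segments <- function(fs, tag, class_names) {
  segment_set(list(), integer(0), character(0), character(0), integer(0),
              fs, tag, class_names)
}

# index of the "normal" class of a form task (the class containing code N);
# falls back to class 1
.normal_class <- function(task) {
  for (i in seq_along(task$classes)) if ("N" %in% task$classes[[i]]) return(i)
  1L
}

#' Heartbeat segmentation
#'
#' One candidate window per annotated beat, of `w = round(duration_s *
#' fs)` samples, floor-centred on the R-peak (`start = r - w %/% 2`).
#' Windows that would cross either record boundary are dropped rather
#' than padded (padding would fabricate signal inside a beat-morphology
#' window). Each kept window is labelled by its own beat's resolved task
#' class; beats whose symbol is unknown or excluded from the task are
#' dropped.
#'
#' @param record An `ecg_record`.
#' @param beats data.frame with columns `sample`, `symbol`.
#' @param duration_s Window duration in seconds (0.72 for single-beat
#'   windows, 2.4 to cover the two neighbouring beats).
#' @param dict An `ecg_label_dict`.
#' @param task An `ecg_task`.
#' @param dataset Dataset name for dictionary lookups.
#' @return A `segment_set` (tag `beats<duration>s`).
#' @export
segment_beats <- function(record, beats, duration_s, dict, task,
                          dataset = "synth") {
  stopifnot(inherits(record, "ecg_record"))
  if (duration_s <= 0) stop("duration_s must be positive")
  tag <- paste0("beats", format(duration_s), "s")
  if (!nrow(beats)) return(.empty_segments(record$fs, tag, task$class_names))
  w <- round(duration_s * record$fs)
  L <- length(record$samples)
  start <- beats$sample - w %/% 2
  ok <- start >= 1 & start + w - 1 <= L
  lab <- resolve_class(task, map_symbol(dict, dataset, beats$symbol, "beat"))
  keep <- ok & !is.na(lab)
  idx <- which(keep)
  segment_set(
    lapply(idx, function(i) record$samples[start[i]:(start[i] + w - 1)]),
    lab[idx], rep(record$record_id, length(idx)),
    rep(record$patient_id, length(idx)), start[idx],
    record$fs, tag, task$class_names)
}

#' Rhythm-episode segmentation
#'
#' One variable-length segment per annotated rhythm episode, labelled
#' from the episode symbol. Provided for completeness; episode spans leak
#' duration information about the class and require known rhythm-change
#' locations, so the windowed transforms are preferred for evaluation.
#'
#' @param record An `ecg_record`.
#' @param episodes data.frame with columns `start`, `end` (half-open,
#'   1-based start), `symbol`.
#' @inheritParams segment_beats
#' @return A `segment_set` (tag `episodes`).
#' @export
segment_episodes <- function(record, episodes, dict, task,
                             dataset = "synth") {
  stopifnot(inherits(record, "ecg_record"))
  if (!nrow(episodes)) {
    return(.empty_segments(record$fs, "episodes", task$class_names))
  }
  episodes <- episodes[order(episodes$start), , drop = FALSE]
  if (any(episodes$end[-nrow(episodes)] > episodes$start[-1])) {
    stop("overlapping rhythm episodes in record ", record$record_id)
  }
  lab <- resolve_class(task, map_symbol(dict, dataset, episodes$symbol,
                                        "rhythm"))
  idx <- which(!is.na(lab))
  segment_set(
    lapply(idx, function(i) {
      record$samples[episodes$start[i]:(episodes$end[i] - 1)]
    }),
    lab[idx], rep(record$record_id, length(idx)),
    rep(record$patient_id, length(idx)), episodes$start[idx],
    record$fs, "episodes", task$class_names)
}

#' Label one window span
#'
#' Implements the window label-assignment rules. For rhythm tasks the
#' window takes the class whose episodes cover the largest portion of the
#' span (coverage voting); an exact coverage tie goes to the class of the
#' earlier-starting episode. For form tasks an abnormal-priority rule
#' applies: if at least one in-span beat resolves to an abnormal class
#' (any class other than the task's normal class), the window takes that
#' abnormal class — when several distinct abnormal classes are present,
#' the globally rarer one (per `class_counts`) wins, ties and missing
#' counts resolved toward the higher class index. Windows with no
#' resolvable beats (form) or no episode coverage (rhythm) are excluded
#' (`NA`).
#'
#' @param span Integer vector `c(start, end)`: half-open window span,
#'   1-based start, exclusive end.
#' @param beats,episodes Record annotations (see [read_record()]).
#' @param dict,task,dataset As in [segment_beats()].
#' @param class_counts Optional numeric vector of global per-class
#'   segment/beat counts used by the form-task abnormal tie-break.
#' @return Class index in `1..C`, or `NA` (excluded).
#' @export
label_window <- function(span, beats, episodes, dict, task,
                         dataset = "synth", class_counts = NULL) {
  C <- task$n_classes
  if (task$kind == "rhythm") {
    if (!nrow(episodes)) return(NA_integer_)
    lab <- resolve_class(task, map_symbol(dict, dataset, episodes$symbol,
                                          "rhythm"))
    cov <- numeric(C)
    first_start <- rep(Inf, C)
    for (i in seq_len(nrow(episodes))) {
      if (is.na(lab[i])) next
      ov <- min(span[2], episodes$end[i]) - max(span[1], episodes$start[i])
      if (ov > 0) {
        cov[lab[i]] <- cov[lab[i]] + ov
        first_start[lab[i]] <- min(first_start[lab[i]], episodes$start[i])
      }
    }
    if (all(cov == 0)) return(NA_integer_)
    best <- which(cov == max(cov))
    if (length(best) > 1) best <- best[which.min(first_start[best])]
    return(as.integer(best))
  }
  # form task: abnormal-priority over in-span beats
  if (!nrow(beats)) return(NA_integer_)
  inspan <- beats$sample >= span[1] & beats$sample < span[2]
  lab <- resolve_class(task, map_symbol(dict, dataset, beats$symbol[inspan],
                                        "beat"))
  lab <- lab[!is.na(lab)]
  if (!length(lab)) return(NA_integer_)
  normal <- .normal_class(task)
  abnormal <- setdiff(unique(lab), normal)
  if (!length(abnormal)) return(as.integer(normal))
  if (length(abnormal) == 1) return(as.integer(abnormal))
  if (is.null(class_counts)) return(as.integer(max(abnormal)))
  cnt <- class_counts[abnormal]
  pick <- abnormal[cnt == min(cnt)]
  as.integer(max(pick))
}

.window_grid <- function(L, w, s) {
  if (w < 1) stop("window rounds to zero samples")
  if (s < 1) stop("window stride rounds to zero samples")
  if (L < w) return(integer(0))
  as.integer(1L + s * (0:((L - w) %/% s)))
}

#' Sliding-window segmentation of a beat-level record
#'
#' Splits the signal into windows of `round(window_s * fs)` samples at
#' stride `round(w * (1 - overlap))`, disregarding heartbeat locations,
#' and labels each window with [label_window()]. Excluded windows are
#' dropped. For `L >= w` the number of candidate windows is
#' `floor((L - w) / s) + 1`.
#'
#' @param record An `ecg_record`.
#' @param beats,episodes Record annotations.
#' @param window_s Window duration in seconds.
#' @param overlap Overlap fraction in `[0, 1)` (0.5 is the usual choice
#'   for inter-patient evaluation, 0 for intra-patient to avoid label
#'   leakage between overlapping windows).
#' @param dict,task,dataset As in [segment_beats()].
#' @param class_counts Optional global class counts for the form
#'   tie-break; when `NULL` and the task is a form task, counts are taken
#'   over this record's resolved beats.
#' @return A `segment_set` (tag `windows<duration>s`).
#' @export
segment_sliding <- function(record, beats, episodes, window_s,
                            overlap = 0.5, dict, task, dataset = "synth",
                            class_counts = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  w <- round(window_s * record$fs)
  s <- round(w * (1 - overlap))
  tag <- paste0("windows", format(window_s), "s")
  if (is.null(class_counts) && task$kind == "form" && nrow(beats)) {
    lab <- resolve_class(task, map_symbol(dict, dataset, beats$symbol, "beat"))
    class_counts <- tabulate(lab[!is.na(lab)], nbins = task$n_classes)
  }
  starts <- .window_grid(length(record$samples), w, s)
  if (!length(starts)) return(.empty_segments(record$fs, tag, task$class_names))
  lab <- vapply(starts, function(st) {
    label_window(c(st, st + w), beats, episodes, dict, task, dataset,
                 class_counts)
  }, integer(1))
  idx <- which(!is.na(lab))
  segment_set(
    lapply(idx, function(i) record$samples[starts[i]:(starts[i] + w - 1)]),
    lab[idx], rep(record$record_id, length(idx)),
    rep(record$patient_id, length(idx)), starts[idx],
    record$fs, tag, task$class_names)
}

# resolve a recording-level label list to a task class (first label used;
# extra labels reported); returns NA when unresolvable
.resolve_recording_label <- function(rec_label, dict, task, dataset,
                                     record_id = "?") {
  if (length(rec_label) > 1) {
    message("record ", record_id, ": using first of ",
            length(rec_label), " labels")
  }
  code <- map_symbol(dict, dataset, rec_label[1], "rhythm")
  if (is.na(code)) code <- map_symbol(dict, dataset, rec_label[1], "beat")
  resolve_class(task, code)
}

#' Sliding-window segmentation of a recording-level record
#'
#' Same windowing arithmetic as [segment_sliding()]; every window
#' inherits the resolved recording label. Records whose label does not
#' resolve into the task are skipped with a warning.
#'
#' @inheritParams segment_sliding
#' @param rec_label Character vector of recording-level symbols.
#' @return A `segment_set`.
#' @export
segment_recording_windows <- function(record, rec_label, window_s,
                                      overlap = 0.5, dict, task,
                                      dataset = "synthrec") {
  stopifnot(inherits(record, "ecg_record"))
  w <- round(window_s * record$fs)
  s <- round(w * (1 - overlap))
  tag <- paste0("windows", format(window_s), "s")
  lab <- .resolve_recording_label(rec_label, dict, task, dataset,
                                  record$record_id)
  if (is.na(lab)) {
    warning("record ", record$record_id,
            ": unresolvable recording label, skipped")
    return(.empty_segments(record$fs, tag, task$class_names))
  }
  starts <- .window_grid(length(record$samples), w, s)
  if (!length(starts)) return(.empty_segments(record$fs, tag, task$class_names))
  segment_set(
    lapply(starts, function(st) record$samples[st:(st + w - 1)]),
    rep(lab, length(starts)), rep(record$record_id, length(starts)),
    rep(record$patient_id, length(starts)), starts,
    record$fs, tag, task$class_names)
}

#' Whole-sequence input
#'
#' The full recording as one segment, cropped or zero-padded to
#' `round(duration_s * fs)` samples and labelled with the resolved
#' recording label.
#'
#' @inheritParams segment_recording_windows
#' @param duration_s Target duration in seconds (10 by convention).
#' @return A `segment_set` with zero or one segment (tag
#'   `sequence<duration>s`).
#' @export
whole_sequence <- function(record, rec_label, duration_s = 10, dict, task,
                           dataset = "synthrec") {
  stopifnot(inherits(record, "ecg_record"))
  tag <- paste0("sequence", format(duration_s), "s")
  lab <- .resolve_recording_label(rec_label, dict, task, dataset,
                                  record$record_id)
  if (is.na(lab)) {
    warning("record ", record$record_id,
            ": unresolvable recording label, skipped")
    return(.empty_segments(record$fs, tag, task$class_names))
  }
  n <- round(duration_s * record$fs)
  segment_set(list(fit_length(record$samples, n)), lab, record$record_id,
              record$patient_id, 1L, record$fs, tag, task$class_names)
}

#' Aggregate window predictions to recording predictions
#'
#' Majority vote of the predicted window classes per recording; an exact
#' tie goes to the lowest class index (deterministic).
#'
#' @param record_id Character vector, one entry per window prediction.
#' @param pred Integer vector of predicted class indices.
#' @return Named integer vector: record id -> predicted class.
#' @export
aggregate_predictions <- function(record_id, pred) {
  if (!length(pred)) stop("no predictions to aggregate")
  stopifnot(length(record_id) == length(pred))
  out <- tapply(pred, record_id, function(p) {
    tab <- tabulate(p, nbins = max(p))
    which.max(tab) # which.max takes the first (lowest) index on ties
  })
  stats::setNames(as.integer(out), names(out))
}
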