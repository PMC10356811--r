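#' Unified arrhythmia code vocabulary
#'
#' The closed vocabulary of unified arrhythmia codes used by label
#' dictionaries and task definitions. Beat-form codes describe the
#' morphology of a single heartbeat (e.g. `PVC`, a premature ventricular
#' contraction); rhythm codes describe episodes spanning several beats
#' (e.g. `AFIB`, atrial fibrillation). `NONE` is the in-band value for
#' "no diagnostic label".
#'
#' @return Character vector of valid unified codes.
#' @export
ecg_codes <- function() {
  c(
    # beat-form codes
    "N", "LBBB", "RBBB", "AESC", "NESC",
    "PAC", "PAC_ABERR", "NPC", "SVPB",
    "PVC", "VESC", "FUSION", "PACE", "PFUS", "UNKNOWN",
    # rhythm codes
    "SINUS", "AFIB", "AFL", "STACH", "SBRAD", "SVTA",
    "BIGEMINY", "TRIGEMINY", "VT", "IVR", "NOISE",
    "NONE"
  )
}

.kinds <- c("beat", "rhythm")

#' Construct a label dictionary
#'
#' A label dictionary unifies dataset-specific annotation symbols into
#' common arrhythmia codes, so that e.g. the symbol `AFIB` in one dataset
#' and `AF` in another both resolve to the unified code `AFIB`. The key of
#' each entry is the triple (dataset, raw symbol, kind): the same raw
#' symbol may map to different codes as a beat label and as a rhythm label.
#'
#' @param entries data.frame with columns `dataset`, `raw_symbol`,
#'   `unified_code`, `kind` (`"beat"` or `"rhythm"`).
#' @return An object of class `ecg_label_dict`.
#' @seealso [load_label_dictionary()], [map_symbol()]
#' @export
label_dictionary <- function(entries) {
  required <- c("dataset", "raw_symbol", "unified_code", "kind")
  if (!is.data.frame(entries) || !all(required %in% names(entries))) {
    stop("label dictionary requires columns: ", paste(required, collapse = ", "))
  }
  entries <- entries[, required, drop = FALSE]
  for (col in required) entries[[col]] <- as.character(entries[[col]])
  bad_kind <- !entries$kind %in% .kinds
  if (any(bad_kind)) {
    stop("invalid annotation kind(s): ", paste(unique(entries$kind[bad_kind]), collapse = ", "))
  }
  bad_code <- !entries$unified_code %in% ecg_codes()
  if (any(bad_code)) {
    stop("unified code(s) outside the vocabulary: ",
         paste(unique(entries$unified_code[bad_code]), collapse = ", "))
  }
  key <- paste(entries$dataset, entries$raw_symbol, entries$kind, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- entries[duplicated(key), , drop = FALSE]
    stop("duplicate (dataset, raw_symbol, kind) entries: ",
         paste(unique(paste0(dup$dataset, "/", dup$raw_symbol, "/", dup$kind)),
               collapse = ", "))
  }
  structure(list(entries = entries, index = stats::setNames(entries$unified_code, key)),
            class = "ecg_label_dict")
}

#' Load a label dictionary from CSV
#'
#' The file must have a header row naming the four columns
#' `dataset,raw_symbol,unified_code,kind`.
#'
#' @param path Path to a CSV file.
#' @return An `ecg_label_dict`.
#' @export
load_label_dictionary <- function(path) {
  if (!file.exists(path)) stop("label dictionary file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"", blank.lines.skip = FALSE)
  bad <- which(!is.na(nf) & nf != 4L)
  if (length(bad)) {
    stop("malformed label dictionary row (expected 4 fields) at line ", bad[1],
         " of ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("dataset", "raw_symbol", "unified_code", "kind")
  if (!identical(sort(names(df)), sort(required))) {
    stop("label dictionary header must name columns: ", paste(required, collapse = ", "))
  }
  label_dictionary(df)
}

#' Write a label dictionary to CSV
#'
#' @param dict An `ecg_label_dict`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "ecg_label_dict"))
  utils::write.csv(dict$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.ecg_label_dict <- function(x, ...) {
  cat("ECG label dictionary:", nrow(x$entries), "entries,",
      length(unique(x$entries$dataset)), "dataset(s)\n")
  tab <- table(x$entries$dataset, x$entries$kind)
  print(tab)
  invisible(x)
}

#' Look up the unified code of a raw annotation symbol
#'
#' Exact-match lookup over the dictionary; there is no fuzzy matching.
#' Unknown symbols yield `NA` (the in-band NONE value) so the caller can
#' decide to skip or to error.
#'
#' @param dict An `ecg_label_dict`.
#' @param dataset Dataset name the symbol comes from.
#' @param raw_symbol Character vector of raw symbols.
#' @param kind `"beat"` or `"rhythm"`.
#' @return Character vector of unified codes, `NA` where the symbol is
#'   not in the dictionary.
#' @export
map_symbol <- function(dict, dataset, raw_symbol, kind) {
  stopifnot(inherits(dict, "ecg_label_dict"))
  kind <- match.arg(kind, .kinds)
  if (!length(raw_symbol)) return(character(0))
  key <- paste(dataset, raw_symbol, kind, sep = "\r")
  unname(dict$index[key])
}

#' Define an arrhythmia classification task
#'
#' A task groups unified codes into an ordered list of target classes.
#' Class order is fixed and defines the integer class labels `1..C` used
#' throughout the package. An optional catch-all class collects every code
#' not assigned to a named class; codes matching no class resolve to
#' `NA` (excluded).
#'
#' @param name Task name.
#' @param classes Named list: class name -> character vector of member
#'   unified codes. Member sets must be pairwise disjoint.
#' @param kind `"form"` (beat-morphology task, labels come from beat
#'   annotations) or `"rhythm"` (labels come from rhythm episodes or
#'   recording labels).
#' @param other_class Optional name of a catch-all class appended after
#'   the named classes.
#' @return An object of class `ecg_task`.
#' @export
task_definition <- function(name, classes, kind = c("form", "rhythm"),
                            other_class = NULL) {
  kind <- match.arg(kind)
  if (!is.list(classes) || is.null(names(classes)) || any(names(classes) == "")) {
    stop("'classes' must be a named list of unified-code vectors")
  }
  codes <- unlist(classes, use.names = FALSE)
  bad <- !codes %in% ecg_codes()
  if (any(bad)) stop("unknown unified code(s) in task '", name, "': ",
                     paste(unique(codes[bad]), collapse = ", "))
  if (anyDuplicated(codes)) {
    stop("task '", name, "': member code sets must be pairwise disjoint (",
         paste(unique(codes[duplicated(codes)]), collapse = ", "), ")")
  }
  class_names <- names(classes)
  if (!is.null(other_class)) {
    if (other_class %in% class_names) stop("other_class clashes with a named class")
    class_names <- c(class_names, other_class)
  }
  if (length(class_names) < 2) stop("a task needs at least 2 classes")
  structure(list(name = name, classes = classes, kind = kind,
                 other_class = other_class, class_names = class_names,
                 n_classes = length(class_names)),
            class = "ecg_task")
}

#' @export
print.ecg_task <- function(x, ...) {
  cat("ECG task '", x$name, "' (", x$kind, "), ", x$n_classes, " classes:\n", sep = "")
  for (cn in names(x$classes)) {
    cat("  ", cn, ": {", paste(x$classes[[cn]], collapse = ", "), "}\n", sep = "")
  }
  if (!is.null(x$other_class)) cat("  ", x$other_class, ": <all other codes>\n", sep = "")
  invisible(x)
}

#' Resolve a unified code to a task class index
#'
#' Total and deterministic: each code maps to the index of the class whose
#' member set contains it, falls through to the catch-all class when one is
#' defined, and otherwise to `NA` (excluded from the task).
#'
#' @param task An `ecg_task`.
#' @param code Character vector of unified codes (may contain `NA`).
#' @return Integer vector of class indices in `1..C`, `NA` where excluded.
#' @export
resolve_class <- function(task, code) {
  stopifnot(inherits(task, "ecg_task"))
  out <- rep(NA_integer_, length(code))
  for (i in seq_along(task$classes)) {
    out[!is.na(code) & code %in% task$classes[[i]]] <- i
  }
  if (!is.null(task$other_class)) {
    out[is.na(out) & !is.na(code)] <- length(task$classes) + 1L
  }
  out
}

#' Load task definitions from CSV
#'
#' Columns: `task,kind,class,member_codes` with member codes separated by
#' `;`. A row with empty `member_codes` declares that class as the task's
#' catch-all class.
#'
#' @param path CSV path.
#' @return Named list of `ecg_task` objects.
#' @export
load_task_definitions <- function(path) {
  if (!file.exists(path)) stop("task definition file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("task", "kind", "class", "member_codes")
  if (!all(required %in% names(df))) {
    stop("task definition header must name columns: ", paste(required, collapse = ", "))
  }
  tasks <- list()
  for (tname in unique(df$task)) {
    rows <- df[df$task == tname, , drop = FALSE]
    is_other <- !nzchar(trimws(rows$member_codes))
    if (sum(is_other) > 1) stop("task '", tname, "' declares more than one catch-all class")
    classes <- lapply(rows$member_codes[!is_other],
                      function(s) trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
    names(classes) <- rows$class[!is_other]
    tasks[[tname]] <- task_definition(
      tname, classes, kind = rows$kind[1],
      other_class = if (any(is_other)) rows$class[is_other] else NULL)
  }
  tasks
}

#' Built-in label dictionary
#'
#' The dictionary shipped with the package: standard single-character beat
#' symbols and rhythm labels for the common Holter-style beat-level datasets,
#' plus the symbols written by the synthetic generator.
#'
#' @return An `ecg_label_dict`.
#' @export
default_label_dictionary <- function() {
  load_label_dictionary(system.file("extdata", "label_dictionary.csv",
                                    package = "ecgbench", mustWork = TRUE))
}

#' Built-in task definitions
#'
#' Three tasks are shipped:
#' \describe{
#'   \item{form}{AAMI-style beat morphology: N (normal + bundle-branch
#'     block + escape beats), SVEB (supraventricular ectopic), VEB
#'     (ventricular ectopic). Fusion/paced/unknown beats are excluded.}
#'   \item{rhythm}{Six rhythm classes: SINUS, STACH, SBRAD, SVTA, AFIB, AFL.}
#'   \item{rhythm_reduced}{AFIB vs SINUS vs all other rhythms.}
#' }
#'
#' @return Named list of `ecg_task` objects.
#' @export
default_tasks <- function() {
  load_task_definitions(system.file("extdata", "tasks.csv",
                                    package = "ecgbench", mustWork = TRUE))
}
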