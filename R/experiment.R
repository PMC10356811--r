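# Experiment orchestration: dataset x task x transform x model x
# evaluation scheme. An experiment opens the dataset, maps annotations
# through the label dictionary, segments every record, prepares network
# inputs at the architecture's frequency, splits with the requested
# evaluation scheme (asserting the inter-patient property before any
# training), trains with early stopping, predicts the test fold and
# computes metrics per fold.

.transform_seconds <- c(`beats0.72s` = 0.72, `beats2.4s` = 2.4,
                        `windows2.5s` = 2.5, `windows10s` = 10,
                        `sequence10s` = 10)

#' Experiment configuration
#'
#' @param dataset_path Dataset directory (see [open_dataset()]).
#' @param dataset_name Name used for label-dictionary lookups.
#' @param task An `ecg_task` or the name of a built-in task
#'   ([default_tasks()]).
#' @param transform One of `"beats0.72s"`, `"beats2.4s"`,
#'   `"windows2.5s"`, `"windows10s"`, `"sequence10s"`, `"episodes"`.
#' @param architecture Model architecture name (see [model_spec()]).
#' @param eval_scheme `"inter_cv"`, `"intra_cv"`, `"lopo"`, `"holdout"`
#'   or `"predefined"`.
#' @param k Number of folds for the cross-validation schemes.
#' @param lead Lead selected from multi-lead records.
#' @param dict An `ecg_label_dict` (defaults to the built-in dictionary).
#' @param overlap Sliding-window overlap fraction; `NULL` binds it to the
#'   evaluation scheme (0.5 for the inter-patient schemes, 0 for
#'   intra-patient, to avoid label leakage through overlapping windows).
#' @param aggregate_to_recording Aggregate window predictions to one
#'   prediction per recording before computing metrics.
#' @param fold_assignment Predefined fold table (`record_id`, `fold`) for
#'   `eval_scheme = "predefined"`/`"holdout"`.
#' @param train A [train_config()].
#' @param seed Master seed: per-fold model seeds are derived from it.
#' @param out_dir Optional output directory for results tables, confusion
#'   matrices and the run manifest.
#' @param verbose Print per-fold progress.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(dataset_path, dataset_name = basename(dataset_path),
                              task = "rhythm_reduced",
                              transform = "windows2.5s",
                              architecture = "cnn",
                              eval_scheme = c("inter_cv", "intra_cv", "lopo",
                                              "holdout", "predefined"),
                              k = 10, lead = NULL, dict = NULL,
                              overlap = NULL,
                              aggregate_to_recording = FALSE,
                              fold_assignment = NULL,
                              train = train_config(), seed = 0,
                              out_dir = NULL, verbose = FALSE) {
  eval_scheme <- match.arg(eval_scheme)
  if (!transform %in% c(names(.transform_seconds), "episodes")) {
    stop("unknown transform: ", transform)
  }
  if (k < 2 && eval_scheme %in% c("inter_cv", "intra_cv")) stop("k must be >= 2")
  structure(list(dataset_path = dataset_path, dataset_name = dataset_name,
                 task = task, transform = transform,
                 architecture = architecture, eval_scheme = eval_scheme,
                 k = k, lead = lead, dict = dict, overlap = overlap,
                 aggregate_to_recording = aggregate_to_recording,
                 fold_assignment = fold_assignment, train = train,
                 seed = seed, out_dir = out_dir, verbose = verbose),
            class = "experiment_config")
}

.resolve_task <- function(task) {
  if (inherits(task, "ecg_task")) return(task)
  tasks <- default_tasks()
  if (!task %in% names(tasks)) stop("unknown task: ", task)
  tasks[[task]]
}

# segment every record of a dataset with the configured transform
.segment_dataset <- function(handle, transform, overlap, dict, task) {
  secs <- .transform_seconds[transform]
  out <- NULL
  if (handle$category == "beat_level") {
    if (transform %in% c("sequence10s")) {
      stop("transform '", transform, "' requires a recording-level dataset")
    }
    # global beat class counts drive the form-task abnormal tie-break
    class_counts <- NULL
    if (task$kind == "form" && startsWith(transform, "windows")) {
      counts <- numeric(task$n_classes)
      for (rid in handle$records$record_id) {
        rr <- read_record(handle, rid)
        lab <- resolve_class(task, map_symbol(dict, handle$name,
                                              rr$beats$symbol, "beat"))
        counts <- counts + tabulate(lab[!is.na(lab)], nbins = task$n_classes)
      }
      class_counts <- counts
    }
    for (rid in handle$records$record_id) {
      rr <- read_record(handle, rid)
      segs <- if (startsWith(transform, "beats")) {
        segment_beats(rr$record, rr$beats, secs, dict, task,
                      dataset = handle$name)
      } else if (transform == "episodes") {
        segment_episodes(rr$record, rr$episodes, dict, task,
                         dataset = handle$name)
      } else {
        segment_sliding(rr$record, rr$beats, rr$episodes, secs,
                        overlap = overlap, dict = dict, task = task,
                        dataset = handle$name, class_counts = class_counts)
      }
      out <- if (is.null(out)) segs else bind_segments(out, segs)
    }
  } else {
    if (startsWith(transform, "beats") || transform == "episodes") {
      stop("transform '", transform, "' requires a beat-level dataset")
    }
    for (rid in handle$records$record_id) {
      rr <- read_record(handle, rid)
      segs <- if (startsWith(transform, "windows")) {
        segment_recording_windows(rr$record, rr$rec_label, secs,
                                  overlap = overlap, dict = dict,
                                  task = task, dataset = handle$name)
      } else {
        whole_sequence(rr$record, rr$rec_label, secs, dict, task,
                       dataset = handle$name)
      }
      out <- if (is.null(out)) segs else bind_segments(out, segs)
    }
  }
  if (is.null(out) || !length(out)) stop("segmentation produced no segments")
  out
}

.make_splits <- function(cfg, segs) {
  switch(cfg$eval_scheme,
    inter_cv = inter_patient_cv(segs, k = cfg$k),
    intra_cv = intra_patient_cv(segs, k = cfg$k, seed = cfg$seed),
    lopo = leave_one_patient_out(segs),
    holdout = ,
    predefined = {
      if (is.null(cfg$fold_assignment)) {
        stop("eval_scheme '", cfg$eval_scheme,
             "' requires a fold_assignment table")
      }
      predefined_folds(segs, cfg$fold_assignment, seed = cfg$seed)
    })
}

#' Run a configured experiment
#'
#' Executes the full pipeline and returns a results table with one row
#' per fold (macro F1 and per-class F1), the per-fold `metrics_report`s
#' as attribute `"reports"` and the trained-fold histories as attribute
#' `"histories"`. For inter-patient schemes the patient-disjointness of
#' every split is asserted before any training starts. The test fold is
#' used for metrics exclusively; early stopping monitors the validation
#' fold.
#'
#' @param cfg An [experiment_config()].
#' @return Results data.frame (see [summarize_metrics()]).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dict <- if (is.null(cfg$dict)) default_label_dictionary() else cfg$dict
  task <- .resolve_task(cfg$task)
  handle <- open_dataset(cfg$dataset_path, name = cfg$dataset_name,
                         lead = cfg$lead)
  overlap <- cfg$overlap
  if (is.null(overlap)) {
    overlap <- if (cfg$eval_scheme %in% c("inter_cv", "lopo", "holdout",
                                          "predefined")) 0.5 else 0
  }
  segs <- .segment_dataset(handle, cfg$transform, overlap, dict, task)
  arch <- cfg$architecture
  secs <- if (cfg$transform == "episodes") NA else
    unname(.transform_seconds[cfg$transform])
  input_fs <- if (arch == "dummy_mv") segs$fs else unname(.default_fs[arch])
  input_len <- max(1L, round(secs * input_fs))
  prep <- prepare_inputs(segs, input_fs, input_len)
  splits <- .make_splits(cfg, segs)
  if (cfg$eval_scheme %in% c("inter_cv", "lopo")) {
    for (sp in splits) {
      ok <- verify_inter_patient(sp, segs)
      if (!ok) {
        stop("inter-patient violation before training: patient(s) ",
             paste(attr(ok, "violations"), collapse = ", "),
             " straddle train/val/test")
      }
    }
  }
  reports <- list()
  histories <- list()
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    if (arch == "dummy_mv") {
      model <- dummy_majority(prep$y[sp$train], task$n_classes)
    } else {
      spec <- model_spec(arch, n_classes = task$n_classes,
                         input_len = input_len, seed = cfg$seed + i)
      model <- build_model(spec)
      model <- train_model(model,
                           prep$x[sp$train, , drop = FALSE], prep$y[sp$train],
                           prep$x[sp$val, , drop = FALSE], prep$y[sp$val],
                           cfg$train)
      histories[[i]] <- model$history
    }
    pr <- predict(model, prep$x[sp$test, , drop = FALSE])
    truth <- prep$y[sp$test]
    pred <- pr$label
    if (cfg$aggregate_to_recording) {
      rid <- prep$meta$record_id[sp$test]
      agg_pred <- aggregate_predictions(rid, pred)
      agg_truth <- vapply(split(truth, rid), function(v) v[1], integer(1))
      agg_truth <- agg_truth[names(agg_pred)]
      truth <- unname(agg_truth)
      pred <- unname(agg_pred)
    }
    reports[[i]] <- compute_metrics(truth, pred, task$n_classes, fold = i)
    if (cfg$verbose) {
      message(sprintf("fold %d/%d: macro F1 = %.4f", i, length(splits),
                      reports[[i]]$macro_f1))
    }
  }
  results <- summarize_metrics(reports)
  attr(results, "reports") <- reports
  attr(results, "histories") <- histories
  attr(results, "config") <- cfg
  if (!is.null(cfg$out_dir)) .write_artifacts(cfg, results, reports)
  results
}

.write_artifacts <- function(cfg, results, reports) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(results),
                   file.path(cfg$out_dir, "results_table.csv"),
                   row.names = FALSE)
  for (r in reports) {
    utils::write.csv(r$confusion,
                     file.path(cfg$out_dir,
                               sprintf("confusion_fold%d.csv", r$fold)))
  }
  manifest <- cfg[setdiff(names(cfg), c("dict", "train"))]
  manifest$train <- unclass(cfg$train)
  manifest$mean_macro_f1 <- attr(results, "mean_macro_f1")
  manifest$sd_macro_f1 <- attr(results, "sd_macro_f1")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(NULL)
}

#' Load an experiment configuration from YAML
#'
#' Keys are the arguments of [experiment_config()]; `train` may be a
#' nested mapping of [train_config()] arguments.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$train)) y$train <- do.call(train_config, y$train)
  do.call(experiment_config, y)
}

#' Class distribution of a dataset under a task
#'
#' Counts distinct annotated occurrences per task class: beats for form
#' tasks, rhythm episodes for rhythm tasks on beat-level datasets, and
#' recordings for recording-level datasets.
#'
#' @param handle An `ecg_dataset`.
#' @param dict An `ecg_label_dict`.
#' @param task An `ecg_task` or built-in task name.
#' @return data.frame with columns `class`, `count`.
#' @export
class_distribution_report <- function(handle, dict = default_label_dictionary(),
                                      task = "rhythm_reduced") {
  task <- .resolve_task(task)
  counts <- numeric(task$n_classes)
  for (rid in handle$records$record_id) {
    rr <- read_record(handle, rid)
    lab <- if (handle$category == "recording_level") {
      .resolve_recording_label(rr$rec_label, dict, task, handle$name, rid)
    } else if (task$kind == "form") {
      resolve_class(task, map_symbol(dict, handle$name, rr$beats$symbol,
                                     "beat"))
    } else {
      resolve_class(task, map_symbol(dict, handle$name, rr$episodes$symbol,
                                     "rhythm"))
    }
    counts <- counts + tabulate(lab[!is.na(lab)], nbins = task$n_classes)
  }
  data.frame(class = task$class_names, count = as.integer(counts))
}

#' Bar chart of a class distribution
#'
#' @param report Output of [class_distribution_report()].
#' @param ... Passed to [graphics::barplot()].
#' @return The report, invisibly.
#' @export
plot_class_distribution <- function(report, ...) {
  graphics::barplot(report$count, names.arg = report$class,
                    ylab = "annotated occurrences", ...)
  invisible(report)
}
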