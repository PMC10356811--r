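# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive results by literal rule application or
# exhaustive enumeration, sharing no code with the package internals.

# literal application of the window-labelling rules: coverage voting for
# rhythm tasks, abnormal-priority for form tasks
oracle_label_window <- function(span, beats, episodes, dict, task,
                                dataset, class_counts = NULL) {
  if (task$kind == "rhythm") {
    cov <- rep(0, task$n_classes)
    first <- rep(Inf, task$n_classes)
    if (nrow(episodes)) for (i in seq_len(nrow(episodes))) {
      code <- map_symbol(dict, dataset, episodes$symbol[i], "rhythm")
      cls <- resolve_class(task, code)
      if (is.na(cls)) next
      lo <- max(span[1], episodes$start[i])
      hi <- min(span[2], episodes$end[i])
      if (hi > lo) {
        cov[cls] <- cov[cls] + (hi - lo)
        first[cls] <- min(first[cls], episodes$start[i])
      }
    }
    if (sum(cov) == 0) return(NA_integer_)
    cand <- which(cov == max(cov))
    if (length(cand) > 1) cand <- cand[order(first[cand])][1]
    return(as.integer(cand))
  }
  labs <- integer(0)
  if (nrow(beats)) for (i in seq_len(nrow(beats))) {
    if (beats$sample[i] >= span[1] && beats$sample[i] < span[2]) {
      cls <- resolve_class(task, map_symbol(dict, dataset, beats$symbol[i],
                                            "beat"))
      if (!is.na(cls)) labs <- c(labs, cls)
    }
  }
  if (!length(labs)) return(NA_integer_)
  normal <- NA_integer_
  for (i in seq_along(task$classes)) {
    if ("N" %in% task$classes[[i]]) normal <- i
  }
  if (is.na(normal)) normal <- 1L
  abn <- sort(unique(labs[labs != normal]))
  if (!length(abn)) return(as.integer(normal))
  if (length(abn) == 1) return(abn)
  if (is.null(class_counts)) return(max(abn))
  rare <- abn[class_counts[abn] == min(class_counts[abn])]
  max(rare)
}

# loop-based per-class metrics, following the stated conventions literally
oracle_metrics <- function(truth, pred, C) {
  f1 <- numeric(C)
  present <- logical(C)
  for (c in seq_len(C)) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    present[c] <- (tp + fp + fn) > 0
  }
  list(f1 = f1, macro_f1 = if (any(present)) mean(f1[present]) else NA_real_)
}

# stratification objective, recomputed independently (population sd)
oracle_objective <- function(fold_counts) {
  sds <- apply(fold_counts, 2, function(x) sqrt(mean((x - mean(x))^2)))
  mean(sds)
}

# exhaustive best objective over all assignments of groups to k folds
oracle_best_partition <- function(counts, k, equal_fold_sizes = FALSE) {
  G <- nrow(counts)
  best <- Inf
  assign_next <- function(assignment, g) {
    if (g > G) {
      if (equal_fold_sizes &&
          length(unique(tabulate(assignment, k))) != 1) return()
      fc <- matrix(0, k, ncol(counts))
      for (i in seq_len(G)) fc[assignment[i], ] <- fc[assignment[i], ] + counts[i, ]
      j <- oracle_objective(fc)
      if (j < best) best <<- j
      return()
    }
    for (f in seq_len(k)) assign_next(c(assignment, f), g + 1)
  }
  assign_next(integer(0), 1)
  best
}

# objective of a uniformly random group-preserving k-partition
random_partition_objective <- function(counts, k) {
  a <- sample.int(k, nrow(counts), replace = TRUE)
  fc <- matrix(0, k, ncol(counts))
  for (i in seq_len(nrow(counts))) fc[a[i], ] <- fc[a[i], ] + counts[i, ]
  oracle_objective(fc)
}

# random annotation stream over a zero signal; exercises unknown symbols too
random_annotation_stream <- function(fs = 100, min_s = 20, max_s = 60) {
  L <- round(stats::runif(1, min_s, max_s) * fs)
  n_beats <- rpois(1, L / fs)
  beats <- data.frame(
    sample = sort(sample.int(L, min(n_beats, L))),
    symbol = sample(c("N", "V", "A", "x"), min(n_beats, L), replace = TRUE,
                    prob = c(0.6, 0.15, 0.15, 0.1)),
    stringsAsFactors = FALSE)
  n_ep <- sample(0:4, 1)
  episodes <- data.frame(start = integer(0), end = integer(0),
                         symbol = character(0), stringsAsFactors = FALSE)
  if (n_ep > 0) {
    cuts <- sort(sample.int(L - 1, n_ep))
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L) + 1L
    episodes <- data.frame(
      start = starts, end = ends,
      symbol = sample(c("N", "AFIB", "ST", "SBR"), n_ep + 1, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  list(record = ecg_record("rnd", "prnd", numeric(L), fs), beats = beats,
       episodes = episodes)
}

# small separable beat dataset for the learning smoke tests
separable_beat_data <- function(per_class = 250, seed = 11, fs_out = 360,
                                duration_s = 0.72) {
  d <- default_label_dictionary()
  task <- default_tasks()$form
  set.seed(seed)
  segs <- NULL
  while (is.null(segs) || min(tabulate(segs$meta$label, 3)) < per_class) {
    plan <- rhythm_plan(rhythm_episode_spec("SINUS", 60))
    g <- generate_record(plan, pvc_rate = 0.3, pac_rate = 0.3, fs = 250,
                         noise_sd = 0.02,
                         record_id = paste0("r", length(segs)),
                         patient_id = "p1")
    sb <- segment_beats(g$record, g$beats, duration_s, d, task,
                        dataset = "synth")
    segs <- if (is.null(segs)) sb else bind_segments(segs, sb)
  }
  idx <- unlist(lapply(1:3, function(c) {
    which(segs$meta$label == c)[seq_len(per_class)]
  }))
  prepare_inputs(segs[idx], fs_out, round(duration_s * fs_out))
}
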