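# Evaluation schemes. The central one is inter-patient cross-validation:
# all segments of a patient form one indivisible group, and the groups are
# split into k folds kept as class-stratified as a greedy heuristic
# allows. Intra-patient CV, leave-one-patient-out, holdout and predefined
# folds are also provided.

.popsd <- function(x) sqrt(mean((x - mean(x))^2))

# mean (over classes) of the across-fold standard deviation of per-class
# counts: the stratification objective minimized by the greedy heuristic
.stratification_objective <- function(fold_counts) {
  mean(apply(fold_counts, 2, .popsd))
}

#' Stratified group k-fold assignment
#'
#' Greedy heuristic: groups (patients) are visited in order of decreasing
#' total segment count (ties by id) and each group is assigned to the
#' fold that minimizes the stratification objective — the mean over
#' classes of the across-fold standard deviation of per-class sample
#' counts — evaluated after the tentative placement. The heuristic can
#' produce suboptimal splits; [verify_inter_patient()] guards the
#' patient-disjointness property downstream and the objective value is
#' reported for inspection.
#'
#' @param group_class_counts Numeric matrix: one row per group (rownames
#'   are the group/patient ids), one column per class, entries the number
#'   of segments of that class in the group.
#' @param k Number of folds (`2 <= k <=` number of groups).
#' @param order_rule `"size"` (default: descending total count) or
#'   `"given"` (row order as supplied).
#' @return An object of class `fold_split`: list with `k`, `folds` (list
#'   of character vectors of group ids), `per_fold_class_counts` (k x C
#'   matrix) and `objective` (final J).
#' @export
stratified_group_kfold <- function(group_class_counts, k,
                                   order_rule = c("size", "given")) {
  order_rule <- match.arg(order_rule)
  m <- as.matrix(group_class_counts)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (any(m < 0)) stop("group class counts must be non-negative")
  if (any(rowSums(m) == 0)) stop("every group must contain at least one segment")
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(m)) stop("k (", k, ") exceeds the number of groups (", nrow(m), ")")
  ord <- if (order_rule == "size") {
    order(-rowSums(m), rownames(m))
  } else {
    seq_len(nrow(m))
  }
  C <- ncol(m)
  fold_counts <- matrix(0, k, C)
  assignment <- integer(nrow(m))
  for (g in ord) {
    j_best <- Inf
    f_best <- 1L
    for (f in seq_len(k)) {
      tentative <- fold_counts
      tentative[f, ] <- tentative[f, ] + m[g, ]
      j <- .stratification_objective(tentative)
      if (j < j_best - 1e-12) {
        j_best <- j
        f_best <- f
      }
    }
    assignment[g] <- f_best
    fold_counts[f_best, ] <- fold_counts[f_best, ] + m[g, ]
  }
  folds <- lapply(seq_len(k), function(f) rownames(m)[assignment == f])
  colnames(fold_counts) <- colnames(m)
  structure(list(k = k, folds = folds,
                 per_fold_class_counts = fold_counts,
                 objective = .stratification_objective(fold_counts)),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("fold_split: k = %d, objective J = %.4f\n", x$k, x$objective))
  sizes <- vapply(x$folds, length, integer(1))
  cat("groups per fold:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

# accept a segment_set or a meta data.frame with patient_id + label
.seg_meta <- function(segments) {
  if (inherits(segments, "segment_set")) return(segments$meta)
  stopifnot(is.data.frame(segments),
            all(c("patient_id", "label") %in% names(segments)))
  segments
}

.n_task_classes <- function(segments, meta) {
  if (inherits(segments, "segment_set")) length(segments$class_names)
  else max(meta$label)
}

.tvt <- function(train, val, test, fold, scheme) {
  structure(list(train = train, val = val, test = test, fold = fold,
                 scheme = scheme),
            class = "train_val_test")
}

#' Inter-patient k-fold cross-validation splits
#'
#' Patients are grouped into k stratified folds with
#' [stratified_group_kfold()] over per-patient class counts. For split i,
#' fold i is the test set, fold `(i mod k) + 1` the validation set (for
#' early stopping) and the remaining folds the training set, so every
#' patient appears in exactly one test fold and every fold serves as
#' validation exactly once. No patient's segments ever straddle
#' train/val/test.
#'
#' @param segments A `segment_set` (or meta data.frame with `patient_id`
#'   and `label`).
#' @param k Number of folds (default 10).
#' @return List of k `train_val_test` objects holding segment indices;
#'   the `fold_split` used is attached as attribute `"fold_split"`.
#' @export
inter_patient_cv <- function(segments, k = 10) {
  meta <- .seg_meta(segments)
  C <- .n_task_classes(segments, meta)
  pats <- sort(unique(meta$patient_id))
  if (length(pats) < k) {
    stop("fewer patients (", length(pats), ") than folds (", k,
         "); consider the leave-one-patient-out evaluation scheme instead")
  }
  counts <- matrix(0, length(pats), C, dimnames = list(pats, NULL))
  tab <- table(meta$patient_id, factor(meta$label, levels = seq_len(C)))
  counts[rownames(tab), ] <- tab
  fs <- stratified_group_kfold(counts, k)
  splits <- lapply(seq_len(k), function(i) {
    test_p <- fs$folds[[i]]
    val_p <- fs$folds[[i %% k + 1]]
    train_p <- setdiff(pats, c(test_p, val_p))
    .tvt(which(meta$patient_id %in% train_p),
         which(meta$patient_id %in% val_p),
         which(meta$patient_id %in% test_p),
         i, "inter_cv")
  })
  attr(splits, "fold_split") <- fs
  splits
}

#' Intra-patient (patient-blind) stratified k-fold splits
#'
#' Segments are split into k class-stratified folds at random,
#' disregarding which patient they originate from — the conventional but
#' optimistic scheme, included for comparison with the inter-patient
#' schemes.
#'
#' @inheritParams inter_patient_cv
#' @param seed RNG seed for the shuffle.
#' @return List of k `train_val_test` objects.
#' @export
intra_patient_cv <- function(segments, k = 10, seed = 0) {
  meta <- .seg_meta(segments)
  C <- .n_task_classes(segments, meta)
  cls_counts <- tabulate(meta$label, nbins = C)
  short <- which(cls_counts > 0 & cls_counts < k)
  if (length(short)) {
    stop("class ", paste(short, collapse = ", "),
         " has fewer segments than folds (k = ", k, ")")
  }
  set.seed(seed)
  fold_of <- integer(nrow(meta))
  offset <- 0L # rotate the round-robin start so fold sizes stay balanced
  for (c in which(cls_counts > 0)) {
    idx <- sample(which(meta$label == c))
    fold_of[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
    offset <- (offset + length(idx)) %% k
  }
  lapply(seq_len(k), function(i) {
    v <- i %% k + 1
    .tvt(which(!fold_of %in% c(i, v)), which(fold_of == v),
         which(fold_of == i), i, "intra_cv")
  })
}

#' Leave-one-patient-out splits
#'
#' One split per patient: that patient's segments are the test set, one
#' other patient (round-robin) the validation set, the rest the training
#' set.
#'
#' @inheritParams inter_patient_cv
#' @return List of `train_val_test` objects, one per patient.
#' @export
leave_one_patient_out <- function(segments) {
  meta <- .seg_meta(segments)
  pats <- sort(unique(meta$patient_id))
  P <- length(pats)
  if (P < 3) stop("leave-one-patient-out needs at least 3 patients")
  lapply(seq_len(P), function(i) {
    test_p <- pats[i]
    val_p <- pats[i %% P + 1]
    .tvt(which(!meta$patient_id %in% c(test_p, val_p)),
         which(meta$patient_id == val_p),
         which(meta$patient_id == test_p),
         i, "lopo")
  })
}

#' Splits from a predefined fold assignment
#'
#' Honours dataset-provided folds exactly (no re-stratification). A
#' 2-valued assignment is treated as a holdout: one train/test split with
#' the validation set carved out of the training patients (about 10% of
#' them, patient-stratified, seeded).
#'
#' @inheritParams inter_patient_cv
#' @param assignment data.frame with columns `record_id`, `fold` (or a
#'   named vector record_id -> fold id). Every record in `segments` must
#'   be assigned exactly once.
#' @param seed RNG seed for the holdout validation carve-out.
#' @return List of `train_val_test` objects (one per fold; a single
#'   split for a 2-valued holdout assignment).
#' @export
predefined_folds <- function(segments, assignment, seed = 0) {
  meta <- .seg_meta(segments)
  if (is.data.frame(assignment)) {
    stopifnot(all(c("record_id", "fold") %in% names(assignment)))
    if (anyDuplicated(assignment$record_id)) {
      dup <- assignment$record_id[duplicated(assignment$record_id)]
      stop("contradictory duplicate fold assignment for record(s): ",
           paste(unique(dup), collapse = ", "))
    }
    amap <- stats::setNames(assignment$fold, assignment$record_id)
  } else {
    amap <- assignment
  }
  fold_of <- unname(amap[meta$record_id])
  if (anyNA(fold_of)) {
    stop("unassigned record(s): ",
         paste(unique(meta$record_id[is.na(fold_of)]), collapse = ", "))
  }
  fold_ids <- sort(unique(amap))
  if (length(fold_ids) == 2) {
    # holdout: first fold id = train, second = test
    train_all <- which(fold_of == fold_ids[1])
    test <- which(fold_of == fold_ids[2])
    train_pats <- sort(unique(meta$patient_id[train_all]))
    set.seed(seed)
    n_val <- max(1, round(0.1 * length(train_pats)))
    val_pats <- sample(train_pats, n_val)
    val <- train_all[meta$patient_id[train_all] %in% val_pats]
    train <- setdiff(train_all, val)
    return(list(.tvt(train, val, test, 1L, "holdout")))
  }
  k <- length(fold_ids)
  lapply(seq_len(k), function(i) {
    test_f <- fold_ids[i]
    val_f <- fold_ids[i %% k + 1]
    .tvt(which(!fold_of %in% c(test_f, val_f)),
         which(fold_of == val_f), which(fold_of == test_f),
         i, "predefined")
  })
}

#' Verify the inter-patient property of a split
#'
#' TRUE iff the patient sets behind train, validation and test are
#' pairwise disjoint. The offending patients, if any, are attached as
#' attribute `"violations"`.
#'
#' @param split A `train_val_test` object.
#' @param segments The `segment_set` (or meta data.frame) the indices
#'   refer to.
#' @return Logical scalar with attribute `violations`.
#' @export
verify_inter_patient <- function(split, segments) {
  meta <- .seg_meta(segments)
  p_train <- unique(meta$patient_id[split$train])
  p_val <- unique(meta$patient_id[split$val])
  p_test <- unique(meta$patient_id[split$test])
  bad <- unique(c(intersect(p_train, p_val), intersect(p_train, p_test),
                  intersect(p_val, p_test)))
  structure(length(bad) == 0, violations = bad)
}

#' Export a patient fold assignment
#'
#' @param fold_split A `fold_split`.
#' @param path CSV output path (`patient_id,fold`).
#' @return `path`, invisibly.
#' @export
write_fold_split <- function(fold_split, path) {
  stopifnot(inherits(fold_split, "fold_split"))
  df <- data.frame(
    patient_id = unlist(fold_split$folds),
    fold = rep(seq_along(fold_split$folds),
               vapply(fold_split$folds, length, integer(1))))
  df <- df[order(df$patient_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
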