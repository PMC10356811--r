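random_meta <- function(n_patients, seg_per_patient = 10, C = 3, seed = 1) {
  set.seed(seed)
  data.frame(
    patient_id = rep(sprintf("p%03d", seq_len(n_patients)),
                     each = seg_per_patient),
    record_id = rep(sprintf("p%03dr1", seq_len(n_patients)),
                    each = seg_per_patient),
    label = sample.int(C, n_patients * seg_per_patient, replace = TRUE))
}

test_that("identical groups split perfectly (J = 0)", {
  counts <- matrix(5, nrow = 8, ncol = 2,
                   dimnames = list(sprintf("g%d", 1:8), NULL))
  fs <- stratified_group_kfold(counts, k = 4)
  expect_equal(fs$objective, 0)
  expect_true(all(vapply(fs$folds, length, integer(1)) == 2L))
})

test_that("greedy split reaches the exhaustive optimum on the 6-group instance", {
  counts <- matrix(c(10, 0, 10, 0, 0, 10, 0, 10, 5, 5, 5, 5),
                   ncol = 2, byrow = TRUE,
                   dimnames = list(sprintf("g%d", 1:6), NULL))
  fs <- stratified_group_kfold(counts, k = 2)
  best <- oracle_best_partition(counts, k = 2, equal_fold_sizes = TRUE)
  expect_equal(fs$objective, best, tolerance = 1e-12)
  # the reported objective is consistent with an independent recomputation
  expect_equal(fs$objective, oracle_objective(fs$per_fold_class_counts),
               tolerance = 1e-12)
})

test_that("k = number of groups degenerates to one group per fold", {
  counts <- matrix(c(3, 1, 2, 2, 5, 0), ncol = 2, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), NULL))
  fs <- stratified_group_kfold(counts, k = 3)
  expect_true(all(vapply(fs$folds, length, integer(1)) == 1L))
  expect_error(stratified_group_kfold(counts, k = 4), "exceeds")
  expect_error(stratified_group_kfold(counts[1, , drop = FALSE], k = 2),
               "exceeds")
})

test_that("greedy stratification beats chance on random instances", {
  set.seed(23)
  n_inst <- 30
  wins <- 0
  for (i in seq_len(n_inst)) {
    G <- sample(10:20, 1)
    C <- sample(2:4, 1)
    counts <- matrix(rpois(G * C, 4), G, C,
                     dimnames = list(sprintf("g%02d", seq_len(G)), NULL))
    counts[rowSums(counts) == 0, 1] <- 1
    k <- sample(3:5, 1)
    fs <- stratified_group_kfold(counts, k)
    rand <- replicate(200, random_partition_objective(counts, k))
    if (fs$objective <= stats::median(rand)) wins <- wins + 1
  }
  expect_identical(wins, n_inst)
})

test_that("greedy stays within one group's granularity of the enumerated optimum", {
  # group-preserving placement cannot balance finer than whole groups, so
  # the greedy objective is compared to the exhaustive optimum up to the
  # granularity of the largest group spread over the k folds
  set.seed(29)
  for (i in 1:10) {
    G <- 7
    counts <- matrix(rpois(G * 2, 5) + 1, G, 2,
                     dimnames = list(sprintf("g%d", seq_len(G)), NULL))
    fs <- stratified_group_kfold(counts, k = 2)
    best <- oracle_best_partition(counts, k = 2)
    expect_lte(fs$objective, best + max(rowSums(counts)) / 2 + 1e-9)
  }
})

test_that("inter-patient CV partitions patients across disjoint test folds", {
  meta <- random_meta(40, seg_per_patient = 12, seed = 41)
  splits <- inter_patient_cv(meta, k = 10)
  expect_length(splits, 10)
  test_patients <- list()
  covered <- integer(0)
  for (sp in splits) {
    ok <- verify_inter_patient(sp, meta)
    expect_true(ok)
    expect_length(attr(ok, "violations"), 0)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$val, sp$test), 0)
    test_patients <- c(test_patients, list(unique(meta$patient_id[sp$test])))
    covered <- c(covered, sp$test)
  }
  # every patient appears in exactly one test fold: 40 patients over 10 folds
  all_p <- unlist(test_patients)
  expect_identical(sort(all_p), sort(unique(meta$patient_id)))
  expect_identical(anyDuplicated(all_p), 0L)
  expect_true(all(vapply(test_patients, length, integer(1)) == 4L))
  # the union of test sets covers every segment exactly once
  expect_identical(sort(covered), seq_len(nrow(meta)))
})

test_that("too few patients for k folds advises leave-one-patient-out", {
  meta <- random_meta(5)
  expect_error(inter_patient_cv(meta, k = 10), "leave-one-patient-out")
})

test_that("intra-patient CV stratifies by class and reproduces under a seed", {
  meta <- random_meta(10, seg_per_patient = 10, seed = 3)
  splits <- intra_patient_cv(meta, k = 10, seed = 5)
  expect_length(splits, 10)
  expect_true(all(vapply(splits, function(s) length(s$test), integer(1)) == 10L))
  # per-fold class proportions within one segment of the global ones
  glob <- tabulate(meta$label, 3)
  for (sp in splits) {
    fold_counts <- tabulate(meta$label[sp$test], 3)
    expect_true(all(abs(fold_counts - glob / 10) <= 1))
  }
  splits2 <- intra_patient_cv(meta, k = 10, seed = 5)
  expect_identical(splits, splits2)
  # a class rarer than k segments is refused by name
  meta$label[meta$label == 3] <- 1
  meta$label[1:2] <- 3
  expect_error(intra_patient_cv(meta, k = 10), "class 3")
})

test_that("leave-one-patient-out gives one split per patient, partitioning segments", {
  meta <- random_meta(5, seg_per_patient = 6)
  splits <- leave_one_patient_out(meta)
  expect_length(splits, 5)
  covered <- unlist(lapply(splits, `[[`, "test"))
  expect_identical(sort(covered), seq_len(nrow(meta)))
  for (sp in splits) expect_true(verify_inter_patient(sp, meta))
  expect_error(leave_one_patient_out(random_meta(2)), "at least 3")
})

test_that("predefined folds are honoured exactly", {
  meta <- random_meta(12, seg_per_patient = 5)
  assignment <- data.frame(record_id = unique(meta$record_id),
                           fold = rep(1:4, each = 3))
  splits <- predefined_folds(meta, assignment)
  expect_length(splits, 4)
  for (i in 1:4) {
    expect_identical(sort(unique(meta$record_id[splits[[i]]$test])),
                     sort(assignment$record_id[assignment$fold == i]))
  }
  # holdout: 2-valued assignment gives one split with a carved-out val set
  hold <- data.frame(record_id = unique(meta$record_id),
                     fold = rep(c("train", "test"), each = 6))
  hs <- predefined_folds(meta, hold, seed = 1)
  expect_length(hs, 1)
  sp <- hs[[1]]
  expect_gt(length(sp$val), 0)
  expect_true(verify_inter_patient(sp, meta))
  expect_identical(sort(c(sp$train, sp$val, sp$test)), seq_len(nrow(meta)))
  # errors: unassigned and contradictory assignments
  expect_error(predefined_folds(meta, assignment[-1, ]), "unassigned")
  expect_error(predefined_folds(meta, rbind(assignment, assignment[1, ])),
               "contradictory")
})

test_that("verify_inter_patient flags patient-straddling splits", {
  meta <- random_meta(4, seg_per_patient = 4)
  bad <- structure(list(train = 1:10, val = 11:12, test = 13:16,
                        fold = 1L, scheme = "manual"),
                   class = "train_val_test")
  ok <- verify_inter_patient(bad, meta)
  expect_false(ok)
  expect_true("p003" %in% attr(ok, "violations"))
  # one segment per patient: intra- and inter-patient coincide
  meta1 <- random_meta(8, seg_per_patient = 1)
  sp <- intra_patient_cv(meta1, k = 2, seed = 1)[[1]]
  expect_true(verify_inter_patient(sp, meta1))
})

test_that("schemes are deterministic under fixed seeds", {
  meta <- random_meta(20, seg_per_patient = 8, seed = 77)
  expect_identical(inter_patient_cv(meta, k = 5), inter_patient_cv(meta, k = 5))
  expect_identical(leave_one_patient_out(meta), leave_one_patient_out(meta))
  fs1 <- stratified_group_kfold(table(meta$patient_id, meta$label), 5)
  fs2 <- stratified_group_kfold(table(meta$patient_id, meta$label), 5)
  expect_identical(fs1, fs2)
})

test_that("fold assignments export to a patient,fold table", {
  meta <- random_meta(9, seg_per_patient = 4)
  splits <- inter_patient_cv(meta, k = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fold_split(attr(splits, "fold_split"), path)
  df <- utils::read.csv(path)
  expect_identical(sort(df$patient_id), sort(unique(meta$patient_id)))
  expect_identical(sort(unique(df$fold)), 1:3)
})
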