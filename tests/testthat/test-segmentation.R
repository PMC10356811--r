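# a minimal record with hand-placed annotations for exact-value checks
toy_record <- function(L = 6500, fs = 250) {
  ecg_record("toy", "ptoy", numeric(L), fs)
}

dict <- default_label_dictionary()
form <- default_tasks()$form
rhythm3 <- default_tasks()$rhythm_reduced

test_that("beat windows have round(duration * fs) samples, centred on the R-peak", {
  rec <- ecg_record("r", "p", seq_len(3600), 360)
  beats <- data.frame(sample = c(10L, 1000L, 2000L, 3595L),
                      symbol = c("N", "V", "N", "N"))
  segs <- segment_beats(rec, beats, 0.72, dict, form, dataset = "synth")
  # 0.72 s at 360 Hz -> 259 samples; boundary beats (10, 3595) dropped
  expect_identical(length(segs), 2L)
  expect_true(all(vapply(segs$signals, length, integer(1)) == 259L))
  expect_identical(segs$meta$start, c(1000L, 2000L) - 259L %/% 2L)
  # window content is the raw signal slice
  expect_identical(segs$signals[[1]],
                   as.numeric((1000 - 129):(1000 + 129)))
})

test_that("interior beats produce one segment each with per-beat labels", {
  rec <- toy_record()
  beats <- data.frame(sample = c(1000L, 2000L, 3000L),
                      symbol = c("N", "V", "N"))
  segs <- segment_beats(rec, beats, 0.72, dict, form, dataset = "synth")
  expect_identical(segs$meta$label, c(1L, 3L, 1L)) # N, VEB, N
  # unknown symbols are dropped, not fatal
  beats2 <- rbind(beats, data.frame(sample = 4000L, symbol = "?"))
  segs2 <- segment_beats(rec, beats2, 0.72, dict, form, dataset = "synth")
  expect_identical(length(segs2), 3L)
  # never more segments than annotated beats
  expect_lte(length(segs2), nrow(beats2))
})

test_that("episode segmentation emits one span-length segment per episode", {
  rec <- toy_record(12000)
  eps <- data.frame(start = c(1L, 5001L), end = c(5001L, 12001L),
                    symbol = c("N", "AFIB"))
  segs <- segment_episodes(rec, eps, dict, rhythm3, dataset = "synth")
  expect_identical(vapply(segs$signals, length, integer(1)), c(5000L, 7000L))
  expect_identical(segs$meta$label, c(2L, 1L)) # SINUS, AFIB
  # single full-record episode
  one <- data.frame(start = 1L, end = 12001L, symbol = "AFIB")
  segs1 <- segment_episodes(rec, one, dict, rhythm3, dataset = "synth")
  expect_identical(segs1$signals[[1]], rec$samples)
  # unmapped episode symbol contributes nothing
  none <- data.frame(start = 1L, end = 12001L, symbol = "??")
  expect_identical(length(segment_episodes(rec, none, dict, rhythm3,
                                           dataset = "synth")), 0L)
  # overlapping episodes violate the upstream invariant
  bad <- data.frame(start = c(1L, 4000L), end = c(5001L, 9000L),
                    symbol = c("N", "AFIB"))
  expect_error(segment_episodes(rec, bad, dict, rhythm3, dataset = "synth"),
               "overlapping")
})

test_that("window labelling follows abnormal-priority and coverage voting", {
  beats <- data.frame(sample = c(100L, 200L, 300L, 400L),
                      symbol = c("N", "N", "V", "N"))
  eps <- data.frame(start = integer(0), end = integer(0),
                    symbol = character(0))
  # one PVC among normals labels the whole window as VEB
  expect_identical(label_window(c(1L, 500L), beats, eps, dict, form,
                                dataset = "synth"), 3L)
  # all-normal window stays N
  beats_n <- data.frame(sample = c(100L, 200L), symbol = c("N", "N"))
  expect_identical(label_window(c(1L, 500L), beats_n, eps, dict, form,
                                dataset = "synth"), 1L)
  # two distinct abnormal classes: the globally rarer one wins
  beats_av <- data.frame(sample = c(100L, 200L), symbol = c("A", "V"))
  expect_identical(
    label_window(c(1L, 500L), beats_av, eps, dict, form, dataset = "synth",
                 class_counts = c(100, 30, 5)), 3L) # VEB rarer -> VEB
  expect_identical(
    label_window(c(1L, 500L), beats_av, eps, dict, form, dataset = "synth",
                 class_counts = c(100, 5, 30)), 2L) # SVEB rarer -> SVEB
  # window with no resolvable beats is excluded
  expect_true(is.na(label_window(c(1L, 500L),
                                 data.frame(sample = 100L, symbol = "?"),
                                 eps, dict, form, dataset = "synth")))
  # rhythm: 60/40 coverage -> majority class
  eps2 <- data.frame(start = c(1L, 301L), end = c(301L, 501L),
                     symbol = c("AFIB", "N"))
  expect_identical(label_window(c(1L, 501L), beats, eps2, dict, rhythm3,
                                dataset = "synth"), 1L)
  # exact 50/50 tie -> earlier-starting episode's class
  eps3 <- data.frame(start = c(1L, 251L), end = c(251L, 501L),
                     symbol = c("N", "AFIB"))
  expect_identical(label_window(c(1L, 501L), beats, eps3, dict, rhythm3,
                                dataset = "synth"), 2L) # SINUS started first
})

test_that("sliding-window counts obey floor((L - w)/s) + 1", {
  rec <- toy_record(6500, 250)
  beats <- data.frame(sample = seq(100L, 6400L, by = 200L), symbol = "N")
  eps <- data.frame(start = 1L, end = 6501L, symbol = "N")
  segs <- segment_sliding(rec, beats, eps, 2.5, 0.5, dict, rhythm3,
                          dataset = "synth")
  expect_identical(length(segs), 19L) # floor((6500-625)/312)+1
  expect_true(all(vapply(segs$signals, length, integer(1)) == 625L))
  # record shorter than the window yields nothing
  expect_identical(length(segment_sliding(toy_record(624), beats[0, ], eps,
                                          2.5, 0.5, dict, rhythm3,
                                          dataset = "synth")), 0L)
  # zero overlap: stride equals window
  segs0 <- segment_sliding(rec, beats, eps, 2.5, 0, dict, rhythm3,
                           dataset = "synth")
  expect_identical(length(segs0), 6500L %/% 625L)
  expect_identical(diff(segs0$meta$start), rep(625L, length(segs0) - 1L))
  # degenerate stride errors
  expect_error(segment_sliding(rec, beats, eps, 0.001, 0.5, dict, rhythm3,
                               dataset = "synth"), "zero")
  # randomized check of the closed form against enumeration
  set.seed(6)
  for (i in 1:50) {
    L <- sample(300:5000, 1)
    w_s <- runif(1, 0.5, 4)
    ov <- runif(1, 0, 0.8)
    w <- round(w_s * 100)
    s <- round(w * (1 - ov))
    if (s < 1 || w < 1) next
    n_enum <- if (L < w) 0L else length(seq(1L, L - w + 1L, by = s))
    got <- length(segment_sliding(ecg_record("x", "x", numeric(L), 100),
                                  beats[0, ],
                                  data.frame(start = 1L, end = L + 1L,
                                             symbol = "AFIB"),
                                  w_s, ov, dict, rhythm3, dataset = "synth"))
    expect_identical(got, n_enum)
    if (L >= w) expect_identical(n_enum, as.integer((L - w) %/% s) + 1L)
  }
})

test_that("sliding-window labels match the brute-force rule applier", {
  set.seed(31)
  tasks <- list(form, rhythm3)
  for (i in 1:150) {
    st <- random_annotation_stream()
    task <- tasks[[1 + i %% 2]]
    counts <- if (task$kind == "form") c(50, 10, 3) else NULL
    segs <- segment_sliding(st$record, st$beats, st$episodes, 2.5, 0.5,
                            dict, task, dataset = "synth",
                            class_counts = counts)
    w <- round(2.5 * st$record$fs)
    s <- round(w * 0.5)
    starts <- ecgbench:::.window_grid(length(st$record$samples), w, s)
    expected <- vapply(starts, function(ss) {
      oracle_label_window(c(ss, ss + w), st$beats, st$episodes, dict, task,
                          "synth", counts)
    }, integer(1))
    expect_identical(segs$meta$label, expected[!is.na(expected)])
    expect_identical(segs$meta$start, starts[!is.na(expected)])
  }
})

test_that("recording windows inherit the recording label", {
  rec <- ecg_record("q1", "q1", numeric(5000), 500)
  segs <- segment_recording_windows(rec, "AFIB", 2.5, 0.5, dict, rhythm3,
                                    dataset = "synthrec")
  expect_identical(length(segs), 7L) # floor((5000-1250)/625)+1
  expect_true(all(segs$meta$label == 1L))
  # a window as long as the record yields exactly one segment
  segs1 <- segment_recording_windows(rec, "AFIB", 10, 0.5, dict, rhythm3,
                                     dataset = "synthrec")
  expect_identical(length(segs1), 1L)
  # unresolvable label: skipped with a warning
  expect_warning(
    s0 <- segment_recording_windows(rec, "NOLABEL", 2.5, 0.5, dict, rhythm3,
                                    dataset = "synthrec"),
    "unresolvable")
  expect_identical(length(s0), 0L)
})

test_that("whole-sequence inputs are cropped or padded to the target length", {
  rhy <- default_tasks()$rhythm
  rec10 <- ecg_record("q1", "q1", numeric(5000), 500)
  s <- whole_sequence(rec10, "SINUS", 10, dict, rhy, dataset = "synthrec")
  expect_identical(length(s$signals[[1]]), 5000L)
  rec8 <- ecg_record("q2", "q2", stats::rnorm(4000), 500)
  s8 <- whole_sequence(rec8, "SINUS", 10, dict, rhy, dataset = "synthrec")
  expect_identical(length(s8$signals[[1]]), 5000L)
  expect_identical(s8$signals[[1]][4001:5000], rep(0, 1000))
  rec60 <- ecg_record("q3", "q3", stats::rnorm(30000), 500)
  s60 <- whole_sequence(rec60, "SINUS", 10, dict, rhy, dataset = "synthrec")
  expect_identical(s60$signals[[1]], rec60$samples[1:5000])
})

test_that("window predictions aggregate by majority with a deterministic tie-break", {
  expect_identical(aggregate_predictions(c("a", "a", "a"), c(1L, 1L, 2L)),
                   c(a = 1L))
  expect_identical(aggregate_predictions(c("a", "a"), c(2L, 1L)),
                   c(a = 1L)) # tie -> lowest class index
  expect_identical(aggregate_predictions("a", 3L), c(a = 3L))
  expect_identical(aggregate_predictions(c("a", "b", "b"), c(3L, 2L, 2L)),
                   c(a = 3L, b = 2L))
  expect_error(aggregate_predictions(character(0), integer(0)), "no predictions")
})

test_that("segments never span records and always carry their patient", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_patients = 4, record_duration_s = 30, seed = 3)
  h <- generate_beat_level_dataset(cfg, dir)
  all_segs <- NULL
  for (rid in h$records$record_id) {
    rr <- read_record(h, rid)
    segs <- segment_sliding(rr$record, rr$beats, rr$episodes, 2.5, 0.5,
                            dict, rhythm3, dataset = "synth")
    L <- length(rr$record$samples)
    w <- round(2.5 * rr$record$fs)
    expect_true(all(segs$meta$start >= 1 & segs$meta$start + w - 1 <= L))
    expect_true(all(segs$meta$record_id == rid))
    expect_true(all(segs$meta$patient_id ==
                      h$records$patient_id[h$records$record_id == rid]))
    all_segs <- if (is.null(all_segs)) segs else bind_segments(all_segs, segs)
  }
  expect_gt(length(all_segs), 0)
})
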