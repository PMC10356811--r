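# quick forward pass through a model's internal network
fwd_logits <- function(model, x, training = FALSE) {
  xa <- ecgbench:::.as_input_array(x, model$spec$input_len)
  ecgbench:::.model_forward(model, xa, training = training)$y
}

test_that("model specs default to each architecture's native frequency", {
  expect_identical(model_spec("cnn", 3, 259)$input_fs, 360)
  expect_identical(model_spec("resnet", 3, 600)$input_fs, 250)
  expect_identical(model_spec("gruattnet", 3, 5000)$input_fs, 500)
  expect_identical(model_spec("rtacnn", 3, 3000)$input_fs, 300)
  expect_error(model_spec("cnn", 1, 259), "n_classes")
})

test_that("the CNN has the prescribed shape and parameter counts", {
  m <- build_cnn(model_spec("cnn", 3, 259, seed = 1))
  conv1 <- m$net$layers[[1]]
  # 5 filters of size 3 on 1 channel: 5*(3*1) weights + 5 biases = 20
  expect_identical(length(m$params[[conv1$W]]) + length(m$params[[conv1$b]]),
                   20L)
  expect_identical(count_conv_layers(m), 3L)
  expect_error(build_cnn(model_spec("cnn", 3, 7)), "too short")
  # forward output is a valid simplex
  set.seed(1)
  p <- predict(m, matrix(rnorm(2 * 259), 2))$prob
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
})

test_that("the ResNet counts 9 convolution layers and pools to a fixed GAP width", {
  m <- build_resnet(model_spec("resnet", 4, 600, seed = 2))
  expect_identical(count_conv_layers(m), 9L)
  # every block carries a size-1 projection shortcut
  blocks <- Filter(function(l) l$type == "res_block", m$net$layers)
  expect_length(blocks, 4)
  for (b in blocks) expect_identical(b$short$k, 1)
  # GAP output width equals the final filter count regardless of input_len
  m2 <- build_resnet(model_spec("resnet", 4, 320, seed = 2))
  dense <- m$net$layers[[length(m$net$layers)]]
  dense2 <- m2$net$layers[[length(m2$net$layers)]]
  expect_equal(dense$din, 256)
  expect_equal(dense2$din, 256)
})

test_that("GRUAttNet uses 12 filters everywhere and normalized attention", {
  m <- build_gruattnet(model_spec("gruattnet", 3, 5000, seed = 3))
  convs <- Filter(function(l) l$type == "conv", m$net$layers)
  expect_length(convs, 15)
  expect_true(all(vapply(convs, `[[`, numeric(1), "cout") == 12))
  # attention weights over time sum to 1 for each input
  att_idx <- which(vapply(m$net$layers, `[[`, character(1), "type") ==
                     "attention")
  set.seed(4)
  xa <- ecgbench:::.as_input_array(matrix(rnorm(2 * 5000), 2), 5000)
  x <- xa
  for (i in seq_len(att_idx - 1)) {
    x <- ecgbench:::.fwd(m$net$layers[[i]], x, m$params, m$state, FALSE)$y
  }
  r <- ecgbench:::.fwd(m$net$layers[[att_idx]], x, m$params, m$state, FALSE)
  expect_equal(unname(rowSums(r$cache$a)), c(1, 1), tolerance = 1e-9)
})

test_that("RTA blocks gate the trunk with attention in [0, 1]", {
  m <- build_rtacnn(model_spec("rtacnn", 3, 3000, seed = 5))
  blocks <- Filter(function(l) l$type == "rta_block", m$net$layers)
  expect_length(blocks, 6)
  b1 <- blocks[[1]]
  set.seed(6)
  xa <- ecgbench:::.as_input_array(matrix(rnorm(2 * 3000), 2), 3000)
  r <- ecgbench:::.fwd(b1, xa, m$params, m$state, FALSE)
  expect_true(all(r$cache$a_out >= 0 & r$cache$a_out <= 1))
  # block output is exactly trunk * (1 + attention); zero attention
  # leaves the trunk untouched
  expect_equal(r$y, r$cache$t_out * (1 + r$cache$a_out), tolerance = 1e-12)
  expect_equal(r$cache$t_out * (1 + 0), r$cache$t_out)
})

test_that("builds are reproducible under a fixed seed", {
  for (arch in c("cnn", "resnet", "gruattnet", "rtacnn")) {
    len <- c(cnn = 259, resnet = 600, gruattnet = 5000, rtacnn = 3000)[[arch]]
    m1 <- build_model(model_spec(arch, 3, len, seed = 11))
    m2 <- build_model(model_spec(arch, 3, len, seed = 11))
    expect_identical(m1$params, m2$params)
  }
})

test_that("losses behave as documented", {
  p_perfect <- matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE)
  expect_equal(cross_entropy_loss(p_perfect, c(1L, 2L)), 0, tolerance = 1e-6)
  expect_equal(en_loss(p_perfect, c(1L, 2L)), 0, tolerance = 1e-6)
  # cross-entropy at p_true = 0.5 is ln 2
  expect_equal(cross_entropy_loss(matrix(c(0.5, 0.5), 1), 1L), log(2),
               tolerance = 1e-12)
  # EN loss is non-negative and monotone in -log p_true
  set.seed(8)
  for (i in 1:20) {
    p <- runif(1)
    expect_gte(en_loss(matrix(c(p, 1 - p), 1), 1L), 0)
  }
  ps <- seq(0.05, 0.95, by = 0.05)
  en <- vapply(ps, function(p) en_loss(matrix(c(p, 1 - p), 1), 1L), numeric(1))
  expect_true(all(diff(en) < 0)) # decreasing in p_true
  # zero probability at the true label is clamped, not -Inf
  expect_true(is.finite(cross_entropy_loss(matrix(c(0, 1), 1), 1L)))
})

test_that("the majority baseline predicts the modal class with tie to lowest", {
  m <- dummy_majority(rep(1:3, c(80, 15, 5)), 3)
  pr <- predict(m, matrix(0, 10, 4))
  expect_true(all(pr$label == 1L))
  expect_true(all(pr$prob[, 1] == 1))
  m2 <- dummy_majority(c(1L, 1L, 2L, 2L), 3)
  expect_identical(predict(m2, matrix(0, 1, 1))$label, 1L)
  # macro F1 on its own training distribution follows the closed form
  truth <- rep(1:3, c(80, 15, 5))
  rep_ <- compute_metrics(truth, predict(m, matrix(0, 100, 1))$label, 3)
  expect_equal(rep_$macro_f1, (2 * 0.8 / 1.8) / 3, tolerance = 1e-12)
})

test_that("one small-step update decreases the batch loss for every architecture", {
  lens <- c(cnn = 259, resnet = 600, gruattnet = 5000, rtacnn = 3000)
  builders <- list(cnn = function(s) build_cnn(s),
                   resnet = function(s) build_resnet(s, dropout = 0),
                   gruattnet = function(s) build_gruattnet(s, dropout = 0),
                   rtacnn = function(s) build_rtacnn(s, dropout = 0))
  for (arch in names(lens)) {
    m <- builders[[arch]](model_spec(arch, 3, lens[[arch]], seed = 1))
    set.seed(9)
    xa <- ecgbench:::.as_input_array(matrix(rnorm(4 * lens[[arch]]), 4),
                                     lens[[arch]])
    yb <- c(1L, 2L, 3L, 1L)
    opt <- ecgbench:::.adam_init(m$params)
    st <- ecgbench:::.train_step(m, xa, yb, opt, 1e-4)
    fw2 <- ecgbench:::.fwd(st$model$net, xa, st$model$params, m$state, TRUE)
    l2 <- ecgbench:::.loss_grad(fw2$y, yb, "cross_entropy")$value
    expect_lt(l2, st$loss)
  }
})

test_that("training is reproducible, stops on patience, and guards inputs", {
  prep <- separable_beat_data(per_class = 30, seed = 15, fs_out = 360)
  set.seed(44)
  sh <- sample(90)
  tr <- sh[1:60]
  va <- sh[61:90]
  cfg <- train_config(max_epochs = 6, batch_size = 16,
                      early_stop_patience = 1)
  m1 <- train_model(build_cnn(model_spec("cnn", 3, 259, seed = 7)),
                    prep$x[tr, ], prep$y[tr], prep$x[va, ], prep$y[va], cfg)
  m2 <- train_model(build_cnn(model_spec("cnn", 3, 259, seed = 7)),
                    prep$x[tr, ], prep$y[tr], prep$x[va, ], prep$y[va], cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  # the early-stopping bookkeeping matches the recorded history: training
  # ends once val loss has failed to improve for patience+1 epochs
  h <- m1$history$val_loss
  running_best <- cummin(h)
  stall <- which(h[-1] >= running_best[-length(h)] - 1e-9)
  if (length(stall) && (stall[1] + 1) < cfg$max_epochs) {
    expect_lte(nrow(m1$history), stall[1] + 1 + cfg$early_stop_patience)
  }
  # patience 0 stops at the first non-improving epoch
  cfg0 <- train_config(max_epochs = 10, batch_size = 16,
                       early_stop_patience = 0, learning_rate = 0.5)
  m0 <- train_model(build_cnn(model_spec("cnn", 3, 259, seed = 7)),
                    prep$x[tr, ], prep$y[tr], prep$x[va, ], prep$y[va], cfg0)
  h0 <- m0$history$val_loss
  first_stall <- which(diff(cummin(h0)) == 0)
  if (length(first_stall)) {
    expect_identical(nrow(m0$history), first_stall[1] + 1L)
  }
  # input-length mismatches are refused, not silently re-fitted
  expect_error(predict(m1, matrix(0, 2, 100)), "input_len")
  expect_error(train_model(build_cnn(model_spec("cnn", 3, 259)),
                           prep$x[integer(0), ], integer(0),
                           prep$x[va, ], prep$y[va], cfg),
               "empty training set")
  expect_warning(train_model(build_cnn(model_spec("cnn", 3, 259, seed = 1)),
                             prep$x[prep$y != 3, ], prep$y[prep$y != 3],
                             prep$x[va, ], prep$y[va],
                             train_config(max_epochs = 1)),
                 "absent")
})

test_that("models round-trip through serialization", {
  m <- build_cnn(model_spec("cnn", 3, 259, seed = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$params, m2$params)
  set.seed(3)
  x <- matrix(rnorm(259), 1)
  expect_identical(predict(m, x), predict(m2, x))
})
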