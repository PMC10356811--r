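# The four benchmark architectures and the majority-class baseline.
# Each network is tied by default to the input frequency of the study
# where it was proposed: CNN 360 Hz, ResNet 250 Hz, GRUAttNet 500 Hz,
# RTA-CNN 300 Hz. Input length is fixed per model; inputs must be
# prepared (resampled + length-fitted) before training or prediction.

.default_fs <- c(cnn = 360, resnet = 250, gruattnet = 500, rtacnn = 300,
                 dummy_mv = NA)

#' Model specification
#'
#' @param architecture One of `"cnn"`, `"resnet"`, `"gruattnet"`,
#'   `"rtacnn"`, `"dummy_mv"`.
#' @param n_classes Number of target classes (>= 2).
#' @param input_len Input length in samples (at `input_fs`).
#' @param input_fs Input frequency in Hz; defaults to the architecture's
#'   native frequency (360/250/500/300).
#' @param loss `"cross_entropy"` (default) or `"en_loss"`.
#' @param seed Integer seed for parameter initialization (and training
#'   shuffles/dropout).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture = c("cnn", "resnet", "gruattnet",
                                        "rtacnn", "dummy_mv"),
                       n_classes, input_len, input_fs = NULL,
                       loss = c("cross_entropy", "en_loss"), seed = 0) {
  architecture <- match.arg(architecture)
  loss <- match.arg(loss)
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (architecture != "dummy_mv" && input_len < 1) stop("input_len must be >= 1")
  if (is.null(input_fs)) input_fs <- unname(.default_fs[architecture])
  structure(list(architecture = architecture, n_classes = n_classes,
                 input_len = as.integer(input_len), input_fs = input_fs,
                 loss = loss, seed = seed),
            class = "model_spec")
}

.finish_model <- function(spec, B, layers) {
  structure(list(spec = spec, net = .layer_seq(layers), params = B$params,
                 state = B$state, trained = FALSE, history = NULL),
            class = "ecg_model")
}

#' Build the simple CNN
#'
#' Three convolution blocks — conv1d / leaky-ReLU / max-pool (stride 2) —
#' with (filters, kernel) = (5, 3), (10, 4), (20, 4), followed by dense
#' layers of 30, 20 and C units (softmax output).
#'
#' @param spec A [model_spec()] with `architecture = "cnn"`.
#' @return An untrained `ecg_model`.
#' @export
build_cnn <- function(spec) {
  stopifnot(spec$architecture == "cnn")
  if (spec$input_len < 8) stop("input_len too short for three stride-2 pools")
  set.seed(spec$seed)
  B <- .nn_builder()
  L <- spec$input_len
  layers <- list()
  filt <- c(5, 10, 20); ks <- c(3, 4, 4); cin <- 1
  for (i in 1:3) {
    layers <- c(layers, list(.layer_conv(B, ks[i], cin, filt[i]),
                             .layer_lrelu(), .layer_pool()))
    cin <- filt[i]; L <- L %/% 2L
  }
  layers <- c(layers, list(
    .layer_flatten(),
    .layer_dense(B, L * 20L, 30L), .layer_lrelu(),
    .layer_dense(B, 30L, 20L), .layer_lrelu(),
    .layer_dense(B, 20L, spec$n_classes)))
  .finish_model(spec, B, layers)
}

#' Build the ResNet
#'
#' Stem convolution (64 filters, size 3) plus four residual blocks of two
#' size-3 convolutions each, with batch normalization and dropout between
#' the convolutions and a projection shortcut around every block — 9
#' convolution layers in total (projection shortcuts not counted). Blocks
#' carry 64, 128, 256 and 256 filters; max-pooling (stride 2) follows
#' blocks 1-3; a global average pooling layer feeds the softmax
#' classification layer.
#'
#' @param spec A [model_spec()] with `architecture = "resnet"`.
#' @param filters Per-block filter counts (length 4).
#' @param dropout Dropout rate inside the blocks.
#' @return An untrained `ecg_model`.
#' @export
build_resnet <- function(spec, filters = c(64, 128, 256, 256),
                         dropout = 0.2) {
  stopifnot(spec$architecture == "resnet", length(filters) == 4)
  if (spec$input_len < 8) stop("input_len too short for the pooling stack")
  set.seed(spec$seed)
  B <- .nn_builder()
  layers <- list(.layer_conv(B, 3, 1, filters[1]),
                 .layer_bn(B, filters[1]), .layer_lrelu())
  cin <- filters[1]
  for (i in 1:4) {
    layers <- c(layers, list(.layer_res_block(B, 3, cin, filters[i], dropout)))
    cin <- filters[i]
    if (i <= 3) layers <- c(layers, list(.layer_pool()))
  }
  layers <- c(layers, list(.layer_gap(),
                           .layer_dense(B, cin, spec$n_classes)))
  .finish_model(spec, B, layers)
}

#' Build GRUAttNet
#'
#' Five convolution blocks of three size-(3, 3, 24) convolutions with 12
#' filters each (leaky-ReLU activations, dropout and stride-2 max-pooling
#' closing each block), followed by a bidirectional GRU of 12 units per
#' direction and an additive attention pooling layer feeding the softmax
#' classification layer.
#'
#' @param spec A [model_spec()] with `architecture = "gruattnet"`.
#' @param dropout Dropout rate at the end of each block.
#' @return An untrained `ecg_model`.
#' @export
build_gruattnet <- function(spec, dropout = 0.2) {
  stopifnot(spec$architecture == "gruattnet")
  if (spec$input_len < 32) stop("input_len too short for five stride-2 pools")
  set.seed(spec$seed)
  B <- .nn_builder()
  layers <- list()
  cin <- 1
  for (i in 1:5) {
    layers <- c(layers, list(
      .layer_conv(B, 3, cin, 12), .layer_lrelu(),
      .layer_conv(B, 3, 12, 12), .layer_lrelu(),
      .layer_conv(B, 24, 12, 12), .layer_lrelu(),
      .layer_dropout(dropout), .layer_pool()))
    cin <- 12
  }
  layers <- c(layers, list(
    .layer_gru_bi(B, 12, 12),
    .layer_attention(B, 24),
    .layer_dense(B, 24, spec$n_classes)))
  .finish_model(spec, B, layers)
}

#' Build RTA-CNN
#'
#' Six residual temporal-attention (RTA) blocks. Each block combines a
#' two-convolution trunk branch with an attention branch
#' (downsample-convolve-upsample, sigmoid weights in `[0, 1]` per time
#' step) as `trunk * (1 + attention)`, so zeroed attention weights leave
#' the trunk output untouched. Kernel lengths decrease over the blocks
#' (32, 16, 9, 9, 3, 3); filter counts default to (16, 32, 64, 64, 64,
#' 128). Batch normalization follows the convolutions, dropout and
#' stride-2 max-pooling follow each block; a 100-unit dense layer
#' precedes the softmax classification layer.
#'
#' @param spec A [model_spec()] with `architecture = "rtacnn"`.
#' @param filters Per-block filter counts (length 6).
#' @param kernels Per-block kernel lengths (length 6).
#' @param dropout Dropout rate after each block.
#' @return An untrained `ecg_model`.
#' @export
build_rtacnn <- function(spec, filters = c(16, 32, 64, 64, 64, 128),
                         kernels = c(32, 16, 9, 9, 3, 3), dropout = 0.2) {
  stopifnot(spec$architecture == "rtacnn", length(filters) == 6,
            length(kernels) == 6)
  if (spec$input_len < 64) stop("input_len too short for six stride-2 pools")
  set.seed(spec$seed)
  B <- .nn_builder()
  layers <- list()
  cin <- 1
  L <- spec$input_len
  for (i in 1:6) {
    layers <- c(layers, list(
      .layer_rta_block(B, kernels[i], cin, filters[i], L),
      .layer_pool(), .layer_dropout(dropout)))
    cin <- filters[i]
    L <- L %/% 2L
  }
  layers <- c(layers, list(
    .layer_flatten(),
    .layer_dense(B, L * cin, 100L), .layer_lrelu(),
    .layer_dense(B, 100L, spec$n_classes)))
  .finish_model(spec, B, layers)
}

#' Build a model from its specification
#'
#' @param spec A [model_spec()].
#' @param ... Architecture-specific arguments passed through (e.g.
#'   `filters`).
#' @return An `ecg_model` (untrained, or a ready majority-class baseline
#'   for `dummy_mv` — see [dummy_majority()]).
#' @export
build_model <- function(spec, ...) {
  switch(spec$architecture,
         cnn = build_cnn(spec, ...),
         resnet = build_resnet(spec, ...),
         gruattnet = build_gruattnet(spec, ...),
         rtacnn = build_rtacnn(spec, ...),
         dummy_mv = stop("use dummy_majority(train_labels, n_classes)"))
}

#' Majority-class baseline
#'
#' Always predicts the most frequent training class (probability 1 on
#' it); ties go to the lowest class index.
#'
#' @param train_labels Integer training labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return A trained `ecg_model` with architecture `dummy_mv`.
#' @export
dummy_majority <- function(train_labels, n_classes) {
  if (!length(train_labels)) stop("empty training labels")
  counts <- tabulate(train_labels, nbins = n_classes)
  spec <- model_spec("dummy_mv", n_classes = n_classes, input_len = 1L)
  structure(list(spec = spec, net = NULL, params = list(),
                 state = list(), trained = TRUE, history = NULL,
                 majority_class = which.max(counts)),
            class = "ecg_model")
}

#' Count convolution layers of a model
#'
#' @param model An `ecg_model`.
#' @param include_projections Count size-1 projection/attention-gating
#'   convolutions too (default FALSE, matching the convention of counting
#'   only feature-extracting convolutions).
#' @return Integer count.
#' @export
count_conv_layers <- function(model, include_projections = FALSE) {
  count <- function(layer) {
    switch(layer$type,
      seq = sum(vapply(layer$layers, count, numeric(1))),
      conv = if (layer$k > 1 || include_projections) 1 else 0,
      res_block = count(layer$body) +
        if (include_projections) count(layer$short) else 0,
      rta_block = count(layer$trunk) + count(layer$att),
      0)
  }
  as.integer(count(model$net))
}

#' Training configuration
#'
#' Defaults: Adam with learning rate 1e-3, batch size 32, up to 100
#' epochs, early stopping with patience 10 on validation loss, best
#' parameters restored.
#'
#' @param max_epochs,batch_size,learning_rate,early_stop_patience Scalars.
#' @param early_stop_metric `"val_loss"` (minimized) or `"val_macro_f1"`
#'   (maximized).
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 100, batch_size = 32,
                         learning_rate = 1e-3, early_stop_patience = 10,
                         early_stop_metric = c("val_loss", "val_macro_f1")) {
  early_stop_metric <- match.arg(early_stop_metric)
  if (max_epochs < 1 || batch_size < 1 || learning_rate <= 0 ||
      early_stop_patience < 0) {
    stop("training hyperparameters must be positive")
  }
  structure(list(max_epochs = max_epochs, batch_size = batch_size,
                 learning_rate = learning_rate,
                 early_stop_patience = early_stop_patience,
                 early_stop_metric = early_stop_metric),
            class = "train_config")
}

.as_input_array <- function(x, input_len) {
  if (is.vector(x)) x <- matrix(x, 1)
  if (ncol(x) != input_len) {
    stop("input length ", ncol(x), " does not match the model input_len ",
         input_len, " (prepare inputs explicitly; no silent re-fitting)")
  }
  array(x, c(nrow(x), ncol(x), 1L))
}

# forward pass to logits; training mode updates BN state
.model_forward <- function(model, x, training = FALSE) {
  r <- .fwd(model$net, x, model$params, model$state, training)
  r
}

# one optimization step on a batch; returns updated model + loss before step
.train_step <- function(model, xb, yb, opt, lr) {
  fw <- .model_forward(model, xb, training = TRUE)
  model$state <- fw$S
  lg <- .loss_grad(fw$y, yb, model$spec$loss)
  bw <- .bwd(model$net, fw$cache, lg$dlogits, model$params)
  up <- .adam_step(model$params, bw$grads, opt, lr)
  model$params <- up$params
  list(model = model, opt = up$st, loss = lg$value)
}

.eval_loss <- function(model, x, y, batch = 256) {
  n <- dim(x)[1]
  total <- 0
  pred <- integer(n)
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(n, s + batch - 1)
    fw <- .model_forward(model, x[idx, , , drop = FALSE], training = FALSE)
    lg <- .loss_grad(fw$y, y[idx], model$spec$loss)
    total <- total + lg$value * length(idx)
    pred[idx] <- max.col(lg$prob, ties.method = "first")
  }
  list(loss = total / n, pred = pred)
}

#' Train a model
#'
#' Minibatch Adam on the model's configured loss with early stopping on a
#' validation metric: training halts when the metric fails to improve for
#' `early_stop_patience` consecutive epochs and the best-validation
#' parameters are restored. All randomness (shuffling, dropout) derives
#' from the model seed, so training is reproducible in this
#' single-threaded engine.
#'
#' @param model An untrained `ecg_model`.
#' @param x,y Training inputs: numeric matrix (one row per segment,
#'   already at the model's input frequency/length) and integer labels.
#' @param val_x,val_y Validation set used for early stopping.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return The trained `ecg_model` with a `history` data.frame
#'   (`epoch`, `train_loss`, `val_loss`, `val_macro_f1`).
#' @export
train_model <- function(model, x, y, val_x, val_y, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "ecg_model"), inherits(cfg, "train_config"))
  if (model$spec$architecture == "dummy_mv") stop("the baseline needs no training")
  if (!length(y)) stop("empty training set")
  missing_cls <- setdiff(seq_len(model$spec$n_classes), unique(y))
  if (length(missing_cls)) {
    warning("class(es) absent from the training set: ",
            paste(missing_cls, collapse = ", "))
  }
  xa <- .as_input_array(x, model$spec$input_len)
  va <- .as_input_array(val_x, model$spec$input_len)
  n <- dim(xa)[1]
  opt <- .adam_init(model$params)
  set.seed(model$spec$seed + 1L)
  best_metric <- Inf
  best_params <- model$params
  best_state <- model$state
  wait <- 0L
  hist <- NULL
  maximize <- cfg$early_stop_metric == "val_macro_f1"
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (s in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[s:min(n, s + cfg$batch_size - 1)]
      st <- .train_step(model, xa[idx, , , drop = FALSE], y[idx], opt,
                        cfg$learning_rate)
      model <- st$model
      opt <- st$opt
      ep_loss <- ep_loss + st$loss * length(idx)
    }
    ev <- .eval_loss(model, va, val_y)
    vf1 <- compute_metrics(val_y, ev$pred, model$spec$n_classes)$macro_f1
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                   val_loss = ev$loss, val_macro_f1 = vf1))
    metric <- if (maximize) -vf1 else ev$loss
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val macro-F1 %.4f",
                      epoch, ep_loss / n, ev$loss, vf1))
    }
    if (metric < best_metric - 1e-9) {
      best_metric <- metric
      best_params <- model$params
      best_state <- model$state
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$early_stop_patience) break
    }
  }
  model$params <- best_params
  model$state <- best_state
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Predict class probabilities and labels
#'
#' @param object A trained `ecg_model`.
#' @param x Numeric matrix, one segment per row, at the model's input
#'   length (no silent re-fitting).
#' @param batch Prediction batch size.
#' @param ... Unused.
#' @return List with `prob` (rows on the probability simplex) and
#'   `label` (argmax, ties to the lowest class index).
#' @export
predict.ecg_model <- function(object, x, batch = 256, ...) {
  if (is.vector(x)) x <- matrix(x, 1)
  C <- object$spec$n_classes
  if (object$spec$architecture == "dummy_mv") {
    prob <- matrix(0, nrow(x), C)
    prob[, object$majority_class] <- 1
    return(list(prob = prob, label = rep(object$majority_class, nrow(x))))
  }
  xa <- .as_input_array(x, object$spec$input_len)
  n <- dim(xa)[1]
  prob <- matrix(0, n, C)
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(n, s + batch - 1)
    fw <- .model_forward(object, xa[idx, , , drop = FALSE], training = FALSE)
    prob[idx, ] <- .softmax(fw$y)
  }
  list(prob = prob, label = max.col(prob, ties.method = "first"))
}

#' @export
print.ecg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("ecg_model: %s, %d classes, input %d samples @ %s Hz, %s, %s\n",
              x$spec$architecture, x$spec$n_classes, x$spec$input_len,
              format(x$spec$input_fs), x$spec$loss,
              if (x$trained) "trained" else "untrained"))
  if (np > 0) cat("parameters:", format(np, big.mark = ","), "\n")
  invisible(x)
}

#' Save / load a model
#'
#' Thin RDS wrappers; the model is a plain R list, so the standard R
#' serialization format is the native model format of this engine.
#'
#' @param model An `ecg_model`.
#' @param path File path.
#' @return `path` (save) or the restored `ecg_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ecg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "ecg_model"))
  m
}
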