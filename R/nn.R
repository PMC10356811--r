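# A compact reverse-mode engine for 1-D neural networks, written on base
# R matrix algebra (convolutions via im2col + BLAS matrix products, BPTT
# for the GRU). It exists so the four benchmark architectures train and
# predict with no dependencies beyond base R; it is deliberately minimal:
# fixed input length per model, stride-1 'same' convolutions, width-2
# max pooling, and the handful of layer types the architectures need.
#
# Tensors are arrays of dim (batch N, time L, channels C). A model keeps
# its parameters in one flat named list (model$params) and mutable layer
# state (batch-norm running moments) in model$state; layers reference
# both by name, which keeps optimizer updates and (de)serialization
# trivial.

.LRELU_ALPHA <- 0.3

# ---- builder -------------------------------------------------------------

.nn_builder <- function() {
  B <- new.env(parent = emptyenv())
  B$params <- list()
  B$state <- list()
  B$n <- 0L
  B
}

.nn_param <- function(B, value) {
  B$n <- B$n + 1L
  nm <- sprintf("p%03d", B$n)
  B$params[[nm]] <- value
  nm
}

.nn_state <- function(B, value) {
  B$n <- B$n + 1L
  nm <- sprintf("s%03d", B$n)
  B$state[[nm]] <- value
  nm
}

.he_init <- function(n, fan_in) stats::rnorm(n, 0, sqrt(2 / fan_in))

# ---- layer constructors --------------------------------------------------

.layer_conv <- function(B, k, cin, cout) {
  W <- matrix(.he_init(k * cin * cout, k * cin), k * cin, cout)
  list(type = "conv", k = k, cin = cin, cout = cout,
       W = .nn_param(B, W), b = .nn_param(B, numeric(cout)))
}

.layer_dense <- function(B, din, dout) {
  W <- matrix(.he_init(din * dout, din), din, dout)
  list(type = "dense", din = din, dout = dout,
       W = .nn_param(B, W), b = .nn_param(B, numeric(dout)))
}

.layer_bn <- function(B, ch) {
  list(type = "bn", ch = ch, eps = 1e-5, momentum = 0.9,
       gamma = .nn_param(B, rep(1, ch)), beta = .nn_param(B, numeric(ch)),
       rmean = .nn_state(B, numeric(ch)), rvar = .nn_state(B, rep(1, ch)))
}

.layer_lrelu <- function(alpha = .LRELU_ALPHA) list(type = "lrelu", alpha = alpha)
.layer_pool <- function() list(type = "pool")
.layer_flatten <- function() list(type = "flatten")
.layer_gap <- function() list(type = "gap")
.layer_dropout <- function(rate) list(type = "dropout", rate = rate)
.layer_sigmoid <- function() list(type = "sigmoid")
.layer_upsample <- function(out_len) list(type = "upsample", out_len = out_len)
.layer_seq <- function(layers) list(type = "seq", layers = layers)

.layer_res_block <- function(B, k, cin, cout, dropout) {
  body <- .layer_seq(list(
    .layer_conv(B, k, cin, cout), .layer_bn(B, cout), .layer_lrelu(),
    .layer_dropout(dropout),
    .layer_conv(B, k, cout, cout), .layer_bn(B, cout)))
  list(type = "res_block", body = body,
       short = .layer_conv(B, 1, cin, cout), alpha = .LRELU_ALPHA)
}

.layer_rta_block <- function(B, k, cin, cout, len) {
  trunk <- .layer_seq(list(
    .layer_conv(B, k, cin, cout), .layer_bn(B, cout), .layer_lrelu(),
    .layer_conv(B, k, cout, cout), .layer_bn(B, cout), .layer_lrelu()))
  att <- .layer_seq(list(
    .layer_pool(),
    .layer_conv(B, k, cin, cout), .layer_bn(B, cout), .layer_lrelu(),
    .layer_conv(B, k, cout, cout),
    .layer_upsample(len),
    .layer_conv(B, 1, cout, cout),
    .layer_sigmoid()))
  list(type = "rta_block", trunk = trunk, att = att)
}

.layer_gru_bi <- function(B, din, h) {
  mk <- function(nr, nc) .nn_param(B, matrix(stats::rnorm(nr * nc, 0, sqrt(1 / nr)), nr, nc))
  dir <- function() list(
    Wz = mk(din, h), Wr = mk(din, h), Wh = mk(din, h),
    Uz = mk(h, h), Ur = mk(h, h), Uh = mk(h, h),
    bz = .nn_param(B, numeric(h)), br = .nn_param(B, numeric(h)),
    bh = .nn_param(B, numeric(h)))
  list(type = "gru_bi", din = din, h = h, fwd = dir(), bwd = dir())
}

.layer_attention <- function(B, din, datt = din) {
  list(type = "attention", din = din, datt = datt,
       Wa = .nn_param(B, matrix(stats::rnorm(din * datt, 0, sqrt(1 / din)), din, datt)),
       ba = .nn_param(B, numeric(datt)),
       va = .nn_param(B, stats::rnorm(datt, 0, sqrt(1 / datt))))
}

# ---- im2col convolution --------------------------------------------------

.conv_im2col <- function(x, k) {
  d <- dim(x)
  N <- d[1]; L <- d[2]; cin <- d[3]
  padL <- (k - 1L) %/% 2L
  xp <- array(0, c(N, L + k - 1L, cin))
  xp[, (padL + 1):(padL + L), ] <- x
  M <- matrix(0, N * L, k * cin)
  for (j in seq_len(k)) {
    seg <- xp[, j:(j + L - 1L), , drop = FALSE]
    dim(seg) <- c(N * L, cin)
    M[, ((j - 1L) * cin + 1L):(j * cin)] <- seg
  }
  M
}

.conv_col2im <- function(dM, k, N, L, cin) {
  padL <- (k - 1L) %/% 2L
  dxp <- array(0, c(N, L + k - 1L, cin))
  for (j in seq_len(k)) {
    dseg <- dM[, ((j - 1L) * cin + 1L):(j * cin), drop = FALSE]
    dim(dseg) <- c(N, L, cin)
    dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), , drop = FALSE] + dseg
  }
  dxp[, (padL + 1):(padL + L), , drop = FALSE]
}

# ---- forward / backward dispatch ----------------------------------------

.fwd <- function(layer, x, P, S, training) {
  switch(layer$type,
    seq = {
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        r <- .fwd(layer$layers[[i]], x, P, S, training)
        x <- r$y; caches[[i]] <- r$cache; S <- r$S
      }
      list(y = x, cache = caches, S = S)
    },
    conv = {
      d <- dim(x)
      M <- .conv_im2col(x, layer$k)
      y <- M %*% P[[layer$W]]
      y <- sweep(y, 2, P[[layer$b]], "+")
      dim(y) <- c(d[1], d[2], layer$cout)
      list(y = y, cache = list(M = M, dims = d), S = S)
    },
    dense = {
      y <- x %*% P[[layer$W]]
      y <- sweep(y, 2, P[[layer$b]], "+")
      list(y = y, cache = list(x = x), S = S)
    },
    lrelu = {
      y <- x
      neg <- x < 0
      y[neg] <- layer$alpha * x[neg]
      list(y = y, cache = list(neg = neg), S = S)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = list(y = y), S = S)
    },
    pool = {
      d <- dim(x)
      Lout <- d[2] %/% 2L
      if (Lout < 1) stop("input too short for max pooling")
      a <- x[, seq(1L, 2L * Lout, 2L), , drop = FALSE]
      b <- x[, seq(2L, 2L * Lout, 2L), , drop = FALSE]
      mask <- a >= b
      y <- pmax(a, b)
      list(y = y, cache = list(mask = mask, Lin = d[2]), S = S)
    },
    upsample = {
      d <- dim(x)
      src <- pmin(ceiling(seq_len(layer$out_len) / 2), d[2])
      y <- x[, src, , drop = FALSE]
      list(y = y, cache = list(src = src, Lin = d[2]), S = S)
    },
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(d[1], d[2] * d[3])
      list(y = y, cache = list(dims = d), S = S)
    },
    gap = {
      d <- dim(x)
      y <- colMeans(aperm(x, c(2, 1, 3)))
      dim(y) <- c(d[1], d[3])
      list(y = y, cache = list(dims = d), S = S)
    },
    bn = {
      d <- dim(x)
      xm <- x
      dim(xm) <- c(d[1] * d[2], d[3])
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        S[[layer$rmean]] <- layer$momentum * S[[layer$rmean]] + (1 - layer$momentum) * mu
        S[[layer$rvar]] <- layer$momentum * S[[layer$rvar]] + (1 - layer$momentum) * v
      } else {
        mu <- S[[layer$rmean]]
        v <- S[[layer$rvar]]
      }
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(sweep(xm, 2, mu, "-"), 2, invstd, "*")
      ym <- sweep(sweep(xhat, 2, P[[layer$gamma]], "*"), 2, P[[layer$beta]], "+")
      y <- ym
      dim(y) <- d
      list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d,
                               training = training), S = S)
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- (stats::runif(length(x)) < keep) / keep
        dim(mask) <- dim(x)
        list(y = x * mask, cache = list(mask = mask), S = S)
      } else {
        list(y = x, cache = list(mask = NULL), S = S)
      }
    },
    res_block = {
      rb <- .fwd(layer$body, x, P, S, training)
      rs <- .fwd(layer$short, x, P, rb$S, training)
      z <- rb$y + rs$y
      y <- z
      neg <- z < 0
      y[neg] <- layer$alpha * z[neg]
      list(y = y, cache = list(body = rb$cache, short = rs$cache, neg = neg),
           S = rs$S)
    },
    rta_block = {
      rt <- .fwd(layer$trunk, x, P, S, training)
      ra <- .fwd(layer$att, x, P, rt$S, training)
      y <- rt$y * (1 + ra$y)
      list(y = y, cache = list(trunk = rt$cache, att = ra$cache,
                               t_out = rt$y, a_out = ra$y), S = ra$S)
    },
    gru_bi = .gru_forward(layer, x, P, S),
    attention = {
      d <- dim(x)
      Hm <- x
      dim(Hm) <- c(d[1] * d[2], d[3])
      u <- tanh(sweep(Hm %*% P[[layer$Wa]], 2, P[[layer$ba]], "+"))
      e <- matrix(u %*% P[[layer$va]], d[1], d[2])
      e <- e - apply(e, 1, max)
      a <- exp(e)
      a <- a / rowSums(a)
      y <- matrix(0, d[1], d[3])
      for (t in seq_len(d[2])) y <- y + a[, t] * matrix(x[, t, ], d[1], d[3])
      list(y = y, cache = list(x = x, u = u, a = a, dims = d), S = S)
    },
    stop("unknown layer type: ", layer$type)
  )
}

.merge_grads <- function(a, b) c(a, b)

.bwd <- function(layer, cache, dy, P) {
  switch(layer$type,
    seq = {
      grads <- list()
      for (i in rev(seq_along(layer$layers))) {
        r <- .bwd(layer$layers[[i]], cache[[i]], dy, P)
        dy <- r$dx
        grads <- .merge_grads(grads, r$grads)
      }
      list(dx = dy, grads = grads)
    },
    conv = {
      d <- cache$dims
      dym <- dy
      dim(dym) <- c(d[1] * d[2], layer$cout)
      g <- list()
      g[[layer$W]] <- crossprod(cache$M, dym)
      g[[layer$b]] <- colSums(dym)
      dM <- tcrossprod(dym, P[[layer$W]])
      dx <- .conv_col2im(dM, layer$k, d[1], d[2], layer$cin)
      list(dx = dx, grads = g)
    },
    dense = {
      g <- list()
      g[[layer$W]] <- crossprod(cache$x, dy)
      g[[layer$b]] <- colSums(dy)
      list(dx = tcrossprod(dy, P[[layer$W]]), grads = g)
    },
    lrelu = {
      dx <- dy
      dx[cache$neg] <- layer$alpha * dy[cache$neg]
      list(dx = dx, grads = list())
    },
    sigmoid = {
      list(dx = dy * cache$y * (1 - cache$y), grads = list())
    },
    pool = {
      m <- cache$mask
      d <- dim(m)
      Lout <- d[2]
      dx <- array(0, c(d[1], cache$Lin, d[3]))
      dx[, seq(1L, 2L * Lout, 2L), ] <- dy * m
      dx[, seq(2L, 2L * Lout, 2L), ] <- dy * !m
      list(dx = dx, grads = list())
    },
    upsample = {
      d <- dim(dy)
      dx <- array(0, c(d[1], cache$Lin, d[3]))
      for (l in seq_along(cache$src)) {
        dx[, cache$src[l], ] <- dx[, cache$src[l], ] + dy[, l, ]
      }
      list(dx = dx, grads = list())
    },
    flatten = {
      dx <- dy
      dim(dx) <- cache$dims
      list(dx = dx, grads = list())
    },
    gap = {
      d <- cache$dims
      dx <- array(0, d)
      sc <- dy / d[2]
      for (l in seq_len(d[2])) dx[, l, ] <- sc
      list(dx = dx, grads = list())
    },
    bn = {
      d <- cache$dims
      m <- d[1] * d[2]
      dym <- dy
      dim(dym) <- c(m, d[3])
      g <- list()
      g[[layer$gamma]] <- colSums(dym * cache$xhat)
      g[[layer$beta]] <- colSums(dym)
      dxhat <- sweep(dym, 2, P[[layer$gamma]], "*")
      if (cache$training) {
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * cache$xhat)
        dxm <- sweep(dxhat, 2, s1 / m, "-") -
          sweep(cache$xhat, 2, s2 / m, "*")
        dxm <- sweep(dxm, 2, cache$invstd, "*")
      } else {
        dxm <- sweep(dxhat, 2, cache$invstd, "*")
      }
      dx <- dxm
      dim(dx) <- d
      list(dx = dx, grads = g)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = list())
      else list(dx = dy * cache$mask, grads = list())
    },
    res_block = {
      dz <- dy
      dz[cache$neg] <- layer$alpha * dy[cache$neg]
      rb <- .bwd(layer$body, cache$body, dz, P)
      rs <- .bwd(layer$short, cache$short, dz, P)
      list(dx = rb$dx + rs$dx, grads = .merge_grads(rb$grads, rs$grads))
    },
    rta_block = {
      dt <- dy * (1 + cache$a_out)
      da <- dy * cache$t_out
      rt <- .bwd(layer$trunk, cache$trunk, dt, P)
      ra <- .bwd(layer$att, cache$att, da, P)
      list(dx = rt$dx + ra$dx, grads = .merge_grads(rt$grads, ra$grads))
    },
    gru_bi = .gru_backward(layer, cache, dy, P),
    attention = {
      d <- cache$dims
      x <- cache$x
      a <- cache$a
      dH <- array(0, d)
      da <- matrix(0, d[1], d[2])
      for (t in seq_len(d[2])) {
        dH[, t, ] <- a[, t] * dy
        da[, t] <- rowSums(dy * matrix(x[, t, ], d[1], d[3]))
      }
      de <- a * (da - rowSums(a * da))
      dem <- as.vector(de)
      du <- outer(dem, P[[layer$va]])
      dpre <- du * (1 - cache$u^2)
      Hm <- x
      dim(Hm) <- c(d[1] * d[2], d[3])
      g <- list()
      g[[layer$va]] <- as.numeric(crossprod(cache$u, dem))
      g[[layer$Wa]] <- crossprod(Hm, dpre)
      g[[layer$ba]] <- colSums(dpre)
      dHm <- tcrossprod(dpre, P[[layer$Wa]])
      dim(dHm) <- d
      list(dx = dH + dHm, grads = g)
    },
    stop("unknown layer type: ", layer$type)
  )
}

# ---- GRU (bidirectional) -------------------------------------------------

.gru_dir_forward <- function(prm, x, P, reverse) {
  d <- dim(x)
  N <- d[1]; TT <- d[2]; H <- ncol(P[[prm$Uz]])
  ts <- if (reverse) rev(seq_len(TT)) else seq_len(TT)
  h <- matrix(0, N, H)
  hs <- array(0, c(N, TT, H))
  cache <- vector("list", TT)
  for (i in seq_along(ts)) {
    t <- ts[i]
    xt <- matrix(x[, t, ], N, d[3])
    az <- xt %*% P[[prm$Wz]] + h %*% P[[prm$Uz]]
    az <- sweep(az, 2, P[[prm$bz]], "+")
    ar <- xt %*% P[[prm$Wr]] + h %*% P[[prm$Ur]]
    ar <- sweep(ar, 2, P[[prm$br]], "+")
    z <- 1 / (1 + exp(-az))
    r <- 1 / (1 + exp(-ar))
    ah <- xt %*% P[[prm$Wh]] + (r * h) %*% P[[prm$Uh]]
    ah <- sweep(ah, 2, P[[prm$bh]], "+")
    hc <- tanh(ah)
    hnew <- (1 - z) * h + z * hc
    cache[[t]] <- list(xt = xt, hprev = h, z = z, r = r, hc = hc)
    h <- hnew
    hs[, t, ] <- h
  }
  list(hs = hs, cache = cache, ts = ts)
}

.gru_dir_backward <- function(prm, fwd_cache, dhs, P) {
  ts <- fwd_cache$ts
  cache <- fwd_cache$cache
  N <- nrow(cache[[ts[1]]]$hprev)
  H <- ncol(cache[[ts[1]]]$hprev)
  D <- ncol(cache[[ts[1]]]$xt)
  g <- list()
  zero <- function(nr, nc) matrix(0, nr, nc)
  dWz <- zero(D, H); dWr <- zero(D, H); dWh <- zero(D, H)
  dUz <- zero(H, H); dUr <- zero(H, H); dUh <- zero(H, H)
  dbz <- numeric(H); dbr <- numeric(H); dbh <- numeric(H)
  dx <- array(0, c(N, length(cache), D))
  dh_next <- zero(N, H)
  for (i in rev(seq_along(ts))) {
    t <- ts[i]
    cc <- cache[[t]]
    dh <- matrix(dhs[, t, ], N, H) + dh_next
    dz <- dh * (cc$hc - cc$hprev)
    dhc <- dh * cc$z
    dhprev <- dh * (1 - cc$z)
    dah <- dhc * (1 - cc$hc^2)
    dWh <- dWh + crossprod(cc$xt, dah)
    dUh <- dUh + crossprod(cc$r * cc$hprev, dah)
    dbh <- dbh + colSums(dah)
    drh <- tcrossprod(dah, P[[prm$Uh]])
    dr <- drh * cc$hprev
    dhprev <- dhprev + drh * cc$r
    daz <- dz * cc$z * (1 - cc$z)
    dar <- dr * cc$r * (1 - cc$r)
    dWz <- dWz + crossprod(cc$xt, daz)
    dUz <- dUz + crossprod(cc$hprev, daz)
    dbz <- dbz + colSums(daz)
    dWr <- dWr + crossprod(cc$xt, dar)
    dUr <- dUr + crossprod(cc$hprev, dar)
    dbr <- dbr + colSums(dar)
    dhprev <- dhprev + tcrossprod(daz, P[[prm$Uz]]) +
      tcrossprod(dar, P[[prm$Ur]])
    dx[, t, ] <- daz %*% t(P[[prm$Wz]]) + dar %*% t(P[[prm$Wr]]) +
      dah %*% t(P[[prm$Wh]])
    dh_next <- dhprev
  }
  g[[prm$Wz]] <- dWz; g[[prm$Wr]] <- dWr; g[[prm$Wh]] <- dWh
  g[[prm$Uz]] <- dUz; g[[prm$Ur]] <- dUr; g[[prm$Uh]] <- dUh
  g[[prm$bz]] <- dbz; g[[prm$br]] <- dbr; g[[prm$bh]] <- dbh
  list(dx = dx, grads = g)
}

.gru_forward <- function(layer, x, P, S) {
  f <- .gru_dir_forward(layer$fwd, x, P, reverse = FALSE)
  b <- .gru_dir_forward(layer$bwd, x, P, reverse = TRUE)
  d <- dim(x)
  y <- array(0, c(d[1], d[2], 2L * layer$h))
  y[, , 1:layer$h] <- f$hs
  y[, , (layer$h + 1):(2 * layer$h)] <- b$hs
  list(y = y, cache = list(f = f, b = b, dims = d), S = S)
}

.gru_backward <- function(layer, cache, dy, P) {
  h <- layer$h
  df <- .gru_dir_backward(layer$fwd, cache$f,
                          dy[, , 1:h, drop = FALSE], P)
  db <- .gru_dir_backward(layer$bwd, cache$b,
                          dy[, , (h + 1):(2 * h), drop = FALSE], P)
  list(dx = df$dx + db$dx, grads = .merge_grads(df$grads, db$grads))
}

# ---- losses --------------------------------------------------------------

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Categorical cross-entropy loss
#'
#' @param prob Matrix of class probabilities (rows on the simplex).
#' @param labels Integer true labels in `1..C`.
#' @param clamp Probability floor before the log (guards `log(0)`).
#' @return Mean negative log-probability of the true classes.
#' @export
cross_entropy_loss <- function(prob, labels, clamp = 1e-7) {
  p <- pmax(prob[cbind(seq_along(labels), labels)], clamp)
  mean(-log(p))
}

#' Exponential-nonlinearity (EN) loss
#'
#' A cross-entropy variant that re-weights hard examples through an
#' exponential nonlinearity: `mean(exp(gamma * (1 - p_true)) - 1)`. It is
#' zero for perfect predictions, non-negative, and a monotone transform
#' of `-log p_true` that grows faster for badly classified examples,
#' which counteracts class imbalance. The default training loss remains
#' cross-entropy; this loss is opt-in per model spec.
#'
#' @inheritParams cross_entropy_loss
#' @param gamma Sharpness of the exponential re-weighting (> 0).
#' @return Mean EN loss.
#' @export
en_loss <- function(prob, labels, gamma = 2, clamp = 1e-7) {
  p <- pmax(prob[cbind(seq_along(labels), labels)], clamp)
  mean(exp(gamma * (1 - p)) - 1)
}

# loss value + gradient w.r.t. logits
.loss_grad <- function(logits, labels, loss = "cross_entropy", gamma = 2) {
  n <- nrow(logits)
  p <- .softmax(logits)
  idx <- cbind(seq_len(n), labels)
  if (loss == "cross_entropy") {
    value <- cross_entropy_loss(p, labels)
    dz <- p
    dz[idx] <- dz[idx] - 1
    dz <- dz / n
  } else {
    value <- en_loss(p, labels, gamma = gamma)
    pt <- pmax(p[idx], 1e-7)
    dLdp <- matrix(0, n, ncol(p))
    dLdp[idx] <- -gamma * exp(gamma * (1 - pt)) / n
    dz <- p * (dLdp - rowSums(dLdp * p))
  }
  list(value = value, dlogits = dz, prob = p)
}

# ---- optimizer -----------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}
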