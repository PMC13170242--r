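# Minimal dense/convolutional/recurrent network engine used by the
# dual-branch gait classifier. Pure R on BLAS matrix products; batch tensors
# are arrays [batch, time, channel]. Every layer has an explicit
# forward/backward pair, verified against finite differences in the test
# suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Valid 1-D convolution as a sum of per-tap matrix products:
# y[, t, ] = sum_j x[, t+j-1, ] %*% W_j, with W row-blocked by tap.
conv1d_forward <- function(x, W, b, k) {
  d <- dim(x); B <- d[1]; T <- d[2]; Cin <- d[3]
  To <- T - k + 1
  slices <- vector("list", k)
  y <- matrix(b, B * To, ncol(W), byrow = TRUE)
  for (j in seq_len(k)) {
    sl <- x[, j:(j + To - 1), , drop = FALSE]
    dim(sl) <- c(B * To, Cin)
    slices[[j]] <- sl
    y <- y + sl %*% W[((j - 1) * Cin + 1):(j * Cin), , drop = FALSE]
  }
  dim(y) <- c(B, To, ncol(W))
  list(y = y, slices = slices,
       dims = c(B = B, T = T, Cin = Cin, To = To, k = k))
}

conv1d_backward <- function(dy, cache, W) {
  dm <- cache$dims
  B <- dm["B"]; T <- dm["T"]; Cin <- dm["Cin"]; To <- dm["To"]; k <- dm["k"]
  dy_mat <- dy; dim(dy_mat) <- c(B * To, ncol(W))
  dW <- matrix(0, nrow(W), ncol(W))
  db <- colSums(dy_mat)
  dx <- array(0, dim = c(B, T, Cin))
  for (j in seq_len(k)) {
    rows <- ((j - 1) * Cin + 1):(j * Cin)
    dW[rows, ] <- crossprod(cache$slices[[j]], dy_mat)
    sl <- dy_mat %*% t(W[rows, , drop = FALSE])
    dim(sl) <- c(B, To, Cin)
    dx[, j:(j + To - 1), ] <- dx[, j:(j + To - 1), , drop = FALSE] + sl
  }
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_backward <- function(dy, cache) dy * cache$mask

maxpool_forward <- function(x, w) {
  d <- dim(x); B <- d[1]; T <- d[2]; C <- d[3]
  To <- T %/% w
  y <- x[, seq(1, by = w, length.out = To), , drop = FALSE]
  arg <- array(1L, dim = c(B, To, C))
  if (w > 1) for (j in 2:w) {
    cand <- x[, seq(j, by = w, length.out = To), , drop = FALSE]
    upd <- cand > y
    y[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(y = y, arg = arg, w = w, T = T)
}

maxpool_backward <- function(dy, cache) {
  d <- dim(dy); B <- d[1]; To <- d[2]; C <- d[3]
  dx <- array(0, dim = c(B, cache$T, C))
  for (j in seq_len(cache$w)) {
    m <- cache$arg == j
    sl <- array(0, dim = d)
    sl[m] <- dy[m]
    dx[, seq(j, by = cache$w, length.out = To), ] <-
      dx[, seq(j, by = cache$w, length.out = To), , drop = FALSE] + sl
  }
  dx
}

bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  xm <- x; dim(xm) <- c(d[1] * d[2], C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
  }
  xhat <- sweep(sweep(xm, 2, mu), 2, sqrt(v + eps), "/")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(y) <- d
  list(y = y, xhat = xhat, mu = mu, v = v, eps = eps, dims = d,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, cache, gamma) {
  d <- cache$dims; N <- d[1] * d[2]
  dym <- dy; dim(dym) <- c(N, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, "*")
  inv_sd <- 1 / sqrt(cache$v + cache$eps)
  dx <- sweep(
    dxhat - matrix(colMeans(dxhat), N, d[3], byrow = TRUE) -
      sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*"),
    2, inv_sd, "*")
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

lstm_forward <- function(x, Wx, Wh, b) {
  d <- dim(x); B <- d[1]; T <- d[2]; D <- d[3]
  H <- ncol(Wh) / 4
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- vector("list", T)
  for (t in seq_len(T)) {
    xt <- x[, t, , drop = FALSE]; dim(xt) <- c(B, D)
    z <- xt %*% Wx + h %*% Wh
    z <- sweep(z, 2, b, "+")
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev_t <- h
    h <- o * tc
    steps[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, cc = cc, tc = tc, h_prev = h_prev_t)
  }
  list(h_last = h, steps = steps, dims = d, H = H)
}

lstm_backward <- function(dh_last, cache, Wx, Wh) {
  d <- cache$dims; B <- d[1]; T <- d[2]; D <- d[3]; H <- cache$H
  dWx <- matrix(0, D, 4 * H); dWh <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dx <- array(0, dim = d)
  dh <- dh_last; dc <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    s <- cache$steps[[t]]
    do_ <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dc <- dc * s$f
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_ * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dh <- dz %*% t(Wh)
    dx[, t, ] <- dz %*% t(Wx)
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

softmax_ce <- function(logits, y_int) {
  B <- nrow(logits)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(B), y_int)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, p = p, dlogits = dlogits / B)
}

init_mat <- function(nr, nc, scale) matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)

# Build initialized parameters for a given modality/architecture.
init_network <- function(arch) {
  p <- list()
  k <- arch$kernel
  if (arch$use_plantar) {
    f <- arch$plantar_filters
    p$pW1 <- init_mat(k * 1, f[1], sqrt(2 / (k * 1)))
    p$pb1 <- numeric(f[1])
    p$pg1 <- rep(1, f[1]); p$pB1 <- numeric(f[1])
    p$pW2 <- init_mat(k * f[1], f[2], sqrt(2 / (k * f[1])))
    p$pb2 <- numeric(f[2])
    p$pg2 <- rep(1, f[2]); p$pB2 <- numeric(f[2])
  }
  if (arch$use_strain) {
    f <- arch$strain_filters
    p$sW1 <- init_mat(k * 3, f[1], sqrt(2 / (k * 3)))
    p$sb1 <- numeric(f[1])
    p$sW2 <- init_mat(k * f[1], f[2], sqrt(2 / (k * f[1])))
    p$sb2 <- numeric(f[2])
    p$sW3 <- init_mat(k * f[2], f[3], sqrt(2 / (k * f[2])))
    p$sb3 <- numeric(f[3])
  }
  H <- arch$lstm_hidden; D <- arch$lstm_input
  sc <- sqrt(1 / H)
  p$lWx <- init_mat(D, 4 * H, sc)
  p$lWh <- init_mat(H, 4 * H, sc)
  p$lb <- numeric(4 * H)
  p$lb[(H + 1):(2 * H)] <- 1  # forget-gate bias init
  p$fW <- init_mat(H, arch$n_classes, sqrt(2 / H))
  p$fb <- numeric(arch$n_classes)
  p
}

init_bn_state <- function(arch) {
  st <- list()
  if (arch$use_plantar) {
    st$m1 <- numeric(arch$plantar_filters[1])
    st$v1 <- rep(1, arch$plantar_filters[1])
    st$m2 <- numeric(arch$plantar_filters[2])
    st$v2 <- rep(1, arch$plantar_filters[2])
  }
  st
}

# Full forward pass. x is [B, T, C] with the modality's channels.
net_forward <- function(p, arch, x, bn_state, training = FALSE,
                        drop_mask = NULL) {
  caches <- list()
  branches <- list()
  if (arch$use_plantar) {
    xp <- x[, , arch$plantar_idx, drop = FALSE]
    c1 <- conv1d_forward(xp, p$pW1, p$pb1, arch$kernel)
    b1 <- bn_forward(c1$y, p$pg1, p$pB1, bn_state$m1, bn_state$v1, training)
    if (training) { bn_state$m1 <- b1$run_mean; bn_state$v1 <- b1$run_var }
    r1 <- relu_forward(b1$y)
    m1 <- maxpool_forward(r1$y, 2L)
    c2 <- conv1d_forward(m1$y, p$pW2, p$pb2, arch$kernel)
    b2 <- bn_forward(c2$y, p$pg2, p$pB2, bn_state$m2, bn_state$v2, training)
    if (training) { bn_state$m2 <- b2$run_mean; bn_state$v2 <- b2$run_var }
    r2 <- relu_forward(b2$y)
    m2 <- maxpool_forward(r2$y, 2L)
    caches$plantar <- list(c1 = c1, b1 = b1, r1 = r1, m1 = m1,
                           c2 = c2, b2 = b2, r2 = r2, m2 = m2)
    branches$plantar <- m2$y
  }
  if (arch$use_strain) {
    xs <- x[, , arch$strain_idx, drop = FALSE]
    c1 <- conv1d_forward(xs, p$sW1, p$sb1, arch$kernel)
    r1 <- relu_forward(c1$y)
    c2 <- conv1d_forward(r1$y, p$sW2, p$sb2, arch$kernel)
    r2 <- relu_forward(c2$y)
    c3 <- conv1d_forward(r2$y, p$sW3, p$sb3, arch$kernel)
    r3 <- relu_forward(c3$y)
    m3 <- maxpool_forward(r3$y, 4L)
    caches$strain <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                          c3 = c3, r3 = r3, m3 = m3)
    branches$strain <- m3$y
  }
  # temporal alignment + channel concatenation
  lens <- vapply(branches, function(b) dim(b)[2], numeric(1))
  Tc <- min(lens)
  feats <- lapply(branches, function(b) b[, seq_len(Tc), , drop = FALSE])
  z <- if (length(feats) == 1) feats[[1]] else {
    d1 <- dim(feats[[1]]); d2 <- dim(feats[[2]])
    out <- array(0, dim = c(d1[1], Tc, d1[3] + d2[3]))
    out[, , seq_len(d1[3])] <- feats[[1]]
    out[, , d1[3] + seq_len(d2[3])] <- feats[[2]]
    out
  }
  caches$branch_lens <- lens; caches$Tc <- Tc
  ls <- lstm_forward(z, p$lWx, p$lWh, p$lb)
  caches$lstm <- ls
  h <- ls$h_last
  if (training && arch$dropout > 0) {
    if (is.null(drop_mask))
      drop_mask <- matrix(stats::rbinom(length(h), 1, 1 - arch$dropout) /
                            (1 - arch$dropout), nrow(h), ncol(h))
    h <- h * drop_mask
  }
  caches$drop_mask <- drop_mask
  caches$h <- h
  logits <- sweep(h %*% p$fW, 2, p$fb, "+")
  list(logits = logits, caches = caches, bn_state = bn_state)
}

net_backward <- function(p, arch, x, fw, dlogits) {
  ca <- fw$caches
  g <- list()
  g$fW <- crossprod(ca$h, dlogits)
  g$fb <- colSums(dlogits)
  dh <- dlogits %*% t(p$fW)
  if (!is.null(ca$drop_mask)) dh <- dh * ca$drop_mask
  lb <- lstm_backward(dh, ca$lstm, p$lWx, p$lWh)
  g$lWx <- lb$dWx; g$lWh <- lb$dWh; g$lb <- lb$db
  dz <- lb$dx
  Tc <- ca$Tc
  split_d <- list()
  if (arch$use_plantar && arch$use_strain) {
    np <- dim(ca$plantar$m2$y)[3]
    split_d$plantar <- dz[, , seq_len(np), drop = FALSE]
    split_d$strain <- dz[, , np + seq_len(dim(dz)[3] - np), drop = FALSE]
  } else if (arch$use_plantar) split_d$plantar <- dz else split_d$strain <- dz

  pad_time <- function(dzb, full_len) {
    if (dim(dzb)[2] == full_len) return(dzb)
    out <- array(0, dim = c(dim(dzb)[1], full_len, dim(dzb)[3]))
    out[, seq_len(dim(dzb)[2]), ] <- dzb
    out
  }
  if (arch$use_plantar) {
    cp <- ca$plantar
    d2 <- maxpool_backward(pad_time(split_d$plantar, dim(cp$m2$y)[2]), cp$m2)
    d2 <- relu_backward(d2, cp$r2)
    bb2 <- bn_backward(d2, cp$b2, p$pg2)
    g$pg2 <- bb2$dgamma; g$pB2 <- bb2$dbeta
    cc2 <- conv1d_backward(bb2$dx, cp$c2, p$pW2)
    g$pW2 <- cc2$dW; g$pb2 <- cc2$db
    d1 <- maxpool_backward(cc2$dx, cp$m1)
    d1 <- relu_backward(d1, cp$r1)
    bb1 <- bn_backward(d1, cp$b1, p$pg1)
    g$pg1 <- bb1$dgamma; g$pB1 <- bb1$dbeta
    cc1 <- conv1d_backward(bb1$dx, cp$c1, p$pW1)
    g$pW1 <- cc1$dW; g$pb1 <- cc1$db
  }
  if (arch$use_strain) {
    cs <- ca$strain
    d3 <- maxpool_backward(pad_time(split_d$strain, dim(cs$m3$y)[2]), cs$m3)
    d3 <- relu_backward(d3, cs$r3)
    cc3 <- conv1d_backward(d3, cs$c3, p$sW3)
    g$sW3 <- cc3$dW; g$sb3 <- cc3$db
    d2 <- relu_backward(cc3$dx, cs$r2)
    cc2 <- conv1d_backward(d2, cs$c2, p$sW2)
    g$sW2 <- cc2$dW; g$sb2 <- cc2$db
    d1 <- relu_backward(cc2$dx, cs$r1)
    cc1 <- conv1d_backward(d1, cs$c1, p$sW1)
    g$sW1 <- cc1$dW; g$sb1 <- cc1$db
  }
  g
}

# Parameters that receive L2 weight decay (weight matrices only).
decayed_params <- function() c("pW1", "pW2", "sW1", "sW2", "sW3",
                               "lWx", "lWh", "fW")

adam_step <- function(p, g, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  decay <- decayed_params()
  for (nm in names(g)) {
    gr <- g[[nm]]
    if (nm %in% decay && wd > 0) gr <- gr + wd * p[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gr * 0
      state$v[[nm]] <- gr * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

# Architecture descriptor derived from a model_config + modality + data shape.
build_arch <- function(config, modality, n_channels, n_classes) {
  use_plantar <- modality %in% c("plantar_only", "fused")
  use_strain <- modality %in% c("strain_only", "fused")
  if (modality == "plantar_only") {
    plantar_idx <- 1L; strain_idx <- integer(0)
    stopifnot(n_channels >= 1)
  } else if (modality == "strain_only") {
    plantar_idx <- integer(0)
    strain_idx <- if (n_channels == 3) 1:3 else 2:4
  } else {
    stopifnot(n_channels == 4)
    plantar_idx <- 1L; strain_idx <- 2:4
  }
  lstm_input <- (if (use_plantar) config$plantar_filters[2] else 0) +
    (if (use_strain) config$strain_filters[3] else 0)
  list(kernel = config$kernel,
       plantar_filters = config$plantar_filters,
       strain_filters = config$strain_filters,
       lstm_hidden = config$lstm_hidden,
       lstm_input = lstm_input,
       dropout = config$dropout,
       n_classes = n_classes,
       use_plantar = use_plantar, use_strain = use_strain,
       plantar_idx = plantar_idx, strain_idx = strain_idx)
}

# Train one network; x [N,T,C], y integer labels 1..K. Validation data used
# for early stopping.
train_network <- function(x, y, x_val, y_val, config, modality, n_classes,
                          seed) {
  with_seed(seed, {
    arch <- build_arch(config, modality, dim(x)[3], n_classes)
    p <- init_network(arch)
    bn <- init_bn_state(arch)
    opt <- list(t = 0, m = list(), v = list())
    N <- dim(x)[1]
    best <- list(loss = Inf, p = p, bn = bn, epoch = 0)
    wait <- 0
    history <- numeric(0)
    for (epoch in seq_len(config$max_epochs)) {
      lr <- config$learning_rate *
        config$lr_decay_factor^((epoch - 1) %/% config$lr_decay_every)
      ord <- sample.int(N)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, N, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, N)]
        if (length(idx) < 2) next  # batch norm needs > 1 sample
        xb <- x[idx, , , drop = FALSE]
        fw <- net_forward(p, arch, xb, bn, training = TRUE)
        bn <- fw$bn_state
        sm <- softmax_ce(fw$logits, y[idx])
        g <- net_backward(p, arch, xb, fw, sm$dlogits)
        up <- adam_step(p, g, opt, lr, config$weight_decay)
        p <- up$p; opt <- up$state
        ep_loss <- ep_loss + sm$loss; nb <- nb + 1
      }
      history <- c(history, ep_loss / max(nb, 1))
      # early stopping on validation loss
      if (length(y_val) > 0) {
        vl <- net_loss(p, arch, bn, x_val, y_val)
      } else {
        vl <- ep_loss / max(nb, 1)
      }
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, p = p, bn = bn, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= config$early_stop_patience) break
      }
    }
    structure(list(params = best$p, bn_state = best$bn, arch = arch,
                   config = config, modality = modality,
                   n_classes = n_classes, train_loss = history,
                   best_epoch = best$epoch, val_loss = best$loss),
              class = "cnn_lstm_model")
  })
}

net_loss <- function(p, arch, bn, x, y) {
  fw <- net_forward(p, arch, x, bn, training = FALSE)
  softmax_ce(fw$logits, y)$loss
}

#' @export
print.cnn_lstm_model <- function(x, ...) {
  cat(sprintf("<cnn_lstm_model> modality %s, %d classes, LSTM hidden %d, best epoch %d\n",
              x$modality, x$n_classes, x$arch$lstm_hidden, x$best_epoch))
  invisible(x)
}

#' Predict class probabilities / labels for an array of windows
#'
#' @param model A trained `cnn_lstm_model`.
#' @param x Array of windows `[n, window_len, n_channels]` with the
#'   modality's channel layout.
#' @param type `"class"` (integer labels 1..K) or `"prob"`.
#' @return Integer class indices or a probability matrix.
#' @export
predict_windows <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "cnn_lstm_model"))
  fw <- net_forward(model$params, model$arch, x, model$bn_state,
                    training = FALSE)
  e <- exp(fw$logits - apply(fw$logits, 1, max))
  prob <- e / rowSums(e)
  if (type == "prob") prob else max.col(prob, ties.method = "first")
}
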