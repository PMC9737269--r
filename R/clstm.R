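# Convolutional LSTM for raw EEG windows.
#
# Architecture (defaults): 1D conv (64 filters, size 10, ReLU) -> max-pool 3
# -> 1D conv (128 filters, size 5, ReLU) -> max-pool 3 -> LSTM (256 units,
# last hidden state) -> dense 256 (ReLU) -> dense 128 (ReLU) -> dense 1
# (sigmoid), trained with binary cross-entropy and Adam at initial learning
# rate 1e-3. Convolutions are stride 1 without padding; pooling stride
# equals the pool size. Implemented directly on BLAS matrix ops (im2col
# convolutions, full BPTT) so training is exactly reproducible from a seed.

.glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

#' Build an untrained convolutional-LSTM network
#'
#' @param n_channels Input channels (14 for the standard layout).
#' @param n_samples Input samples per window (2560 = 20 s at 128 Hz).
#' @param conv_filters,kernel_sizes Filter counts and kernel lengths of the
#'   two 1D convolution layers.
#' @param pool Max-pooling size (= stride) after each convolution.
#' @param lstm_units LSTM hidden units.
#' @param dense Sizes of the two hidden dense layers.
#' @param seed Seed for Glorot-uniform weight initialisation.
#' @return A list of class `eeg_clstm` with `params`, `dims` and `config`.
#' @export
clstm_build <- function(n_channels = 14, n_samples = 2560,
                        conv_filters = c(64, 128), kernel_sizes = c(10, 5),
                        pool = 3, lstm_units = 256, dense = c(256, 128),
                        seed = 0) {
  t1 <- n_samples - kernel_sizes[1] + 1L
  p1 <- t1 %/% pool
  t2 <- p1 - kernel_sizes[2] + 1L
  p2 <- t2 %/% pool
  if (p2 < 1) rlang::abort("input too short for the conv/pool stack")
  set.seed(seed)
  f1 <- conv_filters[1]; f2 <- conv_filters[2]
  k1 <- kernel_sizes[1]; k2 <- kernel_sizes[2]
  h <- lstm_units
  params <- list(
    W1 = matrix(.glorot(k1 * n_channels, f1, k1 * n_channels * f1),
                k1 * n_channels, f1),
    b1 = numeric(f1),
    W2 = matrix(.glorot(k2 * f1, f2, k2 * f1 * f2), k2 * f1, f2),
    b2 = numeric(f2),
    Wx = matrix(.glorot(f2, h, f2 * 4 * h), f2, 4 * h),
    Wh = matrix(.glorot(h, h, h * 4 * h), h, 4 * h),
    bl = c(numeric(h), rep(1, h), numeric(2 * h)),  # forget bias 1
    W4 = matrix(.glorot(h, dense[1], h * dense[1]), h, dense[1]),
    b4 = numeric(dense[1]),
    W5 = matrix(.glorot(dense[1], dense[2], dense[1] * dense[2]),
                dense[1], dense[2]),
    b5 = numeric(dense[2]),
    W6 = matrix(.glorot(dense[2], 1, dense[2]), dense[2], 1),
    b6 = 0
  )
  structure(list(
    params = params,
    dims = list(t1 = t1, p1 = p1, t2 = t2, p2 = p2),
    config = list(n_channels = n_channels, n_samples = n_samples,
                  conv_filters = conv_filters, kernel_sizes = kernel_sizes,
                  pool = pool, lstm_units = lstm_units, dense = dense,
                  seed = seed)
  ), class = "eeg_clstm")
}

#' Per-layer parameter counts of a CLSTM
#'
#' @param net An `eeg_clstm`.
#' @return Tibble `layer`, `n_params` (weights + biases per layer).
#' @export
clstm_parameter_counts <- function(net) {
  p <- net$params
  tibble::tibble(
    layer = c("conv1", "conv2", "lstm", "dense1", "dense2", "output"),
    n_params = c(length(p$W1) + length(p$b1),
                 length(p$W2) + length(p$b2),
                 length(p$Wx) + length(p$Wh) + length(p$bl),
                 length(p$W4) + length(p$b4),
                 length(p$W5) + length(p$b5),
                 length(p$W6) + length(p$b6))
  )
}

# im2col: (B,T,C) -> (B*T2, K*C) with T2 = T-K+1
.im2col <- function(a, k) {
  d <- dim(a); b <- d[1]; t <- d[2]; cc <- d[3]
  t2 <- t - k + 1L
  out <- matrix(0, b * t2, k * cc)
  for (dt in seq_len(k)) {
    blk <- a[, dt:(dt + t2 - 1L), , drop = FALSE]
    dim(blk) <- c(b * t2, cc)
    out[, ((dt - 1L) * cc + 1L):(dt * cc)] <- blk
  }
  out
}

.col2im <- function(dcol, b, t, cc, k) {
  t2 <- t - k + 1L
  da <- array(0, c(b, t, cc))
  for (dt in seq_len(k)) {
    blk <- dcol[, ((dt - 1L) * cc + 1L):(dt * cc), drop = FALSE]
    dim(blk) <- c(b, t2, cc)
    da[, dt:(dt + t2 - 1L), ] <- da[, dt:(dt + t2 - 1L), ] + blk
  }
  da
}

.pool3_forward <- function(a, pool) {
  d <- dim(a); b <- d[1]; t <- d[2]; cc <- d[3]
  t3 <- t %/% pool
  a3 <- a[, seq_len(pool * t3), , drop = FALSE]
  dim(a3) <- c(b, pool, t3, cc)
  slices <- lapply(seq_len(pool), function(j) {
    s <- a3[, j, , , drop = FALSE]; dim(s) <- c(b, t3, cc); s
  })
  out <- Reduce(pmax, slices)
  # argmax mask, first maximum wins
  taken <- array(FALSE, c(b, t3, cc))
  masks <- vector("list", pool)
  for (j in seq_len(pool)) {
    m <- (slices[[j]] == out) & !taken
    taken <- taken | m
    masks[[j]] <- m
  }
  list(out = out, masks = masks, t = t)
}

.pool3_backward <- function(dout, cache, pool) {
  d <- dim(dout); b <- d[1]; t3 <- d[2]; cc <- d[3]
  da3 <- array(0, c(b, pool, t3, cc))
  for (j in seq_len(pool)) {
    da3[, j, , ] <- dout * cache$masks[[j]]
  }
  dim(da3) <- c(b, pool * t3, cc)
  if (pool * t3 < cache$t) {
    da <- array(0, c(b, cache$t, cc))
    da[, seq_len(pool * t3), ] <- da3
    da
  } else da3
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass; returns probabilities, plus caches when `cache = TRUE`.
.clstm_fwd <- function(net, x, cache = FALSE) {
  p <- net$params; cfg <- net$config
  d <- dim(x)
  if (length(d) != 3 || d[2] != cfg$n_samples || d[3] != cfg$n_channels) {
    rlang::abort("input must be a (batch, samples, channels) array matching the build shape")
  }
  b <- d[1]; k1 <- cfg$kernel_sizes[1]; k2 <- cfg$kernel_sizes[2]
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
  h <- cfg$lstm_units; pool <- cfg$pool

  col1 <- .im2col(x, k1)
  z1 <- col1 %*% p$W1
  z1 <- sweep(z1, 2, p$b1, "+")
  a1 <- pmax(z1, 0); dim(a1) <- c(b, net$dims$t1, f1)
  pc1 <- .pool3_forward(a1, pool)

  col2 <- .im2col(pc1$out, k2)
  z2 <- col2 %*% p$W2
  z2 <- sweep(z2, 2, p$b2, "+")
  a2 <- pmax(z2, 0); dim(a2) <- c(b, net$dims$t2, f2)
  pc2 <- .pool3_forward(a2, pool)

  tt <- net$dims$p2
  hs <- if (cache) array(0, c(b, tt, h)) else NULL
  gi <- gf <- gg <- go <- cs <- th <- if (cache) array(0, c(b, tt, h)) else NULL
  hprev <- matrix(0, b, h); cprev <- matrix(0, b, h)
  for (t in seq_len(tt)) {
    xt <- pc2$out[, t, , drop = FALSE]; dim(xt) <- c(b, f2)
    g <- xt %*% p$Wx + hprev %*% p$Wh
    g <- sweep(g, 2, p$bl, "+")
    i_ <- .sigmoid(g[, 1:h, drop = FALSE])
    f_ <- .sigmoid(g[, (h + 1):(2 * h), drop = FALSE])
    g_ <- tanh(g[, (2 * h + 1):(3 * h), drop = FALSE])
    o_ <- .sigmoid(g[, (3 * h + 1):(4 * h), drop = FALSE])
    cprev <- f_ * cprev + i_ * g_
    tc <- tanh(cprev)
    hprev <- o_ * tc
    if (cache) {
      gi[, t, ] <- i_; gf[, t, ] <- f_; gg[, t, ] <- g_; go[, t, ] <- o_
      cs[, t, ] <- cprev; th[, t, ] <- tc; hs[, t, ] <- hprev
    }
  }
  z4 <- sweep(hprev %*% p$W4, 2, p$b4, "+"); a4 <- pmax(z4, 0)
  z5 <- sweep(a4 %*% p$W5, 2, p$b5, "+"); a5 <- pmax(z5, 0)
  z6 <- a5 %*% p$W6 + p$b6
  prob <- as.vector(.sigmoid(z6))
  if (!cache) return(prob)
  list(prob = prob, col1 = col1, z1pos = z1 > 0, pc1 = pc1,
       col2 = col2, z2pos = z2 > 0, pc2 = pc2,
       gi = gi, gf = gf, gg = gg, go = go, cs = cs, th = th, hs = hs,
       hT = hprev, z4pos = z4 > 0, a4 = a4, z5pos = z5 > 0, a5 = a5)
}

# Backward pass for binary cross-entropy; returns gradients by param name.
.clstm_bwd <- function(net, x, y, fw) {
  p <- net$params; cfg <- net$config
  b <- dim(x)[1]; h <- cfg$lstm_units
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
  k1 <- cfg$kernel_sizes[1]; k2 <- cfg$kernel_sizes[2]
  pool <- cfg$pool; tt <- net$dims$p2

  dz6 <- matrix((fw$prob - y) / b, b, 1)
  gW6 <- crossprod(fw$a5, dz6); gb6 <- sum(dz6)
  da5 <- dz6 %*% t(p$W6)
  dz5 <- da5 * fw$z5pos
  gW5 <- crossprod(fw$a4, dz5); gb5 <- colSums(dz5)
  da4 <- dz5 %*% t(p$W5)
  dz4 <- da4 * fw$z4pos
  gW4 <- crossprod(fw$hT, dz4); gb4 <- colSums(dz4)
  dh <- dz4 %*% t(p$W4)

  gWx <- matrix(0, f2, 4 * h); gWh <- matrix(0, h, 4 * h); gbl <- numeric(4 * h)
  dx_lstm <- array(0, c(b, tt, f2))
  dc <- matrix(0, b, h)
  for (t in rev(seq_len(tt))) {
    i_ <- fw$gi[, t, , drop = FALSE]; dim(i_) <- c(b, h)
    f_ <- fw$gf[, t, , drop = FALSE]; dim(f_) <- c(b, h)
    g_ <- fw$gg[, t, , drop = FALSE]; dim(g_) <- c(b, h)
    o_ <- fw$go[, t, , drop = FALSE]; dim(o_) <- c(b, h)
    tc <- fw$th[, t, , drop = FALSE]; dim(tc) <- c(b, h)
    cp <- if (t > 1) {
      v <- fw$cs[, t - 1, , drop = FALSE]; dim(v) <- c(b, h); v
    } else matrix(0, b, h)
    hp <- if (t > 1) {
      v <- fw$hs[, t - 1, , drop = FALSE]; dim(v) <- c(b, h); v
    } else matrix(0, b, h)
    dct <- dc + dh * o_ * (1 - tc^2)
    dzi <- dct * g_ * i_ * (1 - i_)
    dzf <- dct * cp * f_ * (1 - f_)
    dzg <- dct * i_ * (1 - g_^2)
    dzo <- dh * tc * o_ * (1 - o_)
    dg <- cbind(dzi, dzf, dzg, dzo)
    xt <- fw$pc2$out[, t, , drop = FALSE]; dim(xt) <- c(b, f2)
    gWx <- gWx + crossprod(xt, dg)
    gWh <- gWh + crossprod(hp, dg)
    gbl <- gbl + colSums(dg)
    dx_lstm[, t, ] <- dg %*% t(p$Wx)
    dh <- dg %*% t(p$Wh)
    dc <- dct * f_
  }

  da2 <- .pool3_backward(dx_lstm, fw$pc2, pool)
  dim(da2) <- c(b * net$dims$t2, f2)
  dz2 <- da2 * fw$z2pos
  gW2 <- crossprod(fw$col2, dz2); gb2 <- colSums(dz2)
  dcol2 <- dz2 %*% t(p$W2)
  dp1 <- .col2im(dcol2, b, net$dims$p1, f1, k2)
  da1 <- .pool3_backward(dp1, fw$pc1, pool)
  dim(da1) <- c(b * net$dims$t1, f1)
  dz1 <- da1 * fw$z1pos
  gW1 <- crossprod(fw$col1, dz1); gb1 <- colSums(dz1)

  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       Wx = gWx, Wh = gWh, bl = gbl,
       W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5, W6 = gW6, b6 = gb6)
}

.bce <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

#' Forward pass of a CLSTM
#'
#' @param net An `eeg_clstm`.
#' @param x Array `(batch, samples, channels)` matching the build shape.
#' @return Vector of positive-class probabilities in (0, 1).
#' @export
clstm_forward <- function(net, x) .clstm_fwd(net, x, cache = FALSE)

#' Train a CLSTM with Adam on binary cross-entropy
#'
#' Minibatch Adam (beta1 = 0.9, beta2 = 0.999) at the configured initial
#' learning rate. Training stops early once the training F1 reaches
#' `early_stop_f1`.
#'
#' @param net An `eeg_clstm` from [clstm_build()].
#' @param x Training array `(batch, samples, channels)`.
#' @param y Integer 0/1 labels (1 = positive/"high").
#' @param epochs,batch_size,lr Training schedule.
#' @param seed Seed for minibatch shuffling.
#' @param early_stop_f1 Stop when the training F1 reaches this value.
#' @param verbose Print per-epoch loss/F1.
#' @return The trained `eeg_clstm`, with a `history` tibble (epoch, loss,
#'   train F1) attached.
#' @export
clstm_train <- function(net, x, y, epochs = 30, batch_size = 32, lr = 1e-3,
                        seed = 0, early_stop_f1 = 0.995, verbose = FALSE) {
  stopifnot(length(y) == dim(x)[1], all(y %in% c(0, 1)))
  set.seed(seed + 1L)
  n <- dim(x)[1]
  batch_size <- min(batch_size, n)
  m <- lapply(net$params, function(w) w * 0)
  v <- lapply(net$params, function(w) w * 0)
  step <- 0
  hist <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (s in seq(1, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      xb <- x[idx, , , drop = FALSE]
      yb <- y[idx]
      fw <- .clstm_fwd(net, xb, cache = TRUE)
      gr <- .clstm_bwd(net, xb, yb, fw)
      losses <- c(losses, .bce(fw$prob, yb))
      step <- step + 1
      for (nm in names(net$params)) {
        m[[nm]] <- 0.9 * m[[nm]] + 0.1 * gr[[nm]]
        v[[nm]] <- 0.999 * v[[nm]] + 0.001 * gr[[nm]]^2
        mhat <- m[[nm]] / (1 - 0.9^step)
        vhat <- v[[nm]] / (1 - 0.999^step)
        net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    prob <- clstm_forward(net, x)
    pred <- ifelse(prob > 0.5, "high", "low")
    truth <- ifelse(y == 1, "high", "low")
    f1 <- suppressWarnings(prf1(confusion(pred, truth))$f1)
    hist[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses), f1 = f1)
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, train F1 %.3f",
                      ep, mean(losses), f1))
    }
    if (f1 >= early_stop_f1) break
  }
  net$history <- dplyr::bind_rows(hist)
  net
}

#' @export
print.eeg_clstm <- function(x, ...) {
  pc <- clstm_parameter_counts(x)
  cat("<eeg_clstm> input ", x$config$n_channels, " x ", x$config$n_samples,
      ", ", sum(pc$n_params), " parameters",
      if (!is.null(x$history)) paste0(", trained ", nrow(x$history), " epochs"),
      "\n", sep = "")
  invisible(x)
}
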