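# Minimal neural-network layer primitives (forward + backward), vectorised
# over batches via im2col-style gathers and BLAS matrix products. Tensor
# layouts: 2D conv activations are (H, W, C, N); 3D conv activations are
# (H, W, D, C, N); dense activations are (N, F) matrices.

nn_init_mat <- function(nr, nc, fan_in, init) {
  sd <- if (init == "unit") 1 else sqrt(2 / fan_in)
  matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

## ---- 2D convolution (3x3, stride 1, same padding) ----

conv2_layer <- function(cin, cout, k = 3L, init = "he") {
  list(type = "conv2", k = k, cin = cin, cout = cout,
       W = nn_init_mat(k * k * cin, cout, k * k * cin, init),
       b = numeric(cout))
}

conv2_forward <- function(layer, x, train = FALSE) {
  d <- dim(x)  # (H, W, Cin, N)
  H <- d[1]; W <- d[2]; cin <- d[3]; N <- d[4]
  k <- layer$k; p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * p, W + 2L * p, cin, N))
  xp[p + seq_len(H), p + seq_len(W), , ] <- x
  K <- k * k * cin
  xcol <- matrix(0, H * W * N, K)
  col <- 1L
  for (c in seq_len(cin)) {
    for (b in seq_len(k)) {
      for (a in seq_len(k)) {
        xcol[, col] <- xp[a:(a + H - 1L), b:(b + W - 1L), c, ]
        col <- col + 1L
      }
    }
  }
  y <- xcol %*% layer$W
  y <- sweep(y, 2L, layer$b, `+`)
  pre <- aperm(array(y, c(H, W, N, layer$cout)), c(1L, 2L, 4L, 3L))
  out <- pre
  out[out < 0] <- 0  # ReLU
  list(out = out, cache = list(xp = xp, mask = pre > 0, dims = d))
}

conv2_backward <- function(layer, dy, cache) {
  d <- cache$dims
  H <- d[1]; W <- d[2]; cin <- d[3]; N <- d[4]
  k <- layer$k; p <- (k - 1L) %/% 2L
  dy <- dy * cache$mask
  dymat <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), H * W * N, layer$cout)
  dW <- matrix(0, nrow(layer$W), layer$cout)
  db <- colSums(dymat)
  dxp <- array(0, dim(cache$xp))
  col <- 1L
  for (c in seq_len(cin)) {
    for (b in seq_len(k)) {
      for (a in seq_len(k)) {
        xslice <- as.vector(cache$xp[a:(a + H - 1L), b:(b + W - 1L), c, ,
                                     drop = FALSE])
        dW[col, ] <- as.vector(crossprod(matrix(xslice, ncol = 1L), dymat))
        acc <- as.vector(dxp[a:(a + H - 1L), b:(b + W - 1L), c, , drop = FALSE])
        dxp[a:(a + H - 1L), b:(b + W - 1L), c, ] <-
          acc + as.vector(dymat %*% layer$W[col, ])
        col <- col + 1L
      }
    }
  }
  list(dx = dxp[p + seq_len(H), p + seq_len(W), , , drop = FALSE],
       dW = dW, db = db)
}

## ---- 3D convolution (3x3x3, stride 1, same padding) ----

conv3_layer <- function(cin, cout, k = 3L, init = "he") {
  list(type = "conv3", k = k, cin = cin, cout = cout,
       W = nn_init_mat(k^3 * cin, cout, k^3 * cin, init),
       b = numeric(cout))
}

conv3_forward <- function(layer, x, train = FALSE) {
  d <- dim(x)  # (H, W, D, Cin, N)
  H <- d[1]; W <- d[2]; D <- d[3]; cin <- d[4]; N <- d[5]
  k <- layer$k; p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * p, W + 2L * p, D + 2L * p, cin, N))
  xp[p + seq_len(H), p + seq_len(W), p + seq_len(D), , ] <- x
  K <- k^3 * cin
  xcol <- matrix(0, H * W * D * N, K)
  col <- 1L
  for (c in seq_len(cin)) {
    for (e in seq_len(k)) {
      for (b in seq_len(k)) {
        for (a in seq_len(k)) {
          xcol[, col] <- xp[a:(a + H - 1L), b:(b + W - 1L), e:(e + D - 1L), c, ]
          col <- col + 1L
        }
      }
    }
  }
  y <- sweep(xcol %*% layer$W, 2L, layer$b, `+`)
  pre <- aperm(array(y, c(H, W, D, N, layer$cout)), c(1L, 2L, 3L, 5L, 4L))
  out <- pre
  out[out < 0] <- 0
  list(out = out, cache = list(xp = xp, mask = pre > 0, dims = d))
}

conv3_backward <- function(layer, dy, cache) {
  d <- cache$dims
  H <- d[1]; W <- d[2]; D <- d[3]; cin <- d[4]; N <- d[5]
  k <- layer$k; p <- (k - 1L) %/% 2L
  dy <- dy * cache$mask
  dymat <- matrix(aperm(dy, c(1L, 2L, 3L, 5L, 4L)), H * W * D * N, layer$cout)
  dW <- matrix(0, nrow(layer$W), layer$cout)
  db <- colSums(dymat)
  dxp <- array(0, dim(cache$xp))
  col <- 1L
  for (c in seq_len(cin)) {
    for (e in seq_len(k)) {
      for (b in seq_len(k)) {
        for (a in seq_len(k)) {
          xslice <- as.vector(cache$xp[a:(a + H - 1L), b:(b + W - 1L),
                                       e:(e + D - 1L), c, , drop = FALSE])
          dW[col, ] <- as.vector(crossprod(matrix(xslice, ncol = 1L), dymat))
          acc <- as.vector(dxp[a:(a + H - 1L), b:(b + W - 1L),
                               e:(e + D - 1L), c, , drop = FALSE])
          dxp[a:(a + H - 1L), b:(b + W - 1L), e:(e + D - 1L), c, ] <-
            acc + as.vector(dymat %*% layer$W[col, ])
          col <- col + 1L
        }
      }
    }
  }
  list(dx = dxp[p + seq_len(H), p + seq_len(W), p + seq_len(D), , , drop = FALSE],
       dW = dW, db = db)
}

## ---- max pooling (window 2, stride 2, floor; dims of size 1 pass through) ----

# `spatial` gives which of the leading dims are pooled candidates; the last
# two dims are always (C, N) for 2D and (C, N) for 3D inputs.
pool_forward <- function(x, n_spatial) {
  d <- dim(x)
  pooled <- d[seq_len(n_spatial)] >= 2L
  outd <- d
  outd[seq_len(n_spatial)] <- ifelse(pooled, d[seq_len(n_spatial)] %/% 2L,
                                     d[seq_len(n_spatial)])
  # index lists for the 2^k sub-grids
  starts <- lapply(seq_len(n_spatial), function(i) {
    if (pooled[i]) 1:2 else 1L
  })
  grid <- expand.grid(starts)
  subs <- vector("list", nrow(grid))
  sel_all <- lapply(d, seq_len)
  for (g in seq_len(nrow(grid))) {
    sel <- sel_all
    for (i in seq_len(n_spatial)) {
      if (pooled[i]) sel[[i]] <- seq(grid[g, i], 2L * outd[i], by = 2L)
    }
    subs[[g]] <- do.call(`[`, c(list(x), sel, list(drop = FALSE)))
    dim(subs[[g]]) <- outd
  }
  m <- subs[[1]]
  if (length(subs) > 1L) for (g in 2:length(subs)) m <- pmax(m, subs[[g]])
  list(out = m, cache = list(dims = d, outd = outd, grid = grid,
                             pooled = pooled, subs = subs, m = m,
                             n_spatial = n_spatial))
}

pool_backward <- function(dy, cache) {
  d <- cache$dims; outd <- cache$outd
  dx <- array(0, d)
  taken <- array(FALSE, outd)
  sel_all <- lapply(d, seq_len)
  for (g in seq_len(nrow(cache$grid))) {
    mask <- (cache$subs[[g]] == cache$m) & !taken
    taken <- taken | mask
    sel <- sel_all
    for (i in seq_len(cache$n_spatial)) {
      if (cache$pooled[i]) sel[[i]] <- seq(cache$grid[g, i], 2L * outd[i], by = 2L)
    }
    contrib <- dy * mask
    dim(contrib) <- outd
    # scatter: assign into the strided sub-grid (positions are disjoint per g)
    existing <- do.call(`[`, c(list(dx), sel, list(drop = FALSE)))
    dx <- do.call(`[<-`, c(list(dx), sel, list(existing + contrib)))
    }
  dx
}

## ---- dense ----

dense_layer <- function(fin, fout, init = "he", relu = FALSE) {
  list(type = "dense", fin = fin, fout = fout, relu = relu,
       W = nn_init_mat(fin, fout, fin, init), b = numeric(fout))
}

dense_forward <- function(layer, x, train = FALSE) {
  pre <- sweep(x %*% layer$W, 2L, layer$b, `+`)
  out <- if (layer$relu) pmax(pre, 0) else pre
  list(out = out, cache = list(x = x, mask = if (layer$relu) pre > 0 else NULL))
}

dense_backward <- function(layer, dy, cache) {
  if (layer$relu) dy <- dy * cache$mask
  list(dx = dy %*% t(layer$W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

## ---- dropout (inverted; identity at evaluation time) ----

dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim(x) %||% length(x)) / (1 - rate)
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

## ---- LSTM (single layer; classification read from the final step) ----

lstm_layer <- function(fin, hidden, init = "he") {
  l <- list(type = "lstm", fin = fin, hidden = hidden,
            Wx = nn_init_mat(fin, 4L * hidden, fin, init),
            Wh = nn_init_mat(hidden, 4L * hidden, hidden, init),
            b = numeric(4L * hidden))
  l$b[seq_len(hidden) + hidden] <- 1  # forget-gate bias init
  l
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# xs: list of T matrices (N x F). Returns the final hidden state (N x H).
lstm_forward <- function(layer, xs, train = FALSE) {
  H <- layer$hidden
  N <- nrow(xs[[1]])
  h <- matrix(0, N, H); cstate <- matrix(0, N, H)
  steps <- vector("list", length(xs))
  ii <- seq_len(H); ff <- ii + H; gg <- ii + 2L * H; oo <- ii + 3L * H
  for (t in seq_along(xs)) {
    z <- xs[[t]] %*% layer$Wx + h %*% layer$Wh
    z <- sweep(z, 2L, layer$b, `+`)
    i <- sigmoid(z[, ii, drop = FALSE])
    f <- sigmoid(z[, ff, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE])
    o <- sigmoid(z[, oo, drop = FALSE])
    c_prev <- cstate
    cstate <- f * c_prev + i * g
    tc <- tanh(cstate)
    h_prev <- h
    h <- o * tc
    steps[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev, tc = tc,
                       h_prev = h_prev, x = xs[[t]])
  }
  list(out = h, cache = list(steps = steps, N = N))
}

# dh_last: gradient wrt the final hidden state. Returns dxs (list) + grads.
lstm_backward <- function(layer, dh_last, cache) {
  H <- layer$hidden
  steps <- cache$steps
  Tn <- length(steps)
  dWx <- matrix(0, nrow(layer$Wx), ncol(layer$Wx))
  dWh <- matrix(0, nrow(layer$Wh), ncol(layer$Wh))
  db <- numeric(4L * H)
  dxs <- vector("list", Tn)
  dh <- dh_last
  dc <- matrix(0, cache$N, H)
  for (t in rev(seq_len(Tn))) {
    s <- steps[[t]]
    do_ <- dh * s$tc
    dct <- dh * s$o * (1 - s$tc^2) + dc
    di <- dct * s$g
    df <- dct * s$c_prev
    dg <- dct * s$i
    dc <- dct * s$f
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_ * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$x, dz)
    dWh <- dWh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dxs[[t]] <- dz %*% t(layer$Wx)
    dh <- dz %*% t(layer$Wh)
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

## ---- softmax cross-entropy ----

softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: 0-based integer class labels. weights: optional per-class loss weights.
softmax_ce <- function(logits, y, weights = NULL) {
  n <- nrow(logits)
  p <- softmax(logits)
  eps <- 1e-12
  wi <- if (is.null(weights)) rep(1, n) else weights[y + 1L]
  picked <- p[cbind(seq_len(n), y + 1L)]
  loss <- -sum(wi * log(pmax(picked, eps))) / n
  dlogits <- p
  dlogits[cbind(seq_len(n), y + 1L)] <-
    dlogits[cbind(seq_len(n), y + 1L)] - 1
  dlogits <- dlogits * (wi / n)
  list(loss = loss, dlogits = dlogits, probs = p)
}
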