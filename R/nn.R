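# Internal neural-network engine for the CNN-LSTM classifier.
#
# Layers: 1D convolution (im2col + BLAS), two bidirectional LSTM layers
# (first returns the sequence, second the final states), inverted dropout
# between them, dense + softmax head. Backpropagation through time is
# implemented directly; optimization is Adam with global-norm gradient
# clipping. Arrays are laid out [channels, time, batch] so per-time-step
# work is a dense matrix product over the batch.

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

nn_init_lstm <- function(input, hidden) {
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1   # forget-gate bias
  list(Wx = glorot(4 * hidden, input), Wh = glorot(4 * hidden, hidden), b = b)
}

nn_init <- function(spec, in_channels, in_len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- spec$conv_filter_size
  F_ <- spec$conv_filters
  H <- spec$lstm_hidden
  params <- list(
    conv_W = glorot(F_, in_channels * K), conv_b = numeric(F_),
    l1f = nn_init_lstm(F_, H), l1b = nn_init_lstm(F_, H),
    l2f = nn_init_lstm(2 * H, H), l2b = nn_init_lstm(2 * H, H),
    dense_W = glorot(spec$num_classes, 2 * H),
    dense_b = numeric(spec$num_classes)
  )
  params
}

conv_len_out <- function(L, K, stride) floor((L - K) / stride) + 1L

# X: [C, L, B] -> list(Y = [F, Lo, B], Xcol cache)
conv1d_forward <- function(X, W, b, K, stride) {
  d <- dim(X); C <- d[1]; L <- d[2]; B <- d[3]
  Lo <- conv_len_out(L, K, stride)
  if (Lo < 1) stop("sequence shorter than the convolution filter")
  starts <- seq(1L, by = stride, length.out = Lo)
  Xcol <- matrix(0, C * K, Lo * B)
  for (k in seq_len(K)) {
    sl <- X[, starts + k - 1L, , drop = FALSE]
    dim(sl) <- c(C, Lo * B)
    Xcol[((k - 1L) * C + 1L):(k * C), ] <- sl
  }
  Y <- W %*% Xcol + b
  dim(Y) <- c(nrow(W), Lo, B)
  list(Y = Y, Xcol = Xcol, starts = starts, dims = d)
}

conv1d_backward <- function(dY, W, cache, K, stride) {
  d <- cache$dims; C <- d[1]; L <- d[2]; B <- d[3]
  Lo <- length(cache$starts)
  dim(dY) <- c(nrow(W), Lo * B)
  dW <- dY %*% t(cache$Xcol)
  db <- rowSums(dY)
  dXcol <- crossprod(W, dY)
  dX <- array(0, dim = d)
  for (k in seq_len(K)) {
    blk <- dXcol[((k - 1L) * C + 1L):(k * C), , drop = FALSE]
    dim(blk) <- c(C, Lo, B)
    dX[, cache$starts + k - 1L, ] <- dX[, cache$starts + k - 1L, ] + blk
  }
  list(dW = dW, db = db, dX = dX)
}

sigm <- function(x) 1 / (1 + exp(-x))

# one-direction LSTM over X [I, L, B]; returns H_seq [H, L, B] + caches
lstm_forward <- function(X, p) {
  d <- dim(X); I <- d[1]; L <- d[2]; B <- d[3]
  H <- length(p$b) / 4
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  Hs <- array(0, c(H, L, B))
  Cs <- array(0, c(H, L, B))
  G <- array(0, c(4 * H, L, B))     # activated gates i, f, g, o
  ih <- 1:H; fh <- (H + 1):(2 * H); gh <- (2 * H + 1):(3 * H)
  oh <- (3 * H + 1):(4 * H)
  for (t in seq_len(L)) {
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(I, B)
    z <- p$Wx %*% xt + p$Wh %*% h + p$b
    gi <- sigm(z[ih, , drop = FALSE])
    gf <- sigm(z[fh, , drop = FALSE])
    gg <- tanh(z[gh, , drop = FALSE])
    go <- sigm(z[oh, , drop = FALSE])
    cc <- gf * cc + gi * gg
    h <- go * tanh(cc)
    Hs[, t, ] <- h; Cs[, t, ] <- cc
    G[, t, ] <- rbind(gi, gf, gg, go)
  }
  list(H = Hs, C = Cs, G = G, X = X)
}

# dH: gradient wrt the full output sequence [H, L, B] (zero where unused)
lstm_backward <- function(dH, p, cache) {
  X <- cache$X
  d <- dim(X); I <- d[1]; L <- d[2]; B <- d[3]
  H <- length(p$b) / 4
  ih <- 1:H; fh <- (H + 1):(2 * H); gh <- (2 * H + 1):(3 * H)
  oh <- (3 * H + 1):(4 * H)
  dWx <- matrix(0, 4 * H, I); dWh <- matrix(0, 4 * H, H); db <- numeric(4 * H)
  dX <- array(0, d)
  dh <- matrix(0, H, B); dc <- matrix(0, H, B)
  for (t in seq(L, 1L)) {
    g <- cache$G[, t, , drop = FALSE]; dim(g) <- c(4 * H, B)
    gi <- g[ih, , drop = FALSE]; gf <- g[fh, , drop = FALSE]
    gg <- g[gh, , drop = FALSE]; go <- g[oh, , drop = FALSE]
    cc <- cache$C[, t, , drop = FALSE]; dim(cc) <- c(H, B)
    ht <- cache$H[, t, , drop = FALSE]; dim(ht) <- c(H, B)
    dht <- dH[, t, , drop = FALSE]; dim(dht) <- c(H, B)
    dh <- dh + dht
    tc <- tanh(cc)
    do_ <- dh * tc
    dcc <- dc + dh * go * (1 - tc^2)
    c_prev <- if (t > 1L) {
      cp <- cache$C[, t - 1L, , drop = FALSE]; dim(cp) <- c(H, B); cp
    } else matrix(0, H, B)
    di <- dcc * gg; df <- dcc * c_prev; dg <- dcc * gi
    dc <- dcc * gf
    dz <- rbind(di * gi * (1 - gi), df * gf * (1 - gf),
                dg * (1 - gg^2), do_ * go * (1 - go))
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(I, B)
    h_prev <- if (t > 1L) {
      hp <- cache$H[, t - 1L, , drop = FALSE]; dim(hp) <- c(H, B); hp
    } else matrix(0, H, B)
    dWx <- dWx + tcrossprod(dz, xt)
    dWh <- dWh + tcrossprod(dz, h_prev)
    db <- db + rowSums(dz)
    dX[, t, ] <- crossprod(p$Wx, dz)
    dh <- crossprod(p$Wh, dz)
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

rev_time <- function(X) X[, rev(seq_len(dim(X)[2])), , drop = FALSE]

# bidirectional LSTM; mode "sequence" -> [2H, L, B]; "last" -> [2H, B]
bilstm_forward <- function(X, pf, pb, mode = c("sequence", "last")) {
  mode <- match.arg(mode)
  fw <- lstm_forward(X, pf)
  bw <- lstm_forward(rev_time(X), pb)
  L <- dim(X)[2]; B <- dim(X)[3]; H <- dim(fw$H)[1]
  if (mode == "sequence") {
    Y <- array(0, c(2 * H, L, B))
    Y[1:H, , ] <- fw$H
    Y[(H + 1):(2 * H), , ] <- rev_time(bw$H)
  } else {
    hf <- fw$H[, L, , drop = FALSE]; dim(hf) <- c(H, B)
    hb <- bw$H[, L, , drop = FALSE]; dim(hb) <- c(H, B)
    Y <- rbind(hf, hb)
  }
  list(Y = Y, fw = fw, bw = bw, mode = mode)
}

bilstm_backward <- function(dY, pf, pb, cache) {
  fw <- cache$fw; bw <- cache$bw
  H <- dim(fw$H)[1]; L <- dim(fw$H)[2]; B <- dim(fw$H)[3]
  if (cache$mode == "sequence") {
    dHf <- dY[1:H, , , drop = FALSE]
    dHb <- rev_time(dY[(H + 1):(2 * H), , , drop = FALSE])
  } else {
    dHf <- array(0, c(H, L, B)); dHb <- array(0, c(H, L, B))
    dHf[, L, ] <- dY[1:H, , drop = FALSE]
    dHb[, L, ] <- dY[(H + 1):(2 * H), , drop = FALSE]
  }
  gf <- lstm_backward(dHf, pf, fw)
  gb <- lstm_backward(dHb, pb, bw)
  list(gf = gf[c("dWx", "dWh", "db")], gb = gb[c("dWx", "dWh", "db")],
       dX = gf$dX + rev_time(gb$dX))
}

# full network forward; returns probs [n_classes, B] and caches for backward
nn_forward <- function(params, X, spec, train = FALSE, dropmask = NULL) {
  cv <- conv1d_forward(X, params$conv_W, params$conv_b,
                       spec$conv_filter_size, spec$conv_stride)
  A1 <- cv$Y
  if (identical(spec$conv_activation, "relu")) A1 <- pmax(A1, 0)
  b1 <- bilstm_forward(A1, params$l1f, params$l1b, "sequence")
  S <- b1$Y
  if (train && spec$dropout > 0) {
    if (is.null(dropmask)) {
      dropmask <- array(
        (runif(length(S)) >= spec$dropout) / (1 - spec$dropout), dim(S))
    }
    S <- S * dropmask
  }
  b2 <- bilstm_forward(S, params$l2f, params$l2b, "last")
  logits <- params$dense_W %*% b2$Y + params$dense_b
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  probs <- sweep(ex, 2, colSums(ex), "/")
  list(probs = probs, cv = cv, A1 = A1, b1 = b1, S = S, b2 = b2,
       dropmask = dropmask)
}

# cross-entropy loss + full gradient; Y1hot [n_classes, B]
nn_backward <- function(params, X, Y1hot, spec, fwd) {
  B <- ncol(Y1hot)
  dlogits <- (fwd$probs - Y1hot) / B
  grads <- list()
  grads$dense_W <- tcrossprod(dlogits, fwd$b2$Y)
  grads$dense_b <- rowSums(dlogits)
  dY2 <- crossprod(params$dense_W, dlogits)
  g2 <- bilstm_backward(dY2, params$l2f, params$l2b, fwd$b2)
  grads$l2f <- g2$gf; grads$l2b <- g2$gb
  dS <- g2$dX
  if (!is.null(fwd$dropmask)) dS <- dS * fwd$dropmask
  g1 <- bilstm_backward(dS, params$l1f, params$l1b, fwd$b1)
  grads$l1f <- g1$gf; grads$l1b <- g1$gb
  dA1 <- g1$dX
  if (identical(spec$conv_activation, "relu")) dA1 <- dA1 * (fwd$A1 > 0)
  gc_ <- conv1d_backward(dA1, params$conv_W, fwd$cv,
                         spec$conv_filter_size, spec$conv_stride)
  grads$conv_W <- gc_$dW; grads$conv_b <- gc_$db
  # rename lstm grads to parameter names
  for (nm in c("l1f", "l1b", "l2f", "l2b")) {
    names(grads[[nm]]) <- c("Wx", "Wh", "b")
  }
  loss <- -mean(log(pmax(colSums(fwd$probs * Y1hot), 1e-12)))
  list(grads = grads, loss = loss)
}

# flatten/apply helpers over the nested parameter list
nn_walk <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- nn_walk(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

nn_grad_norm <- function(grads) {
  s <- 0
  rec <- function(g) {
    if (is.list(g)) lapply(g, rec) else s <<- s + sum(g^2)
    invisible(NULL)
  }
  rec(grads)
  sqrt(s)
}

adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = NULL) {
  if (!is.null(clip) && is.finite(clip)) {
    gn <- nn_grad_norm(grads)
    if (gn > clip) grads <- nn_walk(grads, grads, function(g, .) g * clip / gn)
  }
  state$t <- state$t + 1
  state$m <- nn_walk(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nn_walk(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- nn_walk(state$m, state$m, function(m, .) m / bc1)
  vh <- nn_walk(state$v, state$v, function(v, .) v / bc2)
  upd <- nn_walk(mh, vh, function(m, v) m / (sqrt(v) + eps))
  params <- nn_walk(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}

# stack a list of feature matrices into [C, L, B]
stack_features <- function(feature_list) {
  d <- dim(feature_list[[1]])
  X <- array(0, c(d[1], d[2], length(feature_list)))
  for (i in seq_along(feature_list)) {
    fi <- feature_list[[i]]
    if (!all(dim(fi) == d)) {
      stop("feature matrix ", i, " has shape ", paste(dim(fi), collapse = "x"),
           ", expected ", paste(d, collapse = "x"))
    }
    X[, , i] <- fi
  }
  X
}
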