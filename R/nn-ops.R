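# Minimal neural-network kernel: forward/backward passes for the handful of
# layer types the generator, critic and predictor need, written against base
# R matrix algebra. Batches are 3-D arrays [batch, length, channels]; reshaping
# a [B, L, C] array to a (B*L) x C matrix is exact because R arrays are
# column-major and the first two dims are contiguous.

sigm <- function(x) 1 / (1 + exp(-x))

# ---- parameter initialisation --------------------------------------------

glorot <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

# ---- pointwise (1x1 conv / per-position linear) --------------------------

pointwise_fwd <- function(X, W, b) {
  d <- dim(X)
  M <- matrix(X, d[1] * d[2], d[3])
  Y <- sweep(M %*% W, 2L, b, "+")
  list(out = array(Y, c(d[1], d[2], ncol(W))), cache = list(M = M, d = d))
}

pointwise_bwd <- function(cache, W, dY) {
  d <- dim(dY)
  dM <- matrix(dY, d[1] * d[2], d[3])
  list(dX = array(dM %*% t(W), cache$d),
       dW = t(cache$M) %*% dM, db = colSums(dM))
}

# ---- conv1d, 'same' zero padding, odd kernel -----------------------------

im2col <- function(X, k) {
  d <- dim(X) # B, L, C
  p <- (k - 1L) %/% 2L
  Xp <- array(0, c(d[1], d[2] + 2L * p, d[3]))
  Xp[, (p + 1L):(p + d[2]), ] <- X
  cols <- matrix(0, d[1] * d[2], d[3] * k)
  for (j in seq_len(k)) {
    cols[, ((j - 1L) * d[3] + 1L):(j * d[3])] <-
      matrix(Xp[, j:(j + d[2] - 1L), , drop = FALSE], d[1] * d[2], d[3])
  }
  cols
}

conv1d_fwd <- function(X, W, b, k) {
  # W is (k*C) x Cout, rows ordered [offset1 channels..., offset2 ...]
  d <- dim(X)
  M <- im2col(X, k)
  Y <- sweep(M %*% W, 2L, b, "+")
  list(out = array(Y, c(d[1], d[2], ncol(W))),
       cache = list(M = M, d = d, k = k))
}

conv1d_bwd <- function(cache, W, dY) {
  d <- cache$d; k <- cache$k
  dM <- matrix(dY, d[1] * d[2], dim(dY)[3])
  dW <- t(cache$M) %*% dM
  db <- colSums(dM)
  dcols <- dM %*% t(W) # (B*L) x (C*k)
  p <- (k - 1L) %/% 2L
  dXp <- array(0, c(d[1], d[2] + 2L * p, d[3]))
  for (j in seq_len(k)) {
    slice <- array(dcols[, ((j - 1L) * d[3] + 1L):(j * d[3])],
                   c(d[1], d[2], d[3]))
    dXp[, j:(j + d[2] - 1L), ] <- dXp[, j:(j + d[2] - 1L), , drop = FALSE] +
      slice
  }
  list(dX = dXp[, (p + 1L):(p + d[2]), , drop = FALSE], dW = dW, db = db)
}

# ---- activations ----------------------------------------------------------

act_fwd <- function(X, slope) { # slope 0 = relu, 0.2 = leaky relu
  out <- ifelse(X > 0, X, slope * X)
  list(out = out, cache = X > 0)
}

act_bwd <- function(cache, slope, dY) {
  dY * ifelse(cache, 1, slope)
}

# ---- row softmax over channels -------------------------------------------

rowsoftmax_fwd <- function(X) {
  d <- dim(X)
  M <- matrix(X, d[1] * d[2], d[3])
  e <- exp(M - apply(M, 1L, max))
  P <- e / rowSums(e)
  list(out = array(P, d), cache = P)
}

rowsoftmax_bwd <- function(cache, dY) {
  d <- dim(dY)
  dM <- matrix(dY, d[1] * d[2], d[3])
  P <- cache
  dX <- P * (dM - rowSums(dM * P))
  array(dX, d)
}

# ---- multi-head self-attention (per Eq.-style definition) ----------------

# One instance: X is n x d_k; params$Aq/Ak/Av are lists of d_k x d_head.
attention_one_fwd <- function(X, params) {
  o <- length(params$Aq)
  dk <- ncol(X)
  scale <- 1 / sqrt(dk)
  heads <- vector("list", o)
  cache <- vector("list", o)
  for (i in seq_len(o)) {
    Q <- X %*% params$Aq[[i]]
    K <- X %*% params$Ak[[i]]
    V <- X %*% params$Av[[i]]
    S <- (Q %*% t(K)) * scale
    e <- exp(S - apply(S, 1L, max))
    P <- e / rowSums(e)
    heads[[i]] <- P %*% V
    cache[[i]] <- list(Q = Q, K = K, V = V, P = P)
  }
  list(out = do.call(cbind, heads), cache = list(h = cache, X = X,
                                                 scale = scale))
}

attention_one_bwd <- function(cache, params, dY) {
  X <- cache$X
  o <- length(params$Aq)
  dh <- ncol(params$Aq[[1]])
  dX <- matrix(0, nrow(X), ncol(X))
  g <- list(Aq = vector("list", o), Ak = vector("list", o),
            Av = vector("list", o))
  for (i in seq_len(o)) {
    ci <- cache$h[[i]]
    dO <- dY[, ((i - 1L) * dh + 1L):(i * dh), drop = FALSE]
    dP <- dO %*% t(ci$V)
    dV <- t(ci$P) %*% dO
    dS <- ci$P * (dP - rowSums(dP * ci$P))
    dQ <- (dS %*% ci$K) * cache$scale
    dK <- (t(dS) %*% ci$Q) * cache$scale
    g$Aq[[i]] <- t(X) %*% dQ
    g$Ak[[i]] <- t(X) %*% dK
    g$Av[[i]] <- t(X) %*% dV
    dX <- dX + dQ %*% t(params$Aq[[i]]) + dK %*% t(params$Ak[[i]]) +
      dV %*% t(params$Av[[i]])
  }
  list(dX = dX, grads = g)
}

#' Multi-head self-attention on a position-by-channel matrix
#'
#' Computes `concat_i( softmax(X Aq_i (X Ak_i)^T / sqrt(d_k)) X Av_i )`
#' over `o` heads, the self-attention operation used inside the generator
#' and critic. Exposed directly so it can be checked against a dense-loop
#' reference on small instances.
#'
#' @param X `n_positions x d_k` numeric matrix.
#' @param params List with elements `Aq`, `Ak`, `Av`, each a list of `o`
#'   projection matrices of size `d_k x d_head`, where `o * d_head == d_k`.
#' @return `n_positions x d_k` matrix.
#' @export
multi_head_attention <- function(X, params) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  o <- length(params$Aq)
  stopifnot(o >= 1L, length(params$Ak) == o, length(params$Av) == o)
  dh <- ncol(params$Aq[[1]])
  if (o * dh != ncol(X)) {
    stop("head count * head width (", o, " * ", dh,
         ") must equal d_k = ", ncol(X))
  }
  for (A in c(params$Aq, params$Ak, params$Av)) {
    if (!all(dim(A) == c(ncol(X), dh))) stop("projection matrix shape mismatch")
  }
  attention_one_fwd(X, params)$out
}

# Batched attention: loop the per-instance kernel over the batch.
attention_fwd <- function(X, params, residual = TRUE) {
  d <- dim(X)
  out <- array(0, d)
  caches <- vector("list", d[1])
  for (b in seq_len(d[1])) {
    Xi <- matrix(X[b, , ], d[2], d[3])
    r <- attention_one_fwd(Xi, params)
    out[b, , ] <- if (residual) Xi + r$out else r$out
    caches[[b]] <- r$cache
  }
  list(out = out, cache = caches)
}

attention_bwd <- function(cache, params, dY, residual = TRUE) {
  d <- dim(dY)
  dX <- array(0, d)
  gsum <- NULL
  for (b in seq_len(d[1])) {
    dYi <- matrix(dY[b, , ], d[2], d[3])
    r <- attention_one_bwd(cache[[b]], params, dYi)
    dX[b, , ] <- if (residual) dYi + r$dX else r$dX
    if (is.null(gsum)) {
      gsum <- r$grads
    } else {
      for (nm in names(gsum)) {
        for (i in seq_along(gsum[[nm]])) {
          gsum[[nm]][[i]] <- gsum[[nm]][[i]] + r$grads[[nm]][[i]]
        }
      }
    }
  }
  list(dX = dX, grads = gsum)
}

# ---- bidirectional LSTM ---------------------------------------------------

lstm_dir_fwd <- function(X, Wx, Wh, b) {
  d <- dim(X) # B, L, C
  H <- nrow(Wh) # Wh is H x 4H
  hs <- array(0, c(d[1], d[2], H))
  cache <- vector("list", d[2])
  h <- matrix(0, d[1], H); c0 <- matrix(0, d[1], H)
  for (t in seq_len(d[2])) {
    Xt <- matrix(X[, t, ], d[1], d[3])
    A <- Xt %*% Wx + h %*% Wh
    A <- sweep(A, 2L, b, "+")
    i <- sigm(A[, 1:H, drop = FALSE])
    f <- sigm(A[, (H + 1L):(2L * H), drop = FALSE])
    g <- tanh(A[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- sigm(A[, (3L * H + 1L):(4L * H), drop = FALSE])
    cc <- f * c0 + i * g
    tc <- tanh(cc)
    hn <- o * tc
    cache[[t]] <- list(Xt = Xt, hprev = h, cprev = c0, i = i, f = f,
                       g = g, o = o, tc = tc)
    h <- hn; c0 <- cc
    hs[, t, ] <- hn
  }
  list(out = hs, cache = cache)
}

lstm_dir_bwd <- function(cache, X, Wx, Wh, dH) {
  d <- dim(X)
  H <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- array(0, d)
  dh_next <- matrix(0, d[1], H)
  dc_next <- matrix(0, d[1], H)
  for (t in rev(seq_len(d[2]))) {
    cc <- cache[[t]]
    dh <- matrix(dH[, t, ], d[1], H) + dh_next
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$cprev
    dc_next <- dc * cc$f
    dA <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do * cc$o * (1 - cc$o))
    dWx <- dWx + t(cc$Xt) %*% dA
    dWh <- dWh + t(cc$hprev) %*% dA
    db <- db + colSums(dA)
    dX[, t, ] <- dA %*% t(Wx)
    dh_next <- dA %*% t(Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

bilstm_fwd <- function(X, p) {
  fw <- lstm_dir_fwd(X, p$Wx_f, p$Wh_f, p$b_f)
  Xr <- X[, rev(seq_len(dim(X)[2])), , drop = FALSE]
  bw <- lstm_dir_fwd(Xr, p$Wx_b, p$Wh_b, p$b_b)
  H <- nrow(p$Wh_f)
  d <- dim(X)
  out <- array(0, c(d[1], d[2], 2L * H))
  out[, , 1:H] <- fw$out
  out[, , (H + 1L):(2L * H)] <- bw$out[, rev(seq_len(d[2])), , drop = FALSE]
  list(out = out, cache = list(fw = fw$cache, bw = bw$cache, Xr = Xr))
}

bilstm_bwd <- function(cache, X, p, dY) {
  H <- nrow(p$Wh_f)
  d <- dim(X)
  dHf <- dY[, , 1:H, drop = FALSE]
  dHb <- dY[, rev(seq_len(d[2])), (H + 1L):(2L * H), drop = FALSE]
  rf <- lstm_dir_bwd(cache$fw, X, p$Wx_f, p$Wh_f, dHf)
  rb <- lstm_dir_bwd(cache$bw, cache$Xr, p$Wx_b, p$Wh_b, dHb)
  dX <- rf$dX + rb$dX[, rev(seq_len(d[2])), , drop = FALSE]
  list(dX = dX,
       grads = list(Wx_f = rf$dWx, Wh_f = rf$dWh, b_f = rf$db,
                    Wx_b = rb$dWx, Wh_b = rb$dWh, b_b = rb$db))
}

# ---- pooling and dense head ----------------------------------------------

avgpool2_fwd <- function(X) {
  d <- dim(X)
  Lo <- d[2] %/% 2L
  out <- (X[, seq(1L, 2L * Lo, 2L), , drop = FALSE] +
            X[, seq(2L, 2L * Lo, 2L), , drop = FALSE]) / 2
  list(out = out, cache = d)
}

avgpool2_bwd <- function(cache, dY) {
  d <- cache
  Lo <- d[2] %/% 2L
  dX <- array(0, d)
  dX[, seq(1L, 2L * Lo, 2L), ] <- dY / 2
  dX[, seq(2L, 2L * Lo, 2L), ] <- dY / 2
  dX
}

gap_fwd <- function(X) {
  d <- dim(X)
  list(out = matrix(colMeans(aperm(X, c(2, 1, 3))), d[1], d[3]),
       cache = d)
}

gap_bwd <- function(cache, dY) {
  d <- cache
  dX <- array(0, d)
  for (t in seq_len(d[2])) dX[, t, ] <- dY / d[2]
  dX
}

dense_fwd <- function(X, W, b) { # X: B x C matrix
  list(out = sweep(X %*% W, 2L, b, "+"), cache = X)
}

dense_bwd <- function(cache, W, dY) {
  list(dX = dY %*% t(W), dW = t(cache) %*% dY, db = colSums(dY))
}

# ---- layer dispatch -------------------------------------------------------

layer_forward <- function(layer, X) {
  switch(layer$type,
    pointwise = pointwise_fwd(X, layer$W, layer$b),
    conv = conv1d_fwd(X, layer$W, layer$b, layer$k),
    act = act_fwd(X, layer$slope),
    rowsoftmax = rowsoftmax_fwd(X),
    attention = attention_fwd(X, layer$params, layer$residual),
    bilstm = bilstm_fwd(X, layer$params),
    avgpool2 = avgpool2_fwd(X),
    gap = gap_fwd(X),
    dense = dense_fwd(X, layer$W, layer$b),
    resblock = resblock_fwd(X, layer),
    denseblock = denseblock_fwd(X, layer),
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, X, dY) {
  switch(layer$type,
    pointwise = {
      r <- pointwise_bwd(cache, layer$W, dY)
      list(dX = r$dX, grads = list(W = r$dW, b = r$db))
    },
    conv = {
      r <- conv1d_bwd(cache, layer$W, dY)
      list(dX = r$dX, grads = list(W = r$dW, b = r$db))
    },
    act = list(dX = act_bwd(cache, layer$slope, dY), grads = NULL),
    rowsoftmax = list(dX = rowsoftmax_bwd(cache, dY), grads = NULL),
    attention = {
      r <- attention_bwd(cache, layer$params, dY, layer$residual)
      list(dX = r$dX, grads = r$grads)
    },
    bilstm = {
      r <- bilstm_bwd(cache, X, layer$params, dY)
      list(dX = r$dX, grads = r$grads)
    },
    avgpool2 = list(dX = avgpool2_bwd(cache, dY), grads = NULL),
    gap = list(dX = gap_bwd(cache, dY), grads = NULL),
    dense = {
      r <- dense_bwd(cache, layer$W, dY)
      list(dX = r$dX, grads = list(W = r$dW, b = r$db))
    },
    resblock = resblock_bwd(layer, cache, dY),
    denseblock = denseblock_bwd(layer, cache, dY),
    stop("unknown layer type: ", layer$type)
  )
}

net_forward <- function(layers, X) {
  caches <- vector("list", length(layers))
  inputs <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    inputs[[l]] <- X
    r <- layer_forward(layers[[l]], X)
    if (!all(is.finite(r$out))) {
      stop("non-finite activations in layer ", l, " (",
           layers[[l]]$type, ")")
    }
    caches[[l]] <- r$cache
    X <- r$out
  }
  list(out = X, caches = caches, inputs = inputs)
}

net_backward <- function(layers, fwd, dOut) {
  grads <- vector("list", length(layers))
  dY <- dOut
  for (l in rev(seq_along(layers))) {
    r <- layer_backward(layers[[l]], fwd$caches[[l]], fwd$inputs[[l]], dY)
    grads[l] <- list(r$grads) # not [[<-: NULL grads must not shrink the list
    dY <- r$dX
  }
  list(dX = dY, grads = grads)
}

# ---- composite blocks -----------------------------------------------------

# y = x + conv2(lrelu(conv1(lrelu(x)))): channel-preserving residual block.
make_resblock <- function(channels, k = 3L, slope = 0.2) {
  list(type = "resblock", slope = slope,
       sub = list(
         list(type = "act", slope = slope),
         list(type = "conv", k = k, W = glorot(k * channels, channels),
              b = numeric(channels)),
         list(type = "act", slope = slope),
         list(type = "conv", k = k,
              W = glorot(k * channels, channels) * 0.1,
              b = numeric(channels))
       ))
}

resblock_fwd <- function(X, layer) {
  r <- net_forward(layer$sub, X)
  list(out = X + r$out, cache = r)
}

resblock_bwd <- function(layer, cache, dY) {
  r <- net_backward(layer$sub, cache, dY)
  list(dX = dY + r$dX, grads = r$grads)
}

# DenseNet block: n_layers dense layers, each conv1(k=1, -> 4*growth),
# relu, conv(k=3, -> growth), relu, then channel-concat onto its input.
make_denseblock <- function(in_channels, n_layers, growth,
                            kernels = c(1L, 3L)) {
  layers <- vector("list", n_layers)
  ch <- in_channels
  for (j in seq_len(n_layers)) {
    bottleneck <- 4L * growth
    layers[[j]] <- list(
      conv1 = list(type = "conv", k = kernels[1],
                   W = glorot(kernels[1] * ch, bottleneck),
                   b = numeric(bottleneck)),
      conv2 = list(type = "conv", k = kernels[2],
                   W = glorot(kernels[2] * bottleneck, growth),
                   b = numeric(growth))
    )
    ch <- ch + growth
  }
  list(type = "denseblock", sub = layers, out_channels = ch)
}

denseblock_fwd <- function(X, layer) {
  caches <- vector("list", length(layer$sub))
  cur <- X
  for (j in seq_along(layer$sub)) {
    lj <- layer$sub[[j]]
    c1 <- conv1d_fwd(cur, lj$conv1$W, lj$conv1$b, lj$conv1$k)
    a1 <- act_fwd(c1$out, 0)
    c2 <- conv1d_fwd(a1$out, lj$conv2$W, lj$conv2$b, lj$conv2$k)
    a2 <- act_fwd(c2$out, 0)
    caches[[j]] <- list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache,
                        a2 = a2$cache, in_ch = dim(cur)[3])
    d <- dim(cur)
    merged <- array(0, c(d[1], d[2], d[3] + dim(a2$out)[3]))
    merged[, , 1:d[3]] <- cur
    merged[, , (d[3] + 1L):dim(merged)[3]] <- a2$out
    cur <- merged
  }
  list(out = cur, cache = caches)
}

denseblock_bwd <- function(layer, cache, dY) {
  grads <- vector("list", length(layer$sub))
  dcur <- dY
  for (j in rev(seq_along(layer$sub))) {
    lj <- layer$sub[[j]]
    cj <- cache[[j]]
    in_ch <- cj$in_ch
    total <- dim(dcur)[3]
    d_new <- dcur[, , (in_ch + 1L):total, drop = FALSE]
    d_in <- dcur[, , 1:in_ch, drop = FALSE]
    da2 <- act_bwd(cj$a2, 0, d_new)
    r2 <- conv1d_bwd(cj$c2, lj$conv2$W, da2)
    da1 <- act_bwd(cj$a1, 0, r2$dX)
    r1 <- conv1d_bwd(cj$c1, lj$conv1$W, da1)
    grads[[j]] <- list(conv1 = list(W = r1$dW, b = r1$db),
                       conv2 = list(W = r2$dW, b = r2$db))
    dcur <- d_in + r1$dX
  }
  list(dX = dcur, grads = grads)
}

# ---- parameter bookkeeping and Adam --------------------------------------

# Walk a layer list, applying fn(param_array, grad_array, state) at every
# leaf numeric parameter. Used for both Adam updates and parameter counts.
# Layers and grads are parallel structures; state is created lazily.

adam_state_new <- function() new.env(parent = emptyenv())

adam_update_layers <- function(layers, grads, state, lr, beta1, beta2,
                               eps = 1e-8) {
  if (is.null(state$t)) state$t <- 0L
  state$t <- state$t + 1L
  t <- state$t
  if (is.null(state$m)) state$m <- list()
  upd <- function(path, p, g) {
    if (is.null(g)) return(p)
    key <- path
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- list(m = p * 0, v = p * 0)
    }
    st <- state$m[[key]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    state$m[[key]] <- st
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p - lr * mhat / (sqrt(vhat) + eps)
  }
  for (l in seq_along(layers)) {
    if (is.null(grads[[l]])) next
    lay <- layers[[l]]
    g <- grads[[l]]
    target <- switch(lay$type,
      pointwise = , conv = , dense = {
        lay$W <- upd(paste0(l, "/W"), lay$W, g$W)
        lay$b <- upd(paste0(l, "/b"), lay$b, g$b)
        lay
      },
      attention = {
        for (nm in c("Aq", "Ak", "Av")) {
          for (i in seq_along(lay$params[[nm]])) {
            lay$params[[nm]][[i]] <- upd(paste0(l, "/", nm, "/", i),
                                         lay$params[[nm]][[i]],
                                         g[[nm]][[i]])
          }
        }
        lay
      },
      bilstm = {
        for (nm in names(g)) {
          lay$params[[nm]] <- upd(paste0(l, "/", nm), lay$params[[nm]],
                                  g[[nm]])
        }
        lay
      },
      resblock = {
        for (j in seq_along(lay$sub)) {
          if (is.null(g[[j]])) next
          lay$sub[[j]]$W <- upd(paste0(l, "/s", j, "/W"), lay$sub[[j]]$W,
                                g[[j]]$W)
          lay$sub[[j]]$b <- upd(paste0(l, "/s", j, "/b"), lay$sub[[j]]$b,
                                g[[j]]$b)
        }
        lay
      },
      denseblock = {
        for (j in seq_along(lay$sub)) {
          for (cv in c("conv1", "conv2")) {
            lay$sub[[j]][[cv]]$W <- upd(paste0(l, "/d", j, "/", cv, "/W"),
                                        lay$sub[[j]][[cv]]$W,
                                        g[[j]][[cv]]$W)
            lay$sub[[j]][[cv]]$b <- upd(paste0(l, "/d", j, "/", cv, "/b"),
                                        lay$sub[[j]][[cv]]$b,
                                        g[[j]][[cv]]$b)
          }
        }
        lay
      },
      lay
    )
    layers[[l]] <- target
  }
  layers
}

make_attention_params <- function(d_k, heads) {
  dh <- d_k %/% heads
  stopifnot(dh * heads == d_k)
  list(Aq = lapply(seq_len(heads), function(i) glorot(d_k, dh)),
       Ak = lapply(seq_len(heads), function(i) glorot(d_k, dh)),
       Av = lapply(seq_len(heads), function(i) glorot(d_k, dh)))
}

# Encode a batch of sequences into a [B, L, 4] array.
encode_batch <- function(seqs) {
  B <- length(seqs)
  L <- nchar(seqs[[1]])
  X <- array(0, c(B, L, 4L))
  for (b in seq_len(B)) X[b, , ] <- encode_onehot(seqs[[b]])
  X
}
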