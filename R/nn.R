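# Compact neural-network engine: dense matrix forward/backward passes for
# the layers the classifier needs (2-D convolution, batch normalization,
# adaptive average pooling, GRU, multi-head self-attention, layer norm,
# feed-forward), plus softmax cross-entropy and Adam. Arrays are
# column-major with layout (H, W, channels, batch) for maps and
# (batch, steps, features) for sequences.

sigmoidMat <- function(x) 1 / (1 + exp(-x))

glorot <- function(din, dout) {
  lim <- sqrt(6 / (din + dout))
  matrix(stats::runif(din * dout, -lim, lim), din, dout)
}

initLinear <- function(din, dout) list(W = glorot(din, dout),
                                       b = numeric(dout))

linearForward <- function(X, p) {
  list(out = sweep(X %*% p$W, 2L, p$b, "+"), X = X)
}

linearBackward <- function(dY, cache, p) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

## ---- 2-D convolution (stride 1) ------------------------------------------

initConv <- function(inC, outC, k) {
  # weight rows indexed (offset-major, input-channel-minor)
  list(W = glorot(k * k * inC, outC) / k, b = numeric(outC))
}

conv2dForward <- function(x, p, k, pad) {
  d <- dim(x)                       # (H, W, inC, n)
  H <- d[1L]; Wd <- d[2L]; inC <- d[3L]; n <- d[4L]
  Ho <- H + 2L * pad - k + 1L
  Wo <- Wd + 2L * pad - k + 1L
  xp <- array(0, c(H + 2L * pad, Wd + 2L * pad, inC, n))
  xp[pad + seq_len(H), pad + seq_len(Wd), , ] <- x
  cols <- matrix(0, Ho * Wo * n, k * k * inC)
  o <- 0L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    o <- o + 1L
    s <- xp[dy + seq_len(Ho), dx + seq_len(Wo), , , drop = FALSE]
    s <- aperm(s, c(1L, 2L, 4L, 3L))
    dim(s) <- c(Ho * Wo * n, inC)
    cols[, ((o - 1L) * inC + 1L):(o * inC)] <- s
  }
  y <- sweep(cols %*% p$W, 2L, p$b, "+")       # (Ho*Wo*n) x outC
  dim(y) <- c(Ho, Wo, n, ncol(p$W))
  list(out = aperm(y, c(1L, 2L, 4L, 3L)), cols = cols,
       dims = c(H, Wd, inC, n, Ho, Wo), k = k, pad = pad)
}

conv2dBackward <- function(dout, cache, p) {
  dm <- cache$dims
  H <- dm[1L]; Wd <- dm[2L]; inC <- dm[3L]; n <- dm[4L]
  Ho <- dm[5L]; Wo <- dm[6L]
  k <- cache$k; pad <- cache$pad
  dY <- aperm(dout, c(1L, 2L, 4L, 3L))         # (Ho, Wo, n, outC)
  dim(dY) <- c(Ho * Wo * n, ncol(p$W))
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  dcols <- dY %*% t(p$W)
  dxp <- array(0, c(H + 2L * pad, Wd + 2L * pad, inC, n))
  o <- 0L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    o <- o + 1L
    blk <- dcols[, ((o - 1L) * inC + 1L):(o * inC), drop = FALSE]
    dim(blk) <- c(Ho, Wo, n, inC)
    dxp[dy + seq_len(Ho), dx + seq_len(Wo), , ] <-
      dxp[dy + seq_len(Ho), dx + seq_len(Wo), , , drop = FALSE] +
      aperm(blk, c(1L, 2L, 4L, 3L))
  }
  list(dX = dxp[pad + seq_len(H), pad + seq_len(Wd), , , drop = FALSE],
       grads = list(W = dW, b = db))
}

## ---- batch normalization over channel maps -------------------------------

initBatchNorm <- function(C) list(gamma = rep(1, C), beta = numeric(C))

initBatchNormBuffers <- function(C) list(mean = numeric(C), var = rep(1, C))

bnReshape <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1L] * d[2L] * d[4L], d[3L])
  m
}

bnRestore <- function(m, d) {
  dim(m) <- c(d[1L], d[2L], d[4L], d[3L])
  aperm(m, c(1L, 2L, 4L, 3L))
}

batchNormForward <- function(x, p, buffers, train, momentum = 0.1,
                             eps = 1e-5) {
  d <- dim(x)
  m <- bnReshape(x)
  if (train) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    buffers$mean <- (1 - momentum) * buffers$mean + momentum * mu
    buffers$var <- (1 - momentum) * buffers$var + momentum * v
  } else {
    mu <- buffers$mean
    v <- buffers$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(m, 2L, mu, "-"), 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(out = bnRestore(y, d), xhat = xhat, invstd = invstd, dims = d,
       buffers = buffers, train = train)
}

batchNormBackward <- function(dout, cache, p) {
  d <- cache$dims
  dy <- bnReshape(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  if (cache$train) {
    nEl <- nrow(dy)
    t1 <- sweep(dy, 2L, dbeta / nEl, "-")
    t2 <- sweep(xhat, 2L, dgamma / nEl, "*")
    dm <- sweep((t1 - t2), 2L, p$gamma * cache$invstd, "*")
  } else {
    dm <- sweep(dy, 2L, p$gamma * cache$invstd, "*")
  }
  list(dX = bnRestore(dm, d), grads = list(gamma = dgamma, beta = dbeta))
}

## ---- ReLU and adaptive average pooling -----------------------------------

reluForward <- function(x) list(out = pmax(x, 0), mask = x > 0)

reluBackward <- function(dout, cache) dout * cache$mask

poolRanges <- function(n, p) {
  lapply(seq_len(p), function(i) {
    (floor((i - 1) * n / p) + 1L):ceiling(i * n / p)
  })
}

adaptiveAvgPoolForward <- function(x, p) {
  d <- dim(x)                      # (H, W, C, n)
  rr <- poolRanges(d[1L], p)
  cr <- poolRanges(d[2L], p)
  out <- array(0, c(p, p, d[3L], d[4L]))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    s <- x[rr[[i]], cr[[j]], , , drop = FALSE]
    ds <- dim(s)
    dim(s) <- c(ds[1L] * ds[2L], ds[3L] * ds[4L])
    out[i, j, , ] <- colMeans(s)
  }
  list(out = out, rr = rr, cr = cr, dims = d)
}

adaptiveAvgPoolBackward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  p <- dim(dout)[1L]
  for (i in seq_len(p)) for (j in seq_len(p)) {
    cell <- length(cache$rr[[i]]) * length(cache$cr[[j]])
    g <- dout[i, j, , ] / cell
    dx[cache$rr[[i]], cache$cr[[j]], , ] <-
      dx[cache$rr[[i]], cache$cr[[j]], , , drop = FALSE] +
      rep(g, each = cell)
  }
  dx
}

## ---- GRU (update/reset gate formulation) ---------------------------------

initGRUCell <- function(din, h) {
  list(Wz = glorot(h + din, h), bz = numeric(h),
       Wr = glorot(h + din, h), br = numeric(h),
       Wh = glorot(h + din, h), bh = numeric(h))
}

#' One step of the gated recurrent unit
#'
#' Computes the update gate `z = sigmoid(Wz [h, x])`, reset gate
#' `r = sigmoid(Wr [h, x])`, candidate state
#' `h~ = tanh(Wh [r * h, x])` and the new hidden state
#' `h_t = (1 - z) * h_prev + z * h~` — a larger update gate admits more of
#' the candidate (new) information. Gates lie in [0, 1]; with
#' `h_prev` in [-1, 1] the new state stays in [-1, 1].
#'
#' @param x current input, n x d_in matrix (rows are batch items).
#' @param hPrev previous hidden state, n x hidden matrix.
#' @param params list with weight matrices `Wz`, `Wr`, `Wh` of shape
#'   (hidden + d_in) x hidden acting on the concatenation
#'   `[h_prev, x]`, and bias vectors `bz`, `br`, `bh`.
#' @return list with the new hidden state `h` plus the gate activations
#'   `z`, `r` and candidate `htil`.
#' @export
gruStep <- function(x, hPrev, params) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(hPrev)) hPrev <- matrix(hPrev, nrow = 1L)
  cz <- cbind(hPrev, x)
  z <- sigmoidMat(sweep(cz %*% params$Wz, 2L, params$bz, "+"))
  r <- sigmoidMat(sweep(cz %*% params$Wr, 2L, params$br, "+"))
  ch <- cbind(r * hPrev, x)
  htil <- tanh(sweep(ch %*% params$Wh, 2L, params$bh, "+"))
  h <- (1 - z) * hPrev + z * htil
  list(h = h, z = z, r = r, htil = htil, cz = cz, ch = ch, hPrev = hPrev)
}

gruStepBackward <- function(dh, cache, params) {
  h <- dim(cache$hPrev)[2L]
  z <- cache$z; r <- cache$r; htil <- cache$htil
  dz <- dh * (htil - cache$hPrev)
  dhtil <- dh * z
  dhPrev <- dh * (1 - z)
  dah <- dhtil * (1 - htil^2)
  dWh <- crossprod(cache$ch, dah)
  dbh <- colSums(dah)
  dch <- dah %*% t(params$Wh)
  drh <- dch[, seq_len(h), drop = FALSE]
  dxh <- dch[, -seq_len(h), drop = FALSE]
  dr <- drh * cache$hPrev
  dhPrev <- dhPrev + drh * r
  daz <- dz * z * (1 - z)
  dar <- dr * r * (1 - r)
  dWz <- crossprod(cache$cz, daz)
  dWr <- crossprod(cache$cz, dar)
  dcz <- daz %*% t(params$Wz) + dar %*% t(params$Wr)
  dhPrev <- dhPrev + dcz[, seq_len(h), drop = FALSE]
  dx <- dxh + dcz[, -seq_len(h), drop = FALSE]
  list(dx = dx, dhPrev = dhPrev,
       grads = list(Wz = dWz, bz = colSums(daz),
                    Wr = dWr, br = colSums(dar),
                    Wh = dWh, bh = dbh))
}

# X: (n, L, din); returns H (n, L, h). reverse=TRUE runs right-to-left but
# stores outputs at their own step index.
gruLayerForward <- function(X, params, reverse = FALSE) {
  d <- dim(X)
  n <- d[1L]; L <- d[2L]
  h <- ncol(params$Wz)
  H <- array(0, c(n, L, h))
  ht <- matrix(0, n, h)
  caches <- vector("list", L)
  order <- if (reverse) L:1 else 1:L
  for (t in order) {
    xt <- matrix(X[, t, ], n)
    st <- gruStep(xt, ht, params)
    ht <- st$h
    H[, t, ] <- ht
    caches[[t]] <- st
  }
  list(out = H, caches = caches, reverse = reverse)
}

gruLayerBackward <- function(dH, cache, params) {
  d <- dim(dH)
  n <- d[1L]; L <- d[2L]
  din <- nrow(params$Wz) - ncol(params$Wz)
  dX <- array(0, c(n, L, din))
  grads <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  dcarry <- matrix(0, n, ncol(params$Wz))
  order <- if (cache$reverse) 1:L else L:1
  for (t in order) {
    dht <- matrix(dH[, t, ], n) + dcarry
    bk <- gruStepBackward(dht, cache$caches[[t]], params)
    dX[, t, ] <- bk$dx
    dcarry <- bk$dhPrev
    for (nm in names(bk$grads)) grads[[nm]] <- grads[[nm]] + bk$grads[[nm]]
  }
  list(dX = dX, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

initBiGRU <- function(din, hidden, layers) {
  lapply(seq_len(layers), function(l) {
    d <- if (l == 1L) din else 2L * hidden
    list(fwd = initGRUCell(d, hidden), bwd = initGRUCell(d, hidden))
  })
}

#' Bidirectional GRU over a feature sequence
#'
#' Runs a forward-in-time and a backward-in-time GRU over each layer and
#' concatenates their hidden states per step, so every output step carries
#' information from both the past and the future. Layers beyond the first
#' consume the previous layer's concatenated output.
#'
#' @param X sequence array, n x L x d_in (batch, steps, features).
#' @param params list of per-layer parameter pairs as built by the model
#'   constructor (`fwd`/`bwd` GRU cells each).
#' @return list with `out` (n x L x 2*hidden) and the per-layer caches.
#' @export
biGRUForward <- function(X, params) {
  caches <- vector("list", length(params))
  inp <- X
  for (l in seq_along(params)) {
    fw <- gruLayerForward(inp, params[[l]]$fwd, reverse = FALSE)
    bw <- gruLayerForward(inp, params[[l]]$bwd, reverse = TRUE)
    d <- dim(fw$out)
    out <- array(0, c(d[1L], d[2L], 2L * d[3L]))
    out[, , seq_len(d[3L])] <- fw$out
    out[, , d[3L] + seq_len(d[3L])] <- bw$out
    caches[[l]] <- list(fwd = fw, bwd = bw, input = inp)
    inp <- out
  }
  list(out = inp, caches = caches)
}

biGRUBackward <- function(dOut, cache, params) {
  grads <- vector("list", length(params))
  d <- dOut
  for (l in rev(seq_along(params))) {
    h <- ncol(params[[l]]$fwd$Wz)
    dfw <- d[, , seq_len(h), drop = FALSE]
    dbw <- d[, , h + seq_len(h), drop = FALSE]
    bf <- gruLayerBackward(dfw, cache[[l]]$fwd, params[[l]]$fwd)
    bb <- gruLayerBackward(dbw, cache[[l]]$bwd, params[[l]]$bwd)
    grads[[l]] <- list(fwd = bf$grads, bwd = bb$grads)
    d <- bf$dX + bb$dX
  }
  list(dX = d, grads = grads)
}

## ---- layer norm, attention, feed-forward ---------------------------------

initLayerNorm <- function(d) list(gamma = rep(1, d), beta = numeric(d))

lnReshape <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L], d[3L])
  x
}

layerNormForward <- function(x, p, eps = 1e-5) {
  d <- dim(x)
  m <- lnReshape(x)
  mu <- rowMeans(m)
  v <- rowMeans(m^2) - mu^2
  invstd <- 1 / sqrt(v + eps)
  xhat <- (m - mu) * invstd
  y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  dim(y) <- d
  list(out = y, xhat = xhat, invstd = invstd, dims = d)
}

layerNormBackward <- function(dout, cache, p) {
  d <- cache$dims
  dy <- lnReshape(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  g <- sweep(dy, 2L, p$gamma, "*")
  dm <- cache$invstd * (g - rowMeans(g) - xhat * rowMeans(g * xhat))
  dim(dm) <- d
  list(dX = dm, grads = list(gamma = dgamma, beta = dbeta))
}

softmaxRows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

initMHA <- function(d) {
  list(Wq = glorot(d, d), bq = numeric(d),
       Wk = glorot(d, d), bk = numeric(d),
       Wv = glorot(d, d), bv = numeric(d),
       Wo = glorot(d, d), bo = numeric(d))
}

mhaForward <- function(X, p, nHeads) {
  d <- dim(X)                      # (n, L, dmodel)
  n <- d[1L]; L <- d[2L]; dm <- d[3L]
  dh <- dm %/% nHeads
  out <- array(0, d)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    Xi <- matrix(X[i, , ], L, dm)
    Q <- sweep(Xi %*% p$Wq, 2L, p$bq, "+")
    K <- sweep(Xi %*% p$Wk, 2L, p$bk, "+")
    V <- sweep(Xi %*% p$Wv, 2L, p$bv, "+")
    O <- matrix(0, L, dm)
    A <- vector("list", nHeads)
    for (h in seq_len(nHeads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
      A[[h]] <- softmaxRows(S)
      O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
    }
    out[i, , ] <- sweep(O %*% p$Wo, 2L, p$bo, "+")
    caches[[i]] <- list(Xi = Xi, Q = Q, K = K, V = V, A = A, O = O)
  }
  list(out = out, caches = caches, nHeads = nHeads, dh = dh)
}

mhaBackward <- function(dout, cache, p) {
  n <- length(cache$caches)
  nHeads <- cache$nHeads; dh <- cache$dh
  g <- lapply(p, function(x) array(0, dim(x) %||% length(x)))
  dX <- array(0, c(n, dim(cache$caches[[1L]]$Xi)))
  for (i in seq_len(n)) {
    ci <- cache$caches[[i]]
    L <- nrow(ci$Xi); dm <- ncol(ci$Xi)
    dYi <- matrix(dout[i, , ], L, dm)
    g$Wo <- g$Wo + crossprod(ci$O, dYi)
    g$bo <- g$bo + colSums(dYi)
    dO <- dYi %*% t(p$Wo)
    dQ <- matrix(0, L, dm); dK <- matrix(0, L, dm); dV <- matrix(0, L, dm)
    for (h in seq_len(nHeads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      A <- ci$A[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- dOh %*% t(ci$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(A * dA))
      dQ[, idx] <- dS %*% ci$K[, idx, drop = FALSE] / sqrt(dh)
      dK[, idx] <- crossprod(dS, ci$Q[, idx, drop = FALSE]) / sqrt(dh)
    }
    g$Wq <- g$Wq + crossprod(ci$Xi, dQ); g$bq <- g$bq + colSums(dQ)
    g$Wk <- g$Wk + crossprod(ci$Xi, dK); g$bk <- g$bk + colSums(dK)
    g$Wv <- g$Wv + crossprod(ci$Xi, dV); g$bv <- g$bv + colSums(dV)
    dX[i, , ] <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }
  list(dX = dX, grads = g)
}

initFFN <- function(d, dff) {
  list(W1 = glorot(d, dff), b1 = numeric(dff),
       W2 = glorot(dff, d), b2 = numeric(d))
}

ffnForward <- function(X, p) {
  d <- dim(X)
  m <- lnReshape(X)
  l1 <- linearForward(m, list(W = p$W1, b = p$b1))
  r <- reluForward(l1$out)
  l2 <- linearForward(r$out, list(W = p$W2, b = p$b2))
  y <- l2$out
  dim(y) <- d
  list(out = y, l1 = l1, r = r, l2 = l2, dims = d)
}

ffnBackward <- function(dout, cache, p) {
  dy <- lnReshape(dout)
  b2 <- linearBackward(dy, cache$l2, list(W = p$W2, b = p$b2))
  dr <- reluBackward(b2$dX, cache$r)
  b1 <- linearBackward(dr, cache$l1, list(W = p$W1, b = p$b1))
  dX <- b1$dX
  dim(dX) <- cache$dims
  list(dX = dX,
       grads = list(W1 = b1$grads$W, b1 = b1$grads$b,
                    W2 = b2$grads$W, b2 = b2$grads$b))
}

dropoutForward <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, mask = NULL))
  mask <- array(stats::runif(length(x)) >= p, dim(x)) / (1 - p)
  list(out = x * mask, mask = mask)
}

dropoutBackward <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

initEncoderLayer <- function(d, dff) {
  list(mha = initMHA(d), ln1 = initLayerNorm(d),
       ffn = initFFN(d, dff), ln2 = initLayerNorm(d))
}

# post-norm encoder layer: LN(x + MHA(x)) then LN(x + FFN(x))
encoderLayerForward <- function(X, p, nHeads, dropout = 0, train = FALSE) {
  a <- mhaForward(X, p$mha, nHeads)
  da <- dropoutForward(a$out, dropout, train)
  n1 <- layerNormForward(X + da$out, p$ln1)
  f <- ffnForward(n1$out, p$ffn)
  df <- dropoutForward(f$out, dropout, train)
  n2 <- layerNormForward(n1$out + df$out, p$ln2)
  list(out = n2$out, a = a, da = da, n1 = n1, f = f, df = df, n2 = n2)
}

encoderLayerBackward <- function(dout, cache, p) {
  b2 <- layerNormBackward(dout, cache$n2, p$ln2)
  dff <- dropoutBackward(b2$dX, cache$df)
  bf <- ffnBackward(dff, cache$f, p$ffn)
  dn1 <- b2$dX + bf$dX
  b1 <- layerNormBackward(dn1, cache$n1, p$ln1)
  datt <- dropoutBackward(b1$dX, cache$da)
  ba <- mhaBackward(datt, cache$a, p$mha)
  list(dX = b1$dX + ba$dX,
       grads = list(mha = ba$grads, ln1 = b1$grads,
                    ffn = bf$grads, ln2 = b2$grads))
}

## ---- loss and optimizer ---------------------------------------------------

softmaxCrossEntropy <- function(logits, y) {
  n <- nrow(logits)
  p <- softmaxRows(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y)] + eps))
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

# recursive walk over a nested parameter list, applying f(leafA, leafB)
paramWalk <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]]) || is.character(a[[nm]])) next
      out[[nm]] <- paramWalk(a[[nm]], if (is.list(b)) b[[nm]] else NULL, f)
    }
    out
  } else if (is.numeric(a)) {
    f(a, b)
  } else a
}

zeroLike <- function(params) paramWalk(params, NULL, function(a, b) a * 0)

adamInit <- function(params) {
  list(t = 0L, m = zeroLike(params), v = zeroLike(params))
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- paramWalk2(state$m, grads,
                        function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- paramWalk2(state$v, grads,
                        function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- paramWalk3(params, state$m, state$v, function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  list(params = params, state = state)
}

paramWalk2 <- function(a, b, f) {
  if (is.list(a)) {
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]]) || is.character(a[[nm]])) next
      a[[nm]] <- paramWalk2(a[[nm]], b[[nm]], f)
    }
    a
  } else if (is.numeric(a)) f(a, b) else a
}

paramWalk3 <- function(a, b, c3, f) {
  if (is.list(a)) {
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]]) || is.character(a[[nm]])) next
      a[[nm]] <- paramWalk3(a[[nm]], b[[nm]], c3[[nm]], f)
    }
    a
  } else if (is.numeric(a)) f(a, b, c3) else a
}

sumAbsParams <- function(params) {
  tot <- 0
  paramWalk(params, NULL, function(a, b) { tot <<- tot + sum(abs(a)); a })
  tot
}
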