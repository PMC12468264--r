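tinyConfig <- function(...) {
  modelConfig(inMaps = 3, nClasses = 2, convFilters = 4, poolOut = 2,
              gruHidden = 4, gruLayers = 2, tokenDim = 4, nHeads = 2,
              encoderLayers = 1, ffDim = 8, ...)
}

test_that("model config enforces divisibility invariants", {
  expect_error(modelConfig(inMaps = 8, nClasses = 2, tokenDim = 100,
                           nHeads = 8), "divisible by nHeads")
  expect_error(modelConfig(inMaps = 8, nClasses = 2, poolOut = 5,
                           gruHidden = 7, tokenDim = 4, nHeads = 2),
               "divisible by tokenDim")
  cfg <- modelConfig(inMaps = 8, nClasses = 2)
  expect_equal(cfg$ffDim, 512L)              # 4 * tokenDim default
})

test_that("forward pass reproduces every printed intermediate shape", {
  # two-channel intracranial configuration
  cfgB <- modelConfig(inMaps = 8, nClasses = 2, convFilters = 16)
  mB <- buildModel(cfgB, seed = 1)
  set.seed(2)
  fwB <- modelForward(mB, array(rnorm(51 * 9 * 8), c(51, 9, 8, 1)))
  expect_equal(fwB$shapes$input, c(8L, 51L, 9L))
  expect_equal(fwB$shapes$pooled, c(16L, 6L, 6L))
  expect_equal(fwB$shapes$sequence, c(6L, 96L))
  expect_equal(fwB$shapes$recurrent, c(6L, 1024L))
  expect_equal(fwB$shapes$tokens, c(48L, 128L))
  expect_equal(fwB$shapes$withCls, c(49L, 128L))
  expect_equal(fwB$shapes$encoded, c(49L, 128L))
  expect_equal(fwB$shapes$clsVector, 128L)
  expect_equal(fwB$shapes$logits, 2L)

  # seven-channel scalp configuration
  cfgT <- modelConfig(inMaps = 56, nClasses = 6, convFilters = 128)
  mT <- buildModel(cfgT, seed = 1)
  fwT <- modelForward(mT, array(rnorm(51 * 9 * 56), c(51, 9, 56, 1)))
  expect_equal(fwT$shapes$pooled, c(128L, 6L, 6L))
  expect_equal(fwT$shapes$sequence, c(6L, 768L))
  expect_equal(fwT$shapes$recurrent, c(6L, 1024L))
  expect_equal(fwT$shapes$withCls, c(49L, 128L))
  expect_equal(fwT$shapes$logits, 6L)
  expect_true(all(is.finite(fwT$logits)))

  expect_error(modelForward(mB, array(0, c(51, 9, 7, 1))), "maps")
})

test_that("convolution block preserves the mean of constant input", {
  cfg <- modelConfig(inMaps = 1, nClasses = 2, convFilters = 1,
                     poolOut = 2, gruHidden = 4, tokenDim = 4, nHeads = 2,
                     gruLayers = 1, encoderLayers = 1)
  m <- buildModel(cfg, seed = 3)
  # identity-like weights: single filter summing the center tap only
  m$params$conv$W[] <- 0
  m$params$conv$W[5, 1] <- 1                 # center of the 3x3 kernel
  m$params$conv$b[] <- 0
  m$params$bn$gamma[] <- 1
  m$params$bn$beta[] <- 0
  x <- array(1, c(6, 6, 1, 1))
  cb <- convBlock(x, m, train = FALSE)       # running stats: mean 0 var 1
  expect_true(all(abs(cb$out - cb$out[1]) < 1e-12))  # constant pooled output
})

test_that("pooled maps become a time-major feature sequence", {
  maps <- array(rnorm(6 * 6 * 16 * 2), c(6, 6, 16, 2))
  s <- mapsToSequence(maps)
  expect_equal(dim(s), c(2L, 6L, 96L))
  # feature index (filter-1)*P + freq
  expect_equal(s[2, 3, (5 - 1) * 6 + 4], maps[4, 3, 5, 2])

  big <- mapsToSequence(array(0, c(6, 6, 128, 1)))
  expect_equal(dim(big), c(1L, 6L, 768L))

  # constant maps give identical steps
  cm <- mapsToSequence(array(2, c(3, 3, 4, 1)))
  expect_true(all(cm[1, 1, ] == cm[1, 2, ]))
})

test_that("gruStep matches hand-evaluated gate equations", {
  # fixed 2-dim weights, x = [1, 0], h = [0, 0]
  p <- list(Wz = matrix(c(0.1, -0.2, 0.3, 0.4,
                          0.5, 0.6, -0.7, 0.8), 4, 2), bz = c(0.05, -0.05),
            Wr = matrix(c(-0.3, 0.2, 0.1, -0.1,
                          0.4, -0.5, 0.6, 0.7), 4, 2), br = c(0, 0.1),
            Wh = matrix(c(0.2, 0.3, -0.4, 0.5,
                          -0.6, 0.7, 0.8, -0.9), 4, 2), bh = c(0.1, 0))
  x <- c(1, 0); h <- c(0, 0)
  st <- gruStep(x, h, p)
  # independent scalar evaluation: concat [h, x] = (0, 0, 1, 0)
  sig <- function(v) 1 / (1 + exp(-v))
  cz <- c(0, 0, 1, 0)
  z <- sig(cz %*% p$Wz + p$bz)
  r <- sig(cz %*% p$Wr + p$br)
  ch <- c(r * h, x)
  htil <- tanh(ch %*% p$Wh + p$bh)
  hExp <- (1 - z) * h + z * htil
  expect_equal(as.numeric(st$h), as.numeric(hExp), tolerance = 1e-12)
  expect_true(all(st$z >= 0 & st$z <= 1))
  expect_true(all(st$r >= 0 & st$r <= 1))

  # forced z = 0 keeps the previous state; z = 1 takes the candidate
  p0 <- p; p0$bz <- c(-40, -40)
  hPrev <- matrix(c(0.3, -0.2), 1)
  expect_equal(gruStep(matrix(x, 1), hPrev, p0)$h, hPrev, tolerance = 1e-12)
  p1 <- p; p1$bz <- c(40, 40)
  s1 <- gruStep(matrix(x, 1), hPrev, p1)
  expect_equal(s1$h, s1$htil, tolerance = 1e-12)
  expect_true(all(abs(s1$h) <= 1))
})

test_that("bidirectional GRU concatenates directions and mirrors palindromes", {
  set.seed(6)
  params <- list(list(fwd = mvmdnet:::initGRUCell(3, 4),
                      bwd = mvmdnet:::initGRUCell(3, 4)))
  X <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  out <- biGRUForward(X, params)$out
  expect_equal(dim(out), c(2L, 5L, 8L))

  # palindromic input with tied weights: h_fwd(t) == h_bwd(L+1-t)
  p <- mvmdnet:::initGRUCell(2, 3)
  Xp <- array(0, c(1, 5, 2))
  base <- matrix(rnorm(10), 5, 2)
  pal <- (base + base[5:1, ]) / 2            # x_t == x_{L+1-t}
  Xp[1, , ] <- pal
  fw <- mvmdnet:::gruLayerForward(Xp, p, reverse = FALSE)$out
  bw <- mvmdnet:::gruLayerForward(Xp, p, reverse = TRUE)$out
  for (t in 1:5)
    expect_equal(fw[1, t, ], bw[1, 5 + 1 - t, ], tolerance = 1e-12)

  # single-step sequence: both directions see the same element
  X1 <- array(rnorm(1 * 1 * 2), c(1, 1, 2))
  f1 <- mvmdnet:::gruLayerForward(X1, p, reverse = FALSE)$out
  b1 <- mvmdnet:::gruLayerForward(X1, p, reverse = TRUE)$out
  expect_equal(f1, b1)
})

test_that("token reshape is an exact row-major round trip", {
  set.seed(7)
  H <- array(rnorm(3 * 6 * 8), c(3, 6, 8))
  tk <- reshapeTokens(H, 4)
  expect_equal(dim(tk), c(3L, 12L, 4L))
  # row-major: token 1 of sample 1 is the first 4 features of step 1
  expect_equal(tk[1, 1, ], H[1, 1, 1:4])
  expect_equal(tk[1, 2, ], H[1, 1, 5:8])
  expect_equal(tk[1, 3, ], H[1, 2, 1:4])
  back <- mvmdnet:::reshapeTokensBackward(tk, dim(H))
  expect_identical(back, H)

  # (6, 1024) with width 128 -> 48 tokens
  H2 <- array(rnorm(1 * 6 * 1024), c(1, 6, 1024))
  expect_equal(dim(reshapeTokens(H2, 128)), c(1L, 48L, 128L))
  # (1, 128) -> a single identity token
  H3 <- array(rnorm(1 * 1 * 128), c(1, 1, 128))
  t3 <- reshapeTokens(H3, 128)
  expect_equal(t3[1, 1, ], H3[1, 1, ])
  expect_error(reshapeTokens(H, 5), "divisible")
})

test_that("positional encoding has the sinusoidal structure", {
  pe <- positionalEncoding(49, 128)
  expect_equal(dim(pe), c(49L, 128L))
  expect_true(all(pe >= -1 & pe <= 1))
  expect_equal(pe[1, seq(1, 127, by = 2)], rep(0, 64))   # sin 0
  expect_equal(pe[1, seq(2, 128, by = 2)], rep(1, 64))   # cos 0
  # spot-check the definition at pos 5, dim pair i = 3
  expect_equal(pe[6, 7], sin(5 / 10000^(6 / 128)))
  expect_equal(pe[6, 8], cos(5 / 10000^(6 / 128)))
})

test_that("class token is prepended and positions added everywhere", {
  set.seed(8)
  tk <- array(rnorm(2 * 48 * 128), c(2, 48, 128))
  cls <- rnorm(128)
  ac <- addClsAndPositions(tk, cls)
  expect_equal(dim(ac$out), c(2L, 49L, 128L))
  pe <- positionalEncoding(49, 128)
  expect_equal(ac$out[1, 1, ], cls + pe[1, ])
  expect_equal(ac$out[2, 10, ], tk[2, 9, ] + pe[10, ])
})

test_that("attention rows are stochastic and the encoder is shape-preserving", {
  set.seed(9)
  d <- 8; L <- 6
  p <- mvmdnet:::initMHA(d)
  X <- array(rnorm(2 * L * d), c(2, L, d))
  mh <- mvmdnet:::mhaForward(X, p, nHeads = 2)
  for (h in 1:2)
    expect_equal(rowSums(mh$caches[[1]]$A[[h]]), rep(1, L), tolerance = 1e-12)

  layers <- list(mvmdnet:::initEncoderLayer(d, 16))
  te <- transformerEncode(X, layers, nHeads = 2)
  expect_equal(dim(te$out), dim(X))
  # (49, 128) in -> (49, 128) out at full size
  layersBig <- list(mvmdnet:::initEncoderLayer(128, 512))
  Xb <- array(rnorm(1 * 49 * 128), c(1, 49, 128))
  expect_equal(dim(transformerEncode(Xb, layersBig, nHeads = 8)$out),
               c(1L, 49L, 128L))
})

test_that("permuting non-CLS tokens permutes encoder outputs correspondingly", {
  set.seed(10)
  d <- 8; L <- 7
  layers <- list(mvmdnet:::initEncoderLayer(d, 16))
  X <- array(rnorm(1 * L * d), c(1, L, d))
  out <- transformerEncode(X, layers, nHeads = 2)$out
  perm <- c(1, 5, 3, 2, 6, 4, 7)             # keep index 1 (CLS) fixed
  Xp <- X[, perm, , drop = FALSE]
  outP <- transformerEncode(Xp, layers, nHeads = 2)$out
  expect_equal(outP[1, , ], out[1, perm, ], tolerance = 1e-10)
})

test_that("classification head returns proper probabilities", {
  set.seed(11)
  tokens <- array(rnorm(3 * 5 * 8), c(3, 5, 8))
  head <- mvmdnet:::initLinear(8, 4)
  pr <- classifyTokens(tokens, head)
  expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-6)
  expect_true(all(pr >= 0))
  # zero logits -> uniform
  head0 <- list(W = matrix(0, 8, 4), b = rep(0, 4))
  expect_equal(classifyTokens(tokens, head0),
               matrix(0.25, 3, 4), ignore_attr = TRUE)
})

test_that("analytic gradients match finite differences through all stages", {
  model <- buildModel(tinyConfig(), seed = 42)
  set.seed(9)
  X <- array(rnorm(7 * 5 * 3 * 3), c(7, 5, 3, 3))
  y <- c(1L, 2L, 1L)
  lg <- modelLossGrad(model, X, y, train = TRUE)
  getv <- function(obj, path) { for (p in path) obj <- obj[[p]]; obj }
  setv <- function(obj, path, val) {
    if (length(path) == 1) { obj[[path[[1]]]] <- val; return(obj) }
    obj[[path[[1]]]] <- setv(obj[[path[[1]]]], path[-1], val)
    obj
  }
  numGrad <- function(path, idx, eps = 1e-5) {
    v <- getv(model$params, path)
    vp <- v; vp[idx] <- vp[idx] + eps
    vm <- v; vm[idx] <- vm[idx] - eps
    mp <- model; mp$params <- setv(model$params, path, vp)
    mm <- model; mm$params <- setv(model$params, path, vm)
    (modelLossGrad(mp, X, y, train = TRUE)$loss -
       modelLossGrad(mm, X, y, train = TRUE)$loss) / (2 * eps)
  }
  checks <- list(
    list(list("conv", "W"), 5), list(list("bn", "gamma"), 3),
    list(list("bigru", 1L, "fwd", "Wz"), 7),
    list(list("bigru", 2L, "bwd", "Wh"), 11),
    list(list("projRes", "W"), 4), list(list("cls"), 2),
    list(list("encoder", 1L, "mha", "Wq"), 6),
    list(list("encoder", 1L, "ffn", "W1"), 13),
    list(list("encoder", 1L, "ln2", "beta"), 3),
    list(list("head", "W"), 2))
  for (ch in checks) {
    ga <- getv(lg$grads, ch[[1]])[ch[[2]]]
    gn <- numGrad(ch[[1]], ch[[2]])
    expect_equal(ga, gn, tolerance = 1e-5,
                 label = paste(unlist(ch[[1]]), collapse = "$"))
  }
})

test_that("every ablation variant is constructible and runs", {
  set.seed(12)
  X <- array(rnorm(51 * 9 * 4 * 2), c(51, 9, 4, 2))
  variants <- list(full = c(TRUE, TRUE, TRUE, TRUE),
                   noCNN = c(FALSE, TRUE, TRUE, TRUE),
                   noBiGRU = c(TRUE, FALSE, TRUE, TRUE),
                   noTransformer = c(TRUE, TRUE, FALSE, TRUE),
                   noResidual = c(TRUE, TRUE, TRUE, FALSE))
  for (nm in names(variants)) {
    v <- variants[[nm]]
    cfg <- modelConfig(inMaps = 4, nClasses = 2, convFilters = 4,
                       poolOut = 3, gruHidden = 8, tokenDim = 8, nHeads = 2,
                       encoderLayers = 1, gruLayers = 1,
                       useCNN = v[1], useBiGRU = v[2], useTransformer = v[3],
                       useResidual = v[4])
    m <- buildModel(cfg, seed = 5)
    fw <- modelForward(m, X)
    expect_equal(dim(fw$logits), c(2L, 2L), label = nm)
    expect_true(all(is.finite(fw$logits)), label = nm)
    # backward also runs on every variant
    lg <- modelLossGrad(m, X, c(1L, 2L), train = TRUE)
    expect_true(is.finite(lg$loss), label = nm)
  }
})

test_that("checkpoints round-trip weights and configuration", {
  model <- buildModel(tinyConfig(), seed = 13)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(model, f)
  m2 <- loadCheckpoint(f)
  expect_equal(m2$config, model$config)
  expect_identical(m2$params, model$params)
  set.seed(14)
  X <- array(rnorm(7 * 5 * 3 * 2), c(7, 5, 3, 2))
  expect_identical(modelForward(model, X)$logits,
                   modelForward(m2, X)$logits)
  expect_error(loadCheckpoint({
    g <- tempfile(); saveRDS(list(a = 1), g); g
  }), "checkpoint")
})
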