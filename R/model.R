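#' Classifier architecture configuration
#'
#' Hyperparameters of the spatial-temporal classifier: a 2-D
#' convolution block (conv + batch norm + ReLU + adaptive average
#' pooling), a stacked bidirectional GRU, token reshaping with a learned
#' class token and sinusoidal positions, a Transformer encoder, and a
#' dense head. The `use*` switches construct the ablation variants: each
#' disabled stage is bypassed with a dimension-matching projection so
#' every variant runs end to end.
#'
#' The study defaults are `convFilters = 16` (two-channel intracranial
#' task) or 128 (seven-channel scalp task), kernel 3, padding 1, adaptive
#' pool output 6, GRU hidden size 512 with 2 layers, token width 128,
#' 8 attention heads and 3 encoder layers.
#'
#' @param inMaps number of input maps, K modes x C channels.
#' @param nClasses number of output classes (>= 2).
#' @param convFilters convolution filter count.
#' @param kernel convolution kernel size (odd).
#' @param padding convolution zero padding.
#' @param poolOut adaptive-pool output edge length P (maps become P x P).
#' @param gruHidden hidden units per GRU direction.
#' @param gruLayers stacked bidirectional GRU layers.
#' @param tokenDim token width fed to the encoder; must divide
#'   `poolOut * 2 * gruHidden` and be divisible by `nHeads` (and even,
#'   for the sinusoidal positions).
#' @param nHeads attention heads.
#' @param encoderLayers Transformer encoder layers.
#' @param ffDim encoder feed-forward width; default `4 * tokenDim`.
#' @param useCNN,useBiGRU,useTransformer,useResidual ablation switches.
#' @param dropout dropout probability inside the encoder sub-blocks
#'   (0 disables; kept as a configuration hook).
#' @return a list of class `"ModelConfig"`.
#' @export
modelConfig <- function(inMaps, nClasses, convFilters = 16L, kernel = 3L,
                        padding = 1L, poolOut = 6L, gruHidden = 512L,
                        gruLayers = 2L, tokenDim = 128L, nHeads = 8L,
                        encoderLayers = 3L, ffDim = NULL,
                        useCNN = TRUE, useBiGRU = TRUE,
                        useTransformer = TRUE, useResidual = TRUE,
                        dropout = 0) {
  if (is.null(ffDim)) ffDim <- 4L * tokenDim
  stopifnot(inMaps >= 1, nClasses >= 2, convFilters >= 1, kernel %% 2 == 1,
            poolOut >= 1, gruHidden >= 1, gruLayers >= 1, tokenDim >= 2,
            nHeads >= 1, encoderLayers >= 1, ffDim >= 1,
            dropout >= 0, dropout < 1)
  if (tokenDim %% nHeads != 0)
    stop("tokenDim must be divisible by nHeads")
  if (tokenDim %% 2 != 0)
    stop("tokenDim must be even (sinusoidal position pairs)")
  if ((poolOut * 2L * gruHidden) %% tokenDim != 0)
    stop("poolOut * 2 * gruHidden must be divisible by tokenDim")
  structure(list(inMaps = as.integer(inMaps), nClasses = as.integer(nClasses),
                 convFilters = as.integer(convFilters),
                 kernel = as.integer(kernel), padding = as.integer(padding),
                 poolOut = as.integer(poolOut),
                 gruHidden = as.integer(gruHidden),
                 gruLayers = as.integer(gruLayers),
                 tokenDim = as.integer(tokenDim), nHeads = as.integer(nHeads),
                 encoderLayers = as.integer(encoderLayers),
                 ffDim = as.integer(ffDim),
                 useCNN = isTRUE(useCNN), useBiGRU = isTRUE(useBiGRU),
                 useTransformer = isTRUE(useTransformer),
                 useResidual = isTRUE(useResidual), dropout = dropout),
            class = "ModelConfig")
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  expr
}

#' Build a classifier with freshly initialized weights
#'
#' Allocates all weight matrices for the configured architecture
#' (Glorot-uniform linear and recurrent weights, unit batch-norm gains,
#' a near-zero learned class token) using the given seed.
#'
#' @param cfg a [modelConfig()].
#' @param seed integer seed for the weight initialization.
#' @return a list of class `"MVMDNetModel"` with elements `config`,
#'   `params` and `buffers` (batch-norm running statistics).
#' @export
buildModel <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "ModelConfig"))
  withSeed(seed, {
    params <- list()
    buffers <- list()
    seqDimIn <- if (cfg$useCNN) cfg$convFilters * cfg$poolOut
                else cfg$inMaps * cfg$poolOut
    seqDim <- cfg$convFilters * cfg$poolOut
    if (cfg$useCNN) {
      params$conv <- initConv(cfg$inMaps, cfg$convFilters, cfg$kernel)
      params$bn <- initBatchNorm(cfg$convFilters)
      buffers$bn <- initBatchNormBuffers(cfg$convFilters)
    } else {
      params$projNoCNN <- initLinear(seqDimIn, seqDim)
    }
    if (cfg$useBiGRU) {
      params$bigru <- initBiGRU(seqDim, cfg$gruHidden, cfg$gruLayers)
      if (cfg$useResidual)
        params$projRes <- initLinear(seqDim, 2L * cfg$gruHidden)
    } else {
      params$projNoGRU <- initLinear(seqDim, 2L * cfg$gruHidden)
    }
    params$cls <- stats::rnorm(cfg$tokenDim, 0, 0.02)
    if (cfg$useTransformer) {
      params$encoder <- lapply(seq_len(cfg$encoderLayers), function(i)
        initEncoderLayer(cfg$tokenDim, cfg$ffDim))
    }
    params$head <- initLinear(cfg$tokenDim, cfg$nClasses)
    structure(list(config = cfg, params = params, buffers = buffers),
              class = "MVMDNetModel")
  })
}

#' @export
print.MVMDNetModel <- function(x, ...) {
  cfg <- x$config
  cat("MVMDNetModel\n")
  cat(sprintf(" input maps %d -> conv %s -> pool %dx%d -> BiGRU %s -> tokens %d-wide -> encoder %s -> %d classes\n",
              cfg$inMaps,
              if (cfg$useCNN) paste0(cfg$convFilters, " filters") else "off",
              cfg$poolOut, cfg$poolOut,
              if (cfg$useBiGRU) paste0(cfg$gruHidden, "x", cfg$gruLayers)
              else "off",
              cfg$tokenDim,
              if (cfg$useTransformer) paste0(cfg$encoderLayers, " layers")
              else "off"))
  cat(sprintf(" residual skips: %s; parameters: %.3g\n",
              if (cfg$useResidual) "on" else "off",
              sumAbsParams(zeroLike(x$params) |>
                             paramWalk(NULL, function(a, b) a + 1))))
  invisible(x)
}

## ---- stage plumbing --------------------------------------------------------

#' Convolution block: conv + batch norm + ReLU + adaptive average pool
#'
#' Applies a single stride-1 2-D convolution (spatial size preserved with
#' `padding = (kernel-1)/2`), batch normalization, ReLU, then adaptive
#' average pooling onto a `poolOut x poolOut` grid of near-equal cells.
#'
#' @param x input array (F, T, inMaps, n).
#' @param model an `MVMDNetModel` built with `useCNN = TRUE`.
#' @param train use batch statistics (TRUE) or running statistics.
#' @return list with `out` (poolOut, poolOut, convFilters, n), the
#'   stage caches and possibly updated batch-norm buffers.
#' @export
convBlock <- function(x, model, train = FALSE) {
  cfg <- model$config
  cv <- conv2dForward(x, model$params$conv, cfg$kernel, cfg$padding)
  bn <- batchNormForward(cv$out, model$params$bn, model$buffers$bn, train)
  rl <- reluForward(bn$out)
  pl <- adaptiveAvgPoolForward(rl$out, cfg$poolOut)
  list(out = pl$out, cv = cv, bn = bn, rl = rl, pl = pl,
       buffers = list(bn = bn$buffers))
}

#' Pooled maps to a feature sequence
#'
#' The pooled time-frame axis becomes the step axis; each step's feature
#' vector stacks (filter, pooled-frequency) pairs filter-major. A
#' (P, P, filters, n) stack therefore becomes an n x P x (filters*P)
#' sequence array, e.g. (16, 6, 6) maps to 6 steps of 96 features.
#'
#' @param maps array (poolFreq, poolTime, filters, n).
#' @return sequence array (n, poolTime, filters * poolFreq).
#' @export
mapsToSequence <- function(maps) {
  d <- dim(maps)                   # (Pf, Pt, C, n)
  b <- aperm(maps, c(1L, 3L, 2L, 4L))   # (Pf, C, Pt, n)
  dim(b) <- c(d[1L] * d[3L], d[2L], d[4L])
  aperm(b, c(3L, 2L, 1L))          # (n, Pt, Pf*C)
}

mapsToSequenceBackward <- function(dSeq, mapDims) {
  b <- aperm(dSeq, c(3L, 2L, 1L))
  dim(b) <- c(mapDims[1L], mapDims[3L], mapDims[2L], mapDims[4L])
  aperm(b, c(1L, 3L, 2L, 4L))
}

seqLinearForward <- function(X, p) {
  d <- dim(X)
  m <- X
  dim(m) <- c(d[1L] * d[2L], d[3L])
  lf <- linearForward(m, p)
  out <- lf$out
  dim(out) <- c(d[1L], d[2L], ncol(p$W))
  list(out = out, lf = lf, dims = d)
}

seqLinearBackward <- function(dY, cache, p) {
  dm <- dY
  d <- dim(dY)
  dim(dm) <- c(d[1L] * d[2L], d[3L])
  bk <- linearBackward(dm, cache$lf, p)
  dX <- bk$dX
  dim(dX) <- cache$dims
  list(dX = dX, grads = bk$grads)
}

#' Re-chunk a hidden-state sequence into fixed-width tokens
#'
#' Row-major flattens each sample's L x d hidden matrix and re-chunks it
#' into tokens of width `tokenDim`; a (6, 1024) output becomes 48 tokens
#' of width 128. The round trip is exact.
#'
#' @param H array (n, L, d) with `L * d` divisible by `tokenDim`.
#' @param tokenDim token width.
#' @return array (n, L*d/tokenDim, tokenDim).
#' @export
reshapeTokens <- function(H, tokenDim) {
  d <- dim(H)
  if ((d[2L] * d[3L]) %% tokenDim != 0)
    stop("sequence element count not divisible by tokenDim")
  v <- aperm(H, c(3L, 2L, 1L))     # (d, L, n); d fastest = row-major in (L,d)
  dim(v) <- c(tokenDim, d[2L] * d[3L] %/% tokenDim, d[1L])
  aperm(v, c(3L, 2L, 1L))
}

reshapeTokensBackward <- function(dT, seqDims) {
  v <- aperm(dT, c(3L, 2L, 1L))
  dim(v) <- c(seqDims[3L], seqDims[2L], seqDims[1L])
  aperm(v, c(3L, 2L, 1L))
}

#' Sinusoidal positional encoding
#'
#' `PE(pos, 2i) = sin(pos / 10000^(2i/d))`,
#' `PE(pos, 2i+1) = cos(pos / 10000^(2i/d))`, positions 0-based. All
#' values lie in [-1, 1]; position 0 has zeros in the even (sine) and
#' ones in the odd (cosine) dimensions.
#'
#' @param L number of positions.
#' @param d encoding width (even).
#' @return L x d matrix.
#' @export
positionalEncoding <- function(L, d) {
  stopifnot(d %% 2 == 0)
  pos <- 0:(L - 1)
  pe <- matrix(0, L, d)
  for (i in 0:(d %/% 2 - 1)) {
    div <- 10000^(2 * i / d)
    pe[, 2L * i + 1L] <- sin(pos / div)
    pe[, 2L * i + 2L] <- cos(pos / div)
  }
  pe
}

#' Prepend the class token and add positional encodings
#'
#' The learned class token is inserted at index 1 of every sample's
#' token sequence (position 0 of the encoding), then the sinusoidal
#' positional encoding is added to every token including the class token.
#'
#' @param tokens array (n, L, d).
#' @param clsToken learned class-token vector of length d.
#' @return list with `out` (n, L+1, d) and the dimensions cached for the
#'   backward pass.
#' @export
addClsAndPositions <- function(tokens, clsToken) {
  d <- dim(tokens)
  n <- d[1L]; L <- d[2L]; td <- d[3L]
  stopifnot(length(clsToken) == td)
  out <- array(0, c(n, L + 1L, td))
  out[, 1L, ] <- matrix(clsToken, n, td, byrow = TRUE)
  out[, -1L, ] <- tokens
  pe <- positionalEncoding(L + 1L, td)
  out <- out + aperm(array(pe, c(L + 1L, td, n)), c(3L, 1L, 2L))
  list(out = out, dims = d)
}

addClsBackward <- function(dOut) {
  list(dTokens = dOut[, -1L, , drop = FALSE],
       dCls = colSums(matrix(dOut[, 1L, ], nrow = dim(dOut)[1L])))
}

#' Transformer encoder over a token sequence
#'
#' Applies `length(layers)` post-norm encoder layers (multi-head
#' self-attention + position-wise feed-forward, each with an internal
#' residual and layer norm). With `outerResidual = TRUE` the encoder
#' input sequence is added to the final output (shape is preserved
#' throughout).
#'
#' @param tokens array (n, L, d).
#' @param layers encoder parameter list (one element per layer).
#' @param nHeads attention heads (d divisible by nHeads).
#' @param dropout dropout probability inside the sub-blocks.
#' @param train training mode (enables dropout).
#' @param outerResidual add the encoder input to the encoder output.
#' @return list with `out` (n, L, d) and per-layer caches.
#' @export
transformerEncode <- function(tokens, layers, nHeads, dropout = 0,
                              train = FALSE, outerResidual = FALSE) {
  x <- tokens
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    el <- encoderLayerForward(x, layers[[l]], nHeads, dropout, train)
    caches[[l]] <- el
    x <- el$out
  }
  if (outerResidual) x <- x + tokens
  list(out = x, caches = caches, outerResidual = outerResidual)
}

transformerBackward <- function(dOut, cache, layers) {
  grads <- vector("list", length(layers))
  dx <- dOut
  for (l in rev(seq_along(layers))) {
    bk <- encoderLayerBackward(dx, cache$caches[[l]], layers[[l]])
    grads[[l]] <- bk$grads
    dx <- bk$dX
  }
  if (cache$outerResidual) dx <- dx + dOut
  list(dX = dx, grads = grads)
}

#' Class probabilities from a token sequence
#'
#' Maps the class-token embedding (index 1) through the dense head and a
#' softmax. Probabilities are nonnegative and sum to 1 per sample.
#'
#' @param tokens array (n, L, d) including the class token at index 1.
#' @param head dense-head parameters (`W` d x nClasses, `b`).
#' @param useCls read the class token (TRUE) or the mean of the other
#'   tokens (used when the encoder stage is ablated).
#' @return n x nClasses matrix of probabilities.
#' @export
classifyTokens <- function(tokens, head, useCls = TRUE) {
  feat <- if (useCls) matrix(tokens[, 1L, ], nrow = dim(tokens)[1L])
          else apply(tokens[, -1L, , drop = FALSE], c(1L, 3L), mean)
  softmaxRows(linearForward(feat, head)$out)
}

## ---- full forward / backward ----------------------------------------------

#' Full forward pass of the classifier
#'
#' Runs a batch of feature tensors through the configured stages and
#' returns logits, the printed shape of every intermediate, and (for
#' training) the caches needed by the backward pass.
#'
#' @param model an `MVMDNetModel`.
#' @param X input array (F, T, inMaps, n).
#' @param train training mode (batch-norm batch statistics, dropout).
#' @return list with `logits` (n x nClasses), `shapes` (named list of
#'   intermediate dimensions, batch axis omitted), `cache`, and updated
#'   `buffers`.
#' @export
modelForward <- function(model, X, train = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- dim(X)
  stopifnot(length(d) == 4L)
  if (d[3L] != cfg$inMaps)
    stop(sprintf("input has %d maps; model expects %d", d[3L], cfg$inMaps))
  shapes <- list(input = c(cfg$inMaps, d[1L], d[2L]))
  cache <- list(inDims = d)
  buffers <- model$buffers

  if (cfg$useCNN) {
    cb <- convBlock(X, model, train)
    buffers <- cb$buffers
    maps <- cb$out
    cache$cb <- cb
  } else {
    pl <- adaptiveAvgPoolForward(X, cfg$poolOut)
    maps <- pl$out
    cache$pl <- pl
  }
  shapes$pooled <- dim(maps)[c(3L, 1L, 2L)]
  cache$mapDims <- dim(maps)

  seq0 <- mapsToSequence(maps)
  if (!cfg$useCNN) {
    pj <- seqLinearForward(seq0, p$projNoCNN)
    seqIn <- pj$out
    cache$pj <- pj
  } else seqIn <- seq0
  cache$seq0Dims <- dim(seq0)
  shapes$sequence <- dim(seqIn)[2:3]

  if (cfg$useBiGRU) {
    bg <- biGRUForward(seqIn, p$bigru)
    H <- bg$out
    cache$bg <- bg
    if (cfg$useResidual) {
      pr <- seqLinearForward(seqIn, p$projRes)
      H <- H + pr$out
      cache$pr <- pr
    }
  } else {
    pg <- seqLinearForward(seqIn, p$projNoGRU)
    H <- pg$out
    cache$pg <- pg
  }
  shapes$recurrent <- dim(H)[2:3]
  cache$seqDims <- dim(H)

  tk <- reshapeTokens(H, cfg$tokenDim)
  shapes$tokens <- dim(tk)[2:3]
  ac <- addClsAndPositions(tk, p$cls)
  cache$ac <- ac
  shapes$withCls <- dim(ac$out)[2:3]

  if (cfg$useTransformer) {
    te <- transformerEncode(ac$out, p$encoder, cfg$nHeads, cfg$dropout,
                            train, outerResidual = cfg$useResidual)
    enc <- te$out
    cache$te <- te
  } else enc <- ac$out
  shapes$encoded <- dim(enc)[2:3]
  cache$encDims <- dim(enc)

  feat <- if (cfg$useTransformer) matrix(enc[, 1L, ], nrow = d[4L])
          else apply(enc[, -1L, , drop = FALSE], c(1L, 3L), mean)
  shapes$clsVector <- ncol(feat)
  hd <- linearForward(feat, p$head)
  cache$hd <- hd
  shapes$logits <- ncol(hd$out)

  list(logits = hd$out, shapes = shapes, cache = cache, buffers = buffers)
}

modelBackward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  n <- cache$inDims[4L]

  bh <- linearBackward(dlogits, cache$hd, p$head)
  grads$head <- bh$grads
  dfeat <- bh$dX

  dEnc <- array(0, cache$encDims)
  if (cfg$useTransformer) {
    dEnc[, 1L, ] <- dfeat
    tb <- transformerBackward(dEnc, cache$te, p$encoder)
    grads$encoder <- tb$grads
    dAc <- tb$dX
  } else {
    L <- cache$encDims[2L] - 1L
    for (j in seq_len(L) + 1L) dEnc[, j, ] <- dfeat / L
    dAc <- dEnc
  }

  cb <- addClsBackward(dAc)
  grads$cls <- cb$dCls
  dH <- reshapeTokensBackward(cb$dTokens, cache$seqDims)

  if (cfg$useBiGRU) {
    if (cfg$useResidual) {
      rb <- seqLinearBackward(dH, cache$pr, p$projRes)
      grads$projRes <- rb$grads
      dSeqRes <- rb$dX
    } else dSeqRes <- 0
    gb <- biGRUBackward(dH, cache$bg$caches, p$bigru)
    grads$bigru <- gb$grads
    dSeqIn <- gb$dX + dSeqRes
  } else {
    gb <- seqLinearBackward(dH, cache$pg, p$projNoGRU)
    grads$projNoGRU <- gb$grads
    dSeqIn <- gb$dX
  }

  if (!cfg$useCNN) {
    jb <- seqLinearBackward(dSeqIn, cache$pj, p$projNoCNN)
    grads$projNoCNN <- jb$grads
    dSeq0 <- jb$dX
  } else dSeq0 <- dSeqIn

  dMaps <- mapsToSequenceBackward(dSeq0, cache$mapDims)

  if (cfg$useCNN) {
    dRelu <- adaptiveAvgPoolBackward(dMaps, cache$cb$pl)
    dBn <- reluBackward(dRelu, cache$cb$rl)
    bb <- batchNormBackward(dBn, cache$cb$bn, p$bn)
    grads$bn <- bb$grads
    vb <- conv2dBackward(bb$dX, cache$cb$cv, p$conv)
    grads$conv <- vb$grads
  } else {
    adaptiveAvgPoolBackward(dMaps, cache$pl)   # input gradient unused
  }
  grads[names(p)[!names(p) %in% names(grads)]] <- NULL
  grads[order(match(names(grads), names(p)))]
}

#' Loss and parameter gradients for one batch
#'
#' Softmax cross-entropy on the forward logits plus the full backward
#' pass. The mean loss over the batch is returned with gradients shaped
#' exactly like `model$params`.
#'
#' @param model an `MVMDNetModel`.
#' @param X input array (F, T, inMaps, n).
#' @param y integer class labels in 1..nClasses, length n.
#' @param train training mode.
#' @return list with `loss`, `grads`, `probs`, updated `buffers`.
#' @export
modelLossGrad <- function(model, X, y, train = TRUE) {
  fw <- modelForward(model, X, train = train)
  ce <- softmaxCrossEntropy(fw$logits, y)
  grads <- modelBackward(model, fw$cache, ce$dlogits)
  list(loss = ce$loss, grads = grads, probs = ce$probs,
       buffers = fw$buffers)
}

#' Predict class probabilities
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no
#' dropout).
#'
#' @param model an `MVMDNetModel`.
#' @param X input array (F, T, inMaps, n).
#' @return list with `probs` (n x nClasses) and `classes` (integer).
#' @export
modelPredict <- function(model, X) {
  fw <- modelForward(model, X, train = FALSE)
  probs <- softmaxRows(fw$logits)
  list(probs = probs, classes = max.col(probs, ties.method = "first"))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing list (package name and version,
#' architecture configuration, weights, batch-norm buffers) serialized
#' with `saveRDS`. `loadCheckpoint` restores a ready-to-use model and
#' round-trips every hyperparameter.
#'
#' @param model an `MVMDNetModel`.
#' @param path file path.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   returns the model.
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(package = "mvmdnet",
              version = as.character(utils::packageVersion("mvmdnet")),
              config = unclass(model$config),
              params = model$params,
              buffers = model$buffers)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$package, "mvmdnet"))
    stop("not an mvmdnet checkpoint: ", path)
  cfg <- do.call(modelConfig, obj$config[setdiff(names(obj$config), NULL)])
  structure(list(config = cfg, params = obj$params, buffers = obj$buffers),
            class = "MVMDNetModel")
}
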