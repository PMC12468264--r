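#' Training configuration
#'
#' Optimizer and schedule settings: Adam at an initial learning rate of
#' 1e-3, multiplied by `lrGamma` every `lrStep` epochs (the study's
#' StepLR schedule: gamma 0.1, step 5), cross-entropy loss, batch size
#' 64, 200 epochs. `lrFloor` optionally stops the decay from driving the
#' rate to zero on long runs (off by default, as printed).
#'
#' @param batchSize minibatch size (>= 1).
#' @param epochs training epochs.
#' @param lr initial learning rate.
#' @param lrStep epochs between learning-rate decays.
#' @param lrGamma multiplicative decay factor in (0, 1].
#' @param lrFloor optional minimum learning rate (`NULL` = none).
#' @param seed seed controlling shuffling (and hence the whole run).
#' @return a list of class `"TrainConfig"`.
#' @export
trainConfig <- function(batchSize = 64L, epochs = 200L, lr = 1e-3,
                        lrStep = 5L, lrGamma = 0.1, lrFloor = NULL,
                        seed = 1L) {
  stopifnot(batchSize >= 1, epochs >= 1, lr > 0, lrStep >= 1,
            lrGamma > 0, lrGamma <= 1)
  structure(list(batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), lr = lr,
                 lrStep = as.integer(lrStep), lrGamma = lrGamma,
                 lrFloor = lrFloor, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Learning rate at a given epoch under the step schedule
#'
#' @param cfg a [trainConfig()].
#' @param epoch 1-based epoch index.
#' @return the learning rate in effect during that epoch.
#' @export
scheduledLr <- function(cfg, epoch) {
  lr <- cfg$lr * cfg$lrGamma^((epoch - 1L) %/% cfg$lrStep)
  if (!is.null(cfg$lrFloor)) lr <- max(lr, cfg$lrFloor)
  lr
}

#' Stack feature tensors into a model input batch
#'
#' Converts a list of [FeatureTensor-class] objects (identical shapes)
#' into the (F, T, maps, n) array [modelForward()] consumes. Optional
#' z-scoring normalizes the whole batch by its global mean and standard
#' deviation.
#'
#' @param tensors list of [FeatureTensor-class] objects.
#' @param normalize z-score the assembled batch.
#' @return array (F, T, maps, n).
#' @export
featuresToArray <- function(tensors, normalize = FALSE) {
  stopifnot(length(tensors) >= 1)
  d <- dim(featureValues(tensors[[1L]]))   # (maps, F, T)
  X <- array(0, c(d[2L], d[3L], d[1L], length(tensors)))
  for (i in seq_along(tensors)) {
    v <- featureValues(tensors[[i]])
    if (!identical(dim(v), d)) stop("feature tensors differ in shape")
    X[, , , i] <- aperm(v, c(2L, 3L, 1L))
  }
  if (normalize) {
    s <- stats::sd(X)
    X <- (X - mean(X)) / (if (s > 0) s else 1)
  }
  X
}

#' Stratified epoch-level cross-validation folds
#'
#' Assigns every sample to one of `k` folds so that each class is spread
#' as evenly as possible across folds (per-class shuffled round-robin).
#' Folds are disjoint, exhaustive, and deterministic under `seed`.
#'
#' @param labels class label per sample (factor or coercible).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer fold id (1..k) per sample.
#' @export
makeEpochFolds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < k))
    stop("every class needs at least k samples for stratified k-fold")
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Patient-level (subject-independent) cross-validation folds
#'
#' Every patient's epochs land in exactly one fold, so each test fold
#' contains only patients unseen during training. Patients are assigned
#' greedily (largest epoch count first, shuffled tie-break) to the
#' currently smallest fold, balancing fold sizes.
#'
#' @param patientIds patient identifier per epoch.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer fold id (1..k) per epoch.
#' @export
makeSubjectFolds <- function(patientIds, k = 3L, seed = 1L) {
  patientIds <- as.character(patientIds)
  pats <- unique(patientIds)
  if (length(pats) < k)
    stop("need at least k distinct patients for subject-independent folds")
  counts <- table(patientIds)[pats]
  assign <- integer(length(pats))
  names(assign) <- pats
  withSeed(seed, {
    ord <- pats[sample(length(pats))]
    ord <- ord[order(-counts[ord])]        # stable: keeps shuffled ties
    sizes <- numeric(k)
    for (p in ord) {
      f <- which.min(sizes)
      assign[p] <- f
      sizes[f] <- sizes[f] + counts[p]
    }
  })
  unname(assign[patientIds])
}

#' Train a classifier
#'
#' Minibatch training with the Adam optimizer, the step learning-rate
#' schedule and softmax cross-entropy. Fully deterministic under
#' `cfg$seed` (shuffling is the only randomness; weights come seeded
#' from [buildModel()]). Aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model an `MVMDNetModel`.
#' @param dataset list with `x` (array F x T x maps x n) and `y`
#'   (integer labels 1..nClasses).
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch loss.
#' @return list with the trained `model`, `lossHistory` (mean loss per
#'   epoch) and `lrHistory`.
#' @export
trainModel <- function(model, dataset, cfg = trainConfig(), verbose = FALSE) {
  stopifnot(inherits(cfg, "TrainConfig"))
  X <- dataset$x
  y <- as.integer(dataset$y)
  n <- dim(X)[4L]
  if (n == 0L || length(y) != n) stop("dataset empty or labels mismatched")
  if (any(y < 1L | y > model$config$nClasses))
    stop("labels out of range 1..nClasses")
  st <- adamInit(model$params)
  lossHistory <- numeric(cfg$epochs)
  lrHistory <- numeric(cfg$epochs)
  withSeed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- scheduledLr(cfg, ep)
      lrHistory[ep] <- lr
      ord <- sample(n)
      losses <- c()
      for (b in seq_len(ceiling(n / cfg$batchSize))) {
        idx <- ord[((b - 1L) * cfg$batchSize + 1L):min(b * cfg$batchSize, n)]
        lg <- modelLossGrad(model,
                            X[, , , idx, drop = FALSE], y[idx], train = TRUE)
        if (!is.finite(lg$loss))
          stop(sprintf("non-finite loss at epoch %d batch %d; reduce lr",
                       ep, b))
        model$buffers <- lg$buffers
        up <- adamStep(model$params, lg$grads, st, lr)
        model$params <- up$params
        st <- up$state
        losses <- c(losses, lg$loss)
      }
      lossHistory[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %3d  lr %.2g  loss %.4f", ep, lr,
                        lossHistory[ep]))
    }
  })
  list(model = model, lossHistory = lossHistory, lrHistory = lrHistory)
}

#' Evaluation report from a confusion matrix
#'
#' Computes accuracy, the class-weighted F1 score, the row-normalized
#' confusion matrix and per-class recalls. For a 2-class task the recall
#' of the positive class is reported as sensitivity and the recall of
#' the other class as specificity (the focal / seizure class is the
#' positive one by convention).
#'
#' @param confusion square count matrix, rows = true classes, columns =
#'   predicted classes.
#' @param positive index or name of the positive class (binary tasks).
#' @return an [EvalReport-class].
#' @export
evalReportFromConfusion <- function(confusion, positive = 2L) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  nc <- nrow(confusion)
  if (is.character(positive)) positive <- match(positive, rownames(confusion))
  total <- sum(confusion)
  acc <- 100 * sum(diag(confusion)) / total
  rowTot <- rowSums(confusion)
  colTot <- colSums(confusion)
  recall <- ifelse(rowTot > 0, diag(confusion) / rowTot, 0)
  precision <- ifelse(colTot > 0, diag(confusion) / colTot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  weightedF1 <- sum(rowTot / total * f1)
  if (nc == 2L) {
    sen <- 100 * recall[positive]
    spe <- 100 * recall[-positive]
  } else {
    sen <- NA_real_
    spe <- NA_real_
  }
  norm <- confusion / ifelse(rowTot > 0, rowTot, 1)
  if (is.null(rownames(confusion)))
    dimnames(confusion) <- dimnames(norm) <-
      list(true = seq_len(nc), pred = seq_len(nc))
  names(recall) <- rownames(confusion)
  new("EvalReport", acc = acc, sen = unname(sen), spe = unname(spe),
      weightedF1 = weightedF1, confusion = confusion, confusionNorm = norm,
      perClassRecall = recall)
}

#' Evaluate a trained classifier on a labeled dataset
#'
#' Predicts every sample in evaluation mode and summarizes the results
#' as an [EvalReport-class]: ACC = correct/total, sensitivity = recall
#' of the positive class, specificity = recall of the negative class
#' (2-class tasks), weighted F1 = sum over classes of
#' `(n_c / N) * F1_c`, and the confusion matrix with rows normalized by
#' true class.
#'
#' @param model a trained `MVMDNetModel`.
#' @param dataset list with `x` and `y` as in [trainModel()].
#' @param positive positive class for sensitivity (binary tasks).
#' @param classNames optional class names for the confusion matrix.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(model, dataset, positive = 2L,
                          classNames = NULL) {
  pred <- modelPredict(model, dataset$x)$classes
  y <- as.integer(dataset$y)
  nc <- model$config$nClasses
  confusion <- matrix(0L, nc, nc)
  for (i in seq_along(y))
    confusion[y[i], pred[i]] <- confusion[y[i], pred[i]] + 1L
  if (!is.null(classNames))
    dimnames(confusion) <- list(true = classNames, pred = classNames)
  evalReportFromConfusion(confusion, positive)
}

#' Cross-validated training and evaluation
#'
#' Runs the full protocol: folds are built either at the epoch level
#' (stratified k-fold, the subject-dependent protocol) or at the patient
#' level (subject-independent; requires `patientIds`), and for each fold
#' a fresh model is trained on the remaining data and evaluated on the
#' held-out fold.
#'
#' @param dataset list with `x` (F, T, maps, n), `y` (labels 1..nClasses),
#'   and optionally `patientIds` (length n).
#' @param modelCfg a [modelConfig()].
#' @param trainCfg a [trainConfig()].
#' @param k number of folds (5 for epoch-level, 3 for patient-level).
#' @param protocol `"epoch"` (stratified) or `"subject"`
#'   (patient-disjoint).
#' @param seed fold-assignment seed; per-fold model seeds derive from it.
#' @param positive positive class for binary metrics.
#' @return list with `reports` (one [EvalReport-class] per fold), `folds`
#'   (assignment vector) and `meanAcc`.
#' @export
crossValidate <- function(dataset, modelCfg, trainCfg, k = 5L,
                          protocol = c("epoch", "subject"), seed = 1L,
                          positive = 2L) {
  protocol <- match.arg(protocol)
  folds <- if (protocol == "epoch") makeEpochFolds(dataset$y, k, seed)
           else makeSubjectFolds(dataset$patientIds, k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- which(folds == f)
    trainIdx <- which(folds != f)
    model <- buildModel(modelCfg, seed = seed + f)
    tcf <- trainCfg
    tcf$seed <- trainCfg$seed + f
    fit <- trainModel(model,
                      list(x = dataset$x[, , , trainIdx, drop = FALSE],
                           y = dataset$y[trainIdx]), tcf)
    reports[[f]] <- evaluateModel(fit$model,
                                  list(x = dataset$x[, , , testIdx,
                                                     drop = FALSE],
                                       y = dataset$y[testIdx]),
                                  positive = positive)
  }
  list(reports = reports, folds = folds,
       meanAcc = mean(vapply(reports, function(r) r@acc, numeric(1L))))
}

#' Export an evaluation report as delimited tables
#'
#' Writes `<stem>_metrics.csv` (the scalar metrics) and
#' `<stem>_confusion.csv` (raw counts) next to each other for audit.
#'
#' @param report an [EvalReport-class].
#' @param stem output path stem.
#' @return the metric file path, invisibly.
#' @export
writeEvalReport <- function(report, stem) {
  m <- metrics(report)
  mf <- paste0(stem, "_metrics.csv")
  utils::write.csv(data.frame(metric = names(m),
                              value = unlist(m, use.names = FALSE)),
                   mf, row.names = FALSE)
  utils::write.csv(confusionMatrix(report), paste0(stem, "_confusion.csv"))
  invisible(mf)
}
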