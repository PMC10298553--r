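#' Construct a drug-target interaction dataset
#'
#' @param features numeric matrix; drug-feature columns prefixed \code{d_},
#'   target-feature columns prefixed \code{t_}.
#' @param labels 0/1 vector (1 = proven interaction).
#' @param pairIds optional row ids.
#' @return a \code{DTIDataset}.
#' @export
dtiDataset <- function(features, labels, pairIds = NULL) {
  features <- as.matrix(features)
  cn <- colnames(features)
  if (is.null(cn)) stop("feature columns must be named with d_/t_ prefixes")
  new("DTIDataset", features = features, labels = as.integer(labels),
      pairIds = pairIds %||% paste0("pair", seq_len(nrow(features))),
      drugCols = cn[startsWith(cn, "d_")],
      targetCols = cn[startsWith(cn, "t_")],
      truth = list())
}

#' Balance a DTI dataset by downsampling negatives
#'
#' Subsamples the unproven (label 0) pairs uniformly without replacement to
#' the proven count, leaving the proven pairs intact. Deterministic per seed.
#'
#' @param dataset a \code{DTIDataset} with more negatives than positives.
#' @param seed integer seed.
#' @return a balanced \code{DTIDataset}.
#' @export
balanceDownsample <- function(dataset, seed = 1L) {
  stopifnot(is(dataset, "DTIDataset"))
  pos <- which(dataset@labels == 1L)
  neg <- which(dataset@labels == 0L)
  if (!length(pos) || !length(neg)) stop("both classes must be nonempty")
  if (length(pos) > length(neg))
    stop("more positives than negatives; expected the usual DTI orientation")
  keepNeg <- withSeed(seed, sort(sample(neg, length(pos))))
  idx <- sort(c(pos, keepNeg))
  new("DTIDataset", features = dataset@features[idx, , drop = FALSE],
      labels = dataset@labels[idx], pairIds = dataset@pairIds[idx],
      drugCols = dataset@drugCols, targetCols = dataset@targetCols,
      truth = dataset@truth)
}

#' Fit / apply a feature standardizer
#'
#' Per-feature z-scoring with training-split statistics only; the standard
#' deviation uses divisor n (population form). Zero-variance features are
#' dropped with a warning.
#'
#' @param X numeric training matrix.
#' @return \code{fitStandardizer}: list with \code{mean}, \code{sd} and the
#'   retained column names \code{kept}; \code{applyStandardizer}: the
#'   standardized matrix restricted to retained columns.
#' @export
fitStandardizer <- function(X) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("empty training split")
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  kept <- colnames(X)[sdv > 0]
  if (length(kept) < ncol(X))
    warning("dropping ", ncol(X) - length(kept), " zero-variance feature(s)")
  list(mean = mu[kept], sd = sdv[kept], kept = kept)
}

#' @rdname fitStandardizer
#' @param std a fitted standardizer.
#' @export
applyStandardizer <- function(std, X) {
  X <- as.matrix(X)[, std$kept, drop = FALSE]
  sweep(sweep(X, 2, std$mean), 2, std$sd, "/")
}

#' Principal-component reduction fitted on the training split
#'
#' Orthonormal basis from the SVD of the centred training block; every split
#' is projected with the same basis, so no statistic of validation/test rows
#' leaks into the transform.
#'
#' @param train numeric training matrix.
#' @param rest optional matrix (or list of matrices) to project with the
#'   fitted basis.
#' @param nComponents number of components; must not exceed
#'   min(training rows, feature count).
#' @return list with \code{train} (scores), \code{rest} (projected),
#'   \code{basis} = list(\code{center}, \code{rotation}, \code{explained}),
#'   where \code{explained} is the per-component variance fraction.
#' @export
pcaReduce <- function(train, rest = NULL, nComponents) {
  train <- as.matrix(train)
  if (nComponents < 1 || nComponents > min(nrow(train), ncol(train)))
    stop("nComponents must be in [1, min(rows, features)]")
  ctr <- colMeans(train)
  Xc <- sweep(train, 2, ctr)
  sv <- svd(Xc, nu = 0)
  rot <- sv$v[, seq_len(nComponents), drop = FALSE]
  varAll <- sum(sv$d^2)
  explained <- if (varAll > 0) sv$d[seq_len(nComponents)]^2 / varAll
               else rep(0, nComponents)
  basis <- list(center = ctr, rotation = rot, explained = explained)
  project <- function(M) sweep(as.matrix(M), 2, ctr) %*% rot
  list(train = project(train),
       rest = if (is.null(rest)) NULL else if (is.list(rest))
         lapply(rest, project) else project(rest),
       basis = basis)
}

#' Binary cross-entropy loss
#'
#' C_n = -[p log p^ + (1 - p) log(1 - p^)], averaged over the batch;
#' predictions are clipped to [1e-7, 1 - 1e-7].
#'
#' @param pTrue 0/1 labels.
#' @param pHat predicted probabilities.
#' @return mean loss.
#' @export
bceLoss <- function(pTrue, pHat) {
  pHat <- .clipProb(pHat)
  mean(-(pTrue * log(pHat) + (1 - pTrue) * log(1 - pHat)))
}

#' Hyperparameters for the DTI classifier
#'
#' Defaults follow the reference architecture: four ReLU hidden layers of
#' 512/256/128/64 units, sigmoid output, Adam at learning rate 0.001, batch
#' size 100, up to 100 epochs with early stopping (patience 10) on
#' validation loss, dropout 0.3 on hidden activations, 996 principal
#' components (capped at the available feature count), 75/25 train/test
#' split and 5-fold cross-validation inside the training portion.
#'
#' @param hidden integer vector of hidden-layer sizes.
#' @param dropout dropout rate on hidden activations.
#' @param lr Adam learning rate.
#' @param epochs maximum epochs.
#' @param batch minibatch size.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param nComponents PCA dimension (capped at available features/rows).
#' @param testFraction held-out test fraction.
#' @param folds cross-validation folds.
#' @return a config list.
#' @export
dtiConfig <- function(hidden = c(512L, 256L, 128L, 64L), dropout = 0.3,
                      lr = 0.001, epochs = 100L, batch = 100L,
                      patience = 10L, nComponents = 996L,
                      testFraction = 0.25, folds = 5L) {
  list(hidden = as.integer(hidden), dropout = dropout, lr = lr,
       epochs = as.integer(epochs), batch = as.integer(batch),
       patience = as.integer(patience), nComponents = as.integer(nComponents),
       testFraction = testFraction, folds = as.integer(folds))
}

# --- multilayer perceptron internals (base matrix ops) ---------------------

.mlpInit <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialisation for ReLU layers, Xavier for the sigmoid output
    sc <- if (l < L) sqrt(2 / sizes[l]) else sqrt(1 / sizes[l])
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1]) * sc, sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

.mlpForward <- function(par, X, dropout = 0, training = FALSE) {
  L <- length(par$W)
  A <- X
  acts <- vector("list", L + 1L); acts[[1]] <- A
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% par$W[[l]], 2, par$b[[l]], "+")
    if (l < L) {
      A <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix(rbinom(length(A), 1, 1 - dropout), nrow(A)) / (1 - dropout)
        A <- A * m
        masks[[l]] <- m
      }
    } else {
      A <- .sigmoid(Z)
    }
    acts[[l + 1L]] <- A
  }
  list(prob = drop(acts[[L + 1L]]), acts = acts, masks = masks)
}

.mlpGrad <- function(par, fw, y) {
  L <- length(par$W)
  n <- length(y)
  dW <- vector("list", L); db <- vector("list", L)
  # BCE + sigmoid: dL/dZ_L = (p - y) / n
  dZ <- matrix(fw$prob - y, n, 1) / n
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fw$acts[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% t(par$W[[l]])
      if (!is.null(fw$masks[[l - 1L]])) dA <- dA * fw$masks[[l - 1L]]
      dZ <- dA * (fw$acts[[l]] > 0)
    }
  }
  list(dW = dW, db = db)
}

.trainOne <- function(Xtr, ytr, Xval, yval, config) {
  sizes <- c(ncol(Xtr), config$hidden, 1L)
  par <- .mlpInit(sizes)
  L <- length(par$W)
  adam <- list(mW = lapply(par$W, function(w) w * 0),
               vW = lapply(par$W, function(w) w * 0),
               mb = lapply(par$b, function(b) b * 0),
               vb = lapply(par$b, function(b) b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  n <- nrow(Xtr)
  best <- list(loss = Inf, par = par, epoch = 0L)
  wait <- 0L
  hist <- list()
  for (epoch in seq_len(config$epochs)) {
    idx <- sample(n)
    starts <- seq(1L, n, by = config$batch)
    for (s in starts) {
      bi <- idx[s:min(s + config$batch - 1L, n)]
      fw <- .mlpForward(par, Xtr[bi, , drop = FALSE],
                        dropout = config$dropout, training = TRUE)
      gr <- .mlpGrad(par, fw, ytr[bi])
      t <- t + 1L
      for (l in seq_len(L)) {
        adam$mW[[l]] <- b1 * adam$mW[[l]] + (1 - b1) * gr$dW[[l]]
        adam$vW[[l]] <- b2 * adam$vW[[l]] + (1 - b2) * gr$dW[[l]]^2
        adam$mb[[l]] <- b1 * adam$mb[[l]] + (1 - b1) * gr$db[[l]]
        adam$vb[[l]] <- b2 * adam$vb[[l]] + (1 - b2) * gr$db[[l]]^2
        par$W[[l]] <- par$W[[l]] - config$lr * (adam$mW[[l]] / (1 - b1^t)) /
          (sqrt(adam$vW[[l]] / (1 - b2^t)) + eps)
        par$b[[l]] <- par$b[[l]] - config$lr * (adam$mb[[l]] / (1 - b1^t)) /
          (sqrt(adam$vb[[l]] / (1 - b2^t)) + eps)
      }
    }
    ptr <- .mlpForward(par, Xtr)$prob
    pval <- .mlpForward(par, Xval)$prob
    trLoss <- bceLoss(ytr, ptr); valLoss <- bceLoss(yval, pval)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = trLoss,
      train_accuracy = mean((ptr >= 0.5) == (ytr == 1)),
      val_loss = valLoss,
      val_accuracy = mean((pval >= 0.5) == (yval == 1)))
    if (valLoss < best$loss - 1e-6) {
      best <- list(loss = valLoss, par = par, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(par = best$par, bestEpoch = best$epoch, history = do.call(rbind, hist))
}

.stratifiedSplit <- function(labels, fraction) {
  heldOut <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    heldOut <- c(heldOut, sample(idx, round(length(idx) * fraction)))
  }
  sort(heldOut)
}

.foldAssign <- function(labels, folds) {
  f <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    f[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  f
}

#' Train the DTI classifier with cross-validation
#'
#' Splits the (balanced) dataset 75/25 into training and testing portions,
#' runs k-fold cross-validation inside the training portion, and for each
#' fold fits the standardizer and PCA basis on the fold's training rows
#' only, trains the network with Adam and early stopping on validation
#' loss, and evaluates on the held-out test rows. The returned model is the
#' fold with the lowest validation loss, carrying its transforms.
#'
#' @param dataset a balanced, labelled \code{DTIDataset}.
#' @param config from \code{dtiConfig()}.
#' @param seed integer seed covering split, folds, initialisation, batch
#'   order and dropout.
#' @return a \code{DTIModel}; per-fold metrics in \code{cvReport()},
#'   learning curves in \code{@history}.
#' @export
trainDTI <- function(dataset, config = dtiConfig(), seed = 1L) {
  stopifnot(is(dataset, "DTIDataset"))
  y <- dataset@labels
  if (min(table(y)) < 10) stop("need at least 10 samples per class")
  X <- dataset@features
  withSeed(seed, {
    testIdx <- .stratifiedSplit(y, config$testFraction)
    trainIdx <- setdiff(seq_along(y), testIdx)
    foldId <- .foldAssign(y[trainIdx], config$folds)
    cvRows <- list()
    histories <- list()
    best <- NULL
    for (f in seq_len(config$folds)) {
      fitIdx <- trainIdx[foldId != f]
      valIdx <- trainIdx[foldId == f]
      std <- fitStandardizer(X[fitIdx, , drop = FALSE])
      Xfit <- applyStandardizer(std, X[fitIdx, , drop = FALSE])
      ncomp <- min(config$nComponents, ncol(Xfit), nrow(Xfit))
      pr <- pcaReduce(Xfit, rest = list(
        val = applyStandardizer(std, X[valIdx, , drop = FALSE]),
        test = applyStandardizer(std, X[testIdx, , drop = FALSE])),
        nComponents = ncomp)
      tr <- .trainOne(pr$train, y[fitIdx], pr$rest$val, y[valIdx], config)
      pval <- .mlpForward(tr$par, pr$rest$val)$prob
      ptest <- .mlpForward(tr$par, pr$rest$test)$prob
      cvRows[[f]] <- data.frame(
        fold = f, best_epoch = tr$bestEpoch,
        val_loss = bceLoss(y[valIdx], pval),
        val_accuracy = mean((pval >= 0.5) == (y[valIdx] == 1)),
        test_loss = bceLoss(y[testIdx], ptest),
        test_accuracy = mean((ptest >= 0.5) == (y[testIdx] == 1)))
      histories[[f]] <- tr$history
      if (is.null(best) || cvRows[[f]]$val_loss < best$valLoss) {
        best <- list(valLoss = cvRows[[f]]$val_loss, par = tr$par,
                     std = std, basis = pr$basis)
      }
    }
    cv <- do.call(rbind, cvRows)
    new("DTIModel", weights = best$par$W, biases = best$par$b,
        config = config, standardizer = best$std, basis = best$basis,
        cv = cv, history = histories,
        schema = list(drugCols = dataset@drugCols,
                      targetCols = dataset@targetCols,
                      testIdx = testIdx))
  })
}

# transform raw features with a model's stored standardizer + PCA basis
.transformFeatures <- function(model, X) {
  Xs <- applyStandardizer(model@standardizer, X)
  sweep(Xs, 2, model@basis$center) %*% model@basis$rotation
}

#' Predicted interaction probabilities for raw feature rows
#'
#' @param model a trained \code{DTIModel}.
#' @param drugFeatures matrix of drug-feature columns (same count/order as
#'   at training).
#' @param targetFeatures matrix of target-feature columns.
#' @return numeric probabilities in (0, 1), one per row, ordered as input.
#' @export
predictDTI <- function(model, drugFeatures, targetFeatures) {
  stopifnot(is(model, "DTIModel"))
  drugFeatures <- as.matrix(drugFeatures)
  targetFeatures <- as.matrix(targetFeatures)
  if (ncol(drugFeatures) != length(model@schema$drugCols))
    stop("drug feature block has ", ncol(drugFeatures), " columns; expected ",
         length(model@schema$drugCols))
  if (ncol(targetFeatures) != length(model@schema$targetCols))
    stop("target feature block has ", ncol(targetFeatures),
         " columns; expected ", length(model@schema$targetCols))
  X <- cbind(drugFeatures, targetFeatures)
  colnames(X) <- c(model@schema$drugCols, model@schema$targetCols)
  p <- .mlpForward(list(W = model@weights, b = model@biases),
                   .transformFeatures(model, X))$prob
  .clipProb(p)
}

#' Confusion, ROC and AUC report for a binary classifier
#'
#' Confusion counts at threshold 0.5; ROC by sweeping all observed score
#' thresholds; AUC by the trapezoid rule. Requires both classes present.
#'
#' @param labels 0/1 labels.
#' @param probs predicted probabilities.
#' @return list with \code{TP}, \code{TN}, \code{FP}, \code{FN}, \code{TPR},
#'   \code{TNR}, \code{FPR}, \code{accuracy}, \code{loss} (BCE), \code{auc}
#'   and a \code{roc} data.frame (\code{fpr}, \code{tpr}) from (0,0) to
#'   (1,1).
#' @export
evalBinary <- function(labels, probs) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("AUC undefined: split contains a single class")
  pred <- as.integer(probs >= 0.5)
  TP <- sum(pred == 1 & labels == 1); TN <- sum(pred == 0 & labels == 0)
  FP <- sum(pred == 1 & labels == 0); FN <- sum(pred == 0 & labels == 1)
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(probs >= t & labels == 1), numeric(1)) / sum(labels == 1)
  fpr <- vapply(thr, function(t) sum(probs >= t & labels == 0), numeric(1)) / sum(labels == 0)
  if (utils::tail(fpr, 1) < 1 || utils::tail(tpr, 1) < 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       TPR = TP / (TP + FN), TNR = TN / (TN + FP), FPR = FP / (TN + FP),
       accuracy = (TP + TN) / length(labels),
       loss = bceLoss(labels, probs), auc = auc,
       roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Evaluate a trained DTI model on labelled raw features
#'
#' @param model a \code{DTIModel}.
#' @param dataset a \code{DTIDataset}.
#' @param idx optional row indices (defaults to the held-out test rows
#'   recorded at training).
#' @return an evaluation report, see \code{evalBinary}.
#' @export
evaluateDTI <- function(model, dataset, idx = NULL) {
  stopifnot(is(model, "DTIModel"), is(dataset, "DTIDataset"))
  idx <- idx %||% model@schema$testIdx
  X <- dataset@features[idx, , drop = FALSE]
  p <- .mlpForward(list(W = model@weights, b = model@biases),
                   .transformFeatures(model, X))$prob
  evalBinary(dataset@labels[idx], .clipProb(p))
}
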