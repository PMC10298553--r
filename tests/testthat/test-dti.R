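test_that("downsampling balances classes deterministically", {
  set.seed(71)
  X <- matrix(rnorm(225 * 4), 225, 4,
              dimnames = list(NULL, c("d_1", "d_2", "t_1", "t_2")))
  ds <- dtiDataset(X, c(rep(1, 100), rep(0, 125)))
  bal <- balanceDownsample(ds, seed = 5)
  expect_equal(as.integer(table(dtiLabels(bal))), c(100L, 100L))
  bal2 <- balanceDownsample(ds, seed = 5)
  expect_identical(bal@pairIds, bal2@pairIds)
  # the published imbalance at 1/1000 scale: 80 proven / 100 unproven -> 80/80
  ds2 <- dtiDataset(X[1:180, ], c(rep(1, 80), rep(0, 100)))
  expect_equal(as.integer(table(dtiLabels(balanceDownsample(ds2, 1)))), c(80L, 80L))
  dsRev <- dtiDataset(X[1:150, ], c(rep(1, 100), rep(0, 50)))
  expect_error(balanceDownsample(dsRev, 1), "orientation")
})

test_that("standardizer uses population sd from the training split only", {
  X <- cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5))
  expect_warning(std <- fitStandardizer(X), "zero-variance")
  expect_equal(std$kept, "f1")
  Z <- applyStandardizer(std, X)
  expect_equal(unname(Z[, 1]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-10)
  # train columns have mean 0, population sd 1 after transform
  set.seed(72)
  Xr <- matrix(rnorm(200 * 5, 3, 2), 200, 5,
               dimnames = list(NULL, paste0("f", 1:5)))
  Zr <- applyStandardizer(fitStandardizer(Xr), Xr)
  expect_lt(max(abs(colMeans(Zr))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(Zr^2)) - 1)), 1e-10)
  # unseen value standardised with train statistics
  expect_equal(unname(applyStandardizer(list(mean = c(f1 = 2), sd = c(f1 = 1),
                                             kept = "f1"),
                                        matrix(2, 1, 1,
                                               dimnames = list(NULL, "f1")))[1, 1]),
               0)
})

test_that("PCA explained variance matches the eigen decomposition oracle", {
  set.seed(73)
  X <- matrix(rnorm(100 * 8), 100, 8) %*% diag(c(4, 3, 2, 1, rep(0.2, 4)))
  pr <- pcaReduce(X, nComponents = 3)
  ev <- eigen(stats::cov(X) * (99 / 100), symmetric = TRUE)$values
  expect_equal(sum(pr$basis$explained), sum(ev[1:3]) / sum(ev), tolerance = 1e-8)
  # rank-1 data: one component explains everything
  X1 <- outer(rnorm(50), rnorm(4))
  colnames(X1) <- paste0("f", 1:4)
  expect_equal(sum(pcaReduce(X1, nComponents = 1)$basis$explained), 1,
               tolerance = 1e-10)
  # full-dimensional basis preserves variance exactly
  pr2 <- pcaReduce(X, nComponents = 8)
  expect_equal(sum(pr2$train^2), sum(scale(X, scale = FALSE)^2), tolerance = 1e-8)
  expect_error(pcaReduce(X, nComponents = 9), "nComponents")
})

test_that("binary cross-entropy matches hand computation", {
  expect_equal(bceLoss(1, 0.5), -log(0.5), tolerance = 1e-12)
  expect_lt(bceLoss(0, 1e-9), 1e-6)
  set.seed(74)
  y <- rbinom(20, 1, 0.5)
  p <- runif(20, 0.05, 0.95)
  byHand <- mean(sapply(seq_along(y), function(i)
    -(y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))))
  expect_equal(bceLoss(y, p), byHand, tolerance = 1e-12)
})

test_that("ROC/AUC report matches the Mann-Whitney pairwise oracle", {
  set.seed(75)
  y <- c(rep(1, 30), rep(0, 40))
  p <- c(rnorm(30, 0.7, 0.15), rnorm(40, 0.4, 0.15))
  p <- pmin(pmax(p, 0.01), 0.99)
  ev <- evalBinary(y, p)
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(ev$auc, mean(cmp), tolerance = 1e-10)
  expect_equal(ev$TPR, ev$TP / (ev$TP + ev$FN))
  expect_equal(ev$FPR, 1 - ev$TNR, tolerance = 1e-12)
  expect_equal(ev$roc$fpr[1], 0)
  expect_equal(utils::tail(ev$roc$tpr, 1), 1)
  expect_true(all(diff(ev$roc$fpr) >= 0) && all(diff(ev$roc$tpr) >= 0))
  # perfect predictor
  evp <- evalBinary(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(evp$auc, 1)
  expect_equal(evp$TPR, 1)
  expect_equal(evp$FPR, 0)
  # TP = 9, FN = 1 gives TPR 0.9
  ev9 <- evalBinary(c(rep(1, 10), rep(0, 5)),
                    c(rep(0.9, 9), 0.1, rep(0.2, 5)))
  expect_equal(ev9$TPR, 0.9)
  expect_error(evalBinary(rep(1, 5), runif(5)), "single class")
})

test_that("training is deterministic per seed and transforms never see test rows", {
  ds <- balanceDownsample(generateDTI(400, seed = 81), seed = 1)
  cfg <- dtiConfig(hidden = c(16L), epochs = 5L, folds = 3L, patience = 3L)
  m1 <- trainDTI(ds, cfg, seed = 2)
  m2 <- trainDTI(ds, cfg, seed = 2)
  expect_identical(m1@history[[1]]$train_loss[1], m2@history[[1]]$train_loss[1])
  expect_identical(m1@weights, m2@weights)
  # leakage check: perturbing held-out test rows leaves the transforms alone
  ds2 <- ds
  ds2@features[m1@schema$testIdx, ] <- ds2@features[m1@schema$testIdx, ] + 100
  m3 <- trainDTI(ds2, cfg, seed = 2)
  expect_equal(m1@standardizer$mean, m3@standardizer$mean)
  expect_equal(m1@basis$rotation, m3@basis$rotation)
})

test_that("prediction is schema-checked, deterministic and rule-following", {
  ds <- balanceDownsample(generateDTI(600, seed = 82), seed = 1)
  m <- trainDTI(ds, dtiConfig(hidden = c(32L), epochs = 25L, folds = 3L), seed = 3)
  X <- dtiFeatures(ds)
  dcols <- X[, startsWith(colnames(X), "d_"), drop = FALSE]
  tcols <- X[, startsWith(colnames(X), "t_"), drop = FALSE]
  p <- predictDTI(m, dcols, tcols)
  expect_true(all(p > 0 & p < 1))
  # duplicate rows get identical probabilities
  p2 <- predictDTI(m, dcols[c(1, 1), , drop = FALSE], tcols[c(1, 1), , drop = FALSE])
  expect_equal(p2[1], p2[2])
  # held-out positives score above negatives on average
  idx <- m@schema$testIdx
  expect_gt(mean(p[idx][dtiLabels(ds)[idx] == 1]),
            mean(p[idx][dtiLabels(ds)[idx] == 0]))
  expect_error(predictDTI(m, dcols[, -1, drop = FALSE], tcols), "drug feature")
  expect_error(predictDTI(m, dcols, tcols[, -1, drop = FALSE]), "target feature")
})
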