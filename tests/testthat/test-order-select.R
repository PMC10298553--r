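test_that("AIC formula and monotonicity", {
  expect_equal(aicScore(1, 1, 10), 0.4)
  expect_equal(aicScore(exp(1), 0, 2), 2.0)
  # each extra parameter adds exactly 2/N at fixed residual variance
  expect_equal(aicScore(0.5, 4, 50) - aicScore(0.5, 3, 50), 2 / 50)
  expect_warning(aicScore(0, 1, 10), "floored")
})

.mkProblem2 <- function(X, y, cmask) {
  regs <- data.frame(regulator = colnames(X)[-ncol(X)],
                     edge_type = ifelse(cmask[-length(cmask)], "miRNA", "TF"),
                     stringsAsFactors = FALSE)
  new("RegressionProblem", targetId = "tgt", targetClass = "gene",
      y = y, X = X, regulators = regs, constraintMask = cmask,
      noRegression = FALSE)
}

test_that("a pure-noise decoy is pruned while the true regulator is kept", {
  set.seed(11)
  N <- 100
  t1 <- rnorm(N, 1, 0.3)
  decoy <- rnorm(N, 1, 0.3)
  y <- 1.0 * t1 + 0.5 + rnorm(N, 0, 0.1)
  X <- cbind(decoy = decoy, t1 = t1, `(basal)` = 1)
  sel <- selectOrder(.mkProblem2(X, y, rep(FALSE, 3)))
  expect_identical(sel$trace@selected, "t1")
  # exhaustive 4-subset comparison with the independent oracle
  or <- oracleAIC(X, y, rep(FALSE, 3))
  expect_identical(sort(colnames(X)[or$subset]), sort(sel$trace@selected))
  expect_equal(sel$trace@aic, or$aic, tolerance = 1e-10)
})

test_that("all-null candidates give the intercept-only model", {
  set.seed(12)
  N <- 100
  X <- cbind(matrix(rnorm(3 * N), N), 1)
  colnames(X) <- c("a", "b", "c", "(basal)")
  y <- rep(2, N) + rnorm(N, 0, 0.1)
  sel <- selectOrder(.mkProblem2(X, y, rep(FALSE, 4)))
  expect_length(sel$trace@selected, 0)
})

test_that("selection equals the exhaustive oracle on random problems", {
  for (rep in 1:10) {
    set.seed(100 + rep)
    N <- 60
    k <- 5
    X <- cbind(matrix(rnorm(N * k), N), 1)
    colnames(X) <- c(paste0("r", 1:k), "(basal)")
    cmask <- c(rep(FALSE, 3), TRUE, TRUE, FALSE)
    theta <- c(1.2, 0, 0.8, -0.5, 0, 0.3)
    y <- drop(X %*% theta) + rnorm(N, 0, 0.2)
    sel <- selectOrder(.mkProblem2(X, y, cmask))
    or <- oracleAIC(X, y, cmask)
    expect_setequal(sel$trace@selected, colnames(X)[or$subset])
    expect_equal(sel$trace@aic, or$aic, tolerance = 1e-9)
    # trace invariant: the selected AIC is minimal over everything visited
    expect_lte(sel$trace@aic, min(sel$trace@visited$aic) + 1e-12)
  }
})

test_that("greedy backward search is used above the exhaustive limit", {
  set.seed(13)
  N <- 80
  k <- 6
  X <- cbind(matrix(rnorm(N * k), N), 1)
  colnames(X) <- c(paste0("r", 1:k), "(basal)")
  y <- 1.5 * X[, 1] - 0.9 * X[, 2] + rnorm(N, 0, 0.1)
  sel <- selectOrder(.mkProblem2(X, y, rep(FALSE, k + 1)), exhaustiveLimit = 3L)
  expect_false(sel$trace@exhaustive)
  # both informative regulators survive backward elimination
  expect_true(all(c("r1", "r2") %in% sel$trace@selected))
  # selected model never worse than the full or intercept-only model
  expect_lte(sel$trace@aic, min(sel$trace@visited$aic) + 1e-12)
})

test_that("pruning keeps selected-edge count below candidate count and logs missing targets", {
  tr <- generateTruth(seed = 21)
  cand <- corruptCandidate(tr, 0.5, seed = 22)
  se <- simulateExpression(tr, nSamples = 120, noiseSd = 0.05, seed = 23)
  idn <- pruneNetwork(cand, se)
  nCand <- nrow(ppiEdges(cand)) + nrow(regEdges(cand))
  expect_lte(nrow(identifiedEdges(idn)), nCand)
  expect_true(all(targetSummary(idn)$n_selected <= targetSummary(idn)$n_candidates))
  # per-target selected AIC <= full-model and intercept-only AIC
  for (trc in idn@traces[1:5]) {
    expect_lte(trc@aic, min(trc@visited$aic) + 1e-12)
  }
  # dropping an expression row excludes that target with a message
  E <- SummarizedExperiment::assay(se)
  expect_message(idn2 <- pruneNetwork(cand, E[rownames(E) != "G01", ],
                                      keepTraces = FALSE),
                 "G01")
  expect_false("G01" %in% targetSummary(idn2)$target_id)
})

test_that("with no decoys and no noise every true edge is recovered", {
  tr <- generateTruth(seed = 31)
  se <- simulateExpression(tr, nSamples = 80, noiseSd = 0, seed = 32)
  idn <- suppressWarnings(pruneNetwork(asCandidateNetwork(tr), se))
  rec <- edgeRecovery(idn, tr)
  expect_equal(rec$recall, 1)
})
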