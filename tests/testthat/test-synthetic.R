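test_that("truth generation is a pure function of config and seed", {
  t1 <- generateTruth(seed = 91)
  t2 <- generateTruth(seed = 91)
  expect_equal(trueEdges(t1), trueEdges(t2))
  expect_equal(t1@basal, t2@basal)
  t3 <- generateTruth(seed = 92)
  expect_false(identical(trueEdges(t1)$ability, trueEdges(t3)$ability))
})

test_that("ability supports match the stated distributions", {
  tr <- generateTruth(nGenes = 30, seed = 93)
  ed <- trueEdges(tr)
  mir <- ed$ability[ed$edge_type == "miRNA"]
  expect_true(all(mir <= -0.1 & mir >= -1))        # repression, stored signed
  free <- ed$ability[ed$edge_type %in% c("TF", "lncRNA")]
  expect_true(all(abs(free) >= 0.1 & abs(free) < 1))
  # PPI abilities rescaled so each leaf's denominator stays within bounds
  ppi <- ed[ed$edge_type == "ppi", ]
  sums <- tapply(abs(ppi$ability), ppi$target, sum)
  expect_true(all(sums <= 0.4 + 1e-12))
})

test_that("a minimal two-protein request yields one PPI edge in range", {
  tr <- generateTruth(nProteins = 2, nTfs = 0, nGenes = 0, nLnc = 0,
                      nMirna = 0, edgesPerTarget = 1, seed = 94)
  ed <- trueEdges(tr)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$edge_type, "ppi")
  expect_true(abs(ed$ability) >= 0.1 && abs(ed$ability) < 1)
  expect_error(generateTruth(nProteins = 2, nTfs = 0, nGenes = 0, nLnc = 0,
                             nMirna = 0, edgesPerTarget = 3, seed = 1),
               "impossible degree")
})

test_that("simulated expression satisfies the closed-form equations exactly", {
  # single gene driven by one TF: g = (alpha t + basal + noise)
  tr <- generateTruth(nProteins = 0, nTfs = 1, nGenes = 1, nLnc = 0,
                      nMirna = 0, edgesPerTarget = 1, seed = 95)
  se <- simulateExpression(tr, nSamples = 5, noiseSd = 0, seed = 96)
  E <- SummarizedExperiment::assay(se)
  ab <- trueEdges(tr)$ability
  expect_equal(unname(E["G01", ]), unname(ab * E["T01", ] + tr@basal["G01"]),
               tolerance = 1e-12)
  # hand value: alpha = 1, t = 2, basal = 0.5 -> g = 2.5
  tr@edges$ability <- 1
  tr@basal["G01"] <- 0.5
  se2 <- simulateExpression(tr, nSamples = 4, noiseSd = 0, seed = 97)
  E2 <- SummarizedExperiment::assay(se2)
  expect_equal(unname(E2["G01", ]), unname(E2["T01", ] + 0.5), tolerance = 1e-12)
})

test_that("expression is nonnegative and noise draws average to zero", {
  tr <- generateTruth(seed = 98)
  means <- sapply(1:5, function(s) {
    se <- simulateExpression(tr, nSamples = 150, noiseSd = 0.05, seed = s)
    expect_true(all(SummarizedExperiment::assay(se) >= 0))
    mean(S4Vectors::metadata(se)$noise)
  })
  n <- length(tr@basal) * 150
  expect_lt(max(abs(means)), 3 * 0.05 / sqrt(n) * 3)
})

test_that("decoy corruption adds the requested disjoint class-compatible edges", {
  tr <- generateTruth(seed = 99)
  nTrue <- nrow(trueEdges(tr))
  expect_equal(nrow(ppiEdges(corruptCandidate(tr, 0, seed = 1))) +
                 nrow(regEdges(corruptCandidate(tr, 0, seed = 1))), nTrue)
  cand <- corruptCandidate(tr, 1.0, seed = 2)
  nCand <- nrow(ppiEdges(cand)) + nrow(regEdges(cand))
  expect_equal(nCand, 2L * nTrue)
  # decoys never duplicate true edges (constructor would reject duplicates,
  # and the candidate must contain every true edge)
  base <- asCandidateNetwork(tr)
  trueRegKeys <- paste(base@reg$regulator, base@reg$target)
  candRegKeys <- paste(regEdges(cand)$regulator, regEdges(cand)$target)
  expect_true(all(trueRegKeys %in% candRegKeys))
  expect_error(corruptCandidate(tr, 1e6, seed = 3), "non-edges")
})

test_that("planted-rule DTI data hits the target class balance and is learnable", {
  ds <- generateDTI(2000, seed = 7)
  frac <- mean(dtiLabels(ds))
  expect_lt(abs(frac - 0.803 / 1.803), 0.02)
  expect_identical(dtiLabels(generateDTI(2000, seed = 7)), dtiLabels(ds))
  # scoring with the planted rule itself is near-perfect
  s <- dtiFeatures(ds) %*% ds@truth$w + ds@truth$b
  ev <- evalBinary(dtiLabels(ds), pmin(pmax(1 / (1 + exp(-s)), 1e-7), 1 - 1e-7))
  expect_gte(ev$auc, 0.95)
  # zero planted weights: positive rate is governed by the bias alone
  ds0 <- generateDTI(500, mDrugFeats = 2, nTargetFeats = 2, seed = 11,
                     signalScale = 1e-9)
  expect_lt(abs(mean(dtiLabels(ds0)) - 0.803 / 1.803), 0.06)
})
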