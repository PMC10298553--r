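test_that("W assembly places abilities symmetrically with correct block order", {
  idn <- tinyIdentified()
  nm <- assembleW(idn)
  W <- nm@W
  expect_equal(dim(W), c(4L, 3L))  # rows P1,P2,T1,G1; cols ppi|P1, ppi|P2, TF|T1
  expect_equal(rownames(W), c("P1", "P2", "T1", "G1"))
  expect_equal(sum(W != 0), 3L)
  expect_equal(W["P1", "ppi|P2"], 0.5)
  expect_equal(W["P2", "ppi|P1"], 0.5)
  expect_equal(W["G1", "TF|T1"], 1.2)
  expect_true(all(W["T1", ] == 0))  # regulator-only node keeps a zero row
  # Frobenius norm equals the edge-table sum of squares (PPI once per row)
  expect_equal(sum(W^2), sum(idn@edges$ability^2))
})

test_that("one-sided PPI selections are mirrored to the partner row", {
  idn <- tinyIdentified()
  idn@edges <- idn@edges[-2, ]  # drop P2's own record of the pair
  W <- assembleW(idn)@W
  expect_equal(W["P2", "ppi|P1"], 0.5)
})

test_that("energy rank is the minimal K reaching the threshold", {
  er <- energyRank(diag(c(3, 1)))
  expect_equal(er$K, 1L)
  expect_equal(er$EK, 0.9)
  er2 <- energyRank(diag(2))
  expect_equal(er2$K, 2L)
  expect_equal(er2$EK, 1.0)
  expect_error(energyRank(matrix(0, 3, 3)), "all zero")
})

test_that("energy rank matches the full-SVD cumulative spectrum on random matrices", {
  for (rep in 1:5) {
    set.seed(200 + rep)
    W <- matrix(rnorm(20 * 15), 20, 15) %*% diag(exp(-seq(0, 3, length.out = 15)))
    er <- energyRank(W)
    d <- svd(W)$d
    frac <- cumsum(d^2) / sum(d^2)
    expect_equal(er$K, which(frac >= 0.85)[1])
    expect_equal(er$EK, frac[er$K], tolerance = 1e-12)
    expect_gte(er$EK, 0.85)
    if (er$K > 1) expect_lt(frac[er$K - 1], 0.85)
  }
})

test_that("projection scores obey the Parseval identity at full rank", {
  set.seed(42)
  W <- matrix(rnorm(12 * 9), 12, 9)
  rownames(W) <- paste0("n", 1:12)
  P <- projectionScores(W, K = 9, mode = "l2")
  expect_equal(P, apply(W, 1, function(r) sqrt(sum(r^2))), tolerance = 1e-10)
  expect_lt(abs(sum(P^2) - sum(W^2)) / sum(W^2), 1e-8)
  # identity rows project to unit scores; zero rows to zero, in both modes
  expect_equal(unname(projectionScores(diag(2), K = 2, mode = "l2")), c(1, 1))
  W0 <- rbind(diag(2), 0)
  expect_equal(unname(projectionScores(W0, K = 2, mode = "l2"))[3], 0)
  expect_equal(unname(projectionScores(W0, K = 2, mode = "sum"))[3], 0)
})

test_that("scores are invariant under row permutation", {
  set.seed(7)
  W <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(paste0("n", 1:8), NULL))
  P <- projectionScores(W, K = 3)
  perm <- sample(8)
  P2 <- projectionScores(W[perm, ], K = 3)
  expect_equal(P2[names(P)], P, tolerance = 1e-9)
})

test_that("core extraction takes the top-M nodes with lexicographic tie-break", {
  idn <- tinyIdentified()
  scores <- c(P1 = 3, P2 = 1, T1 = 1, G1 = 2)
  df <- extractCore(idn, scores, M = 2)
  expect_equal(df$node_id[df$selected], c("P1", "G1"))
  # tie at the cut: lexicographically smaller id wins
  df2 <- extractCore(idn, scores, M = 3)
  expect_equal(df2$node_id[df2$selected], c("P1", "G1", "P2"))
  expect_warning(df3 <- extractCore(idn, scores, M = 10), "exceeds")
  expect_true(all(df3$selected))
  # induced subnetwork keeps only edges with both endpoints selected
  expect_equal(nrow(attr(df, "edges")), 0L)
  df4 <- extractCore(idn, scores, M = 3)
  expect_setequal(attr(df4, "edges")$edge_type, "ppi")
})

test_that("selecting by l2 score maximises retained squared projection over subsets", {
  set.seed(9)
  W <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(paste0("n", 1:8), NULL))
  P <- projectionScores(W, K = 6, mode = "l2")
  M <- 3
  top <- sum(sort(P^2, decreasing = TRUE)[1:M])
  combs <- utils::combn(8, M)
  all_sums <- apply(combs, 2, function(ix) sum(P[ix]^2))
  expect_equal(top, max(all_sums), tolerance = 1e-12)
})

test_that("the full PNP wrapper meets the energy rule end to end", {
  tr <- generateTruth(seed = 51)
  se <- simulateExpression(tr, nSamples = 100, noiseSd = 0.05, seed = 52)
  idn <- pruneNetwork(asCandidateNetwork(tr), se)
  core <- suppressWarnings(pnpCore(idn, M = 10))
  expect_gte(core@energyFraction, 0.85)
  d <- core@singularValues
  if (core@K > 1)
    expect_lt(sum(d[seq_len(core@K - 1)]^2) / sum(d^2), 0.85)
  expect_equal(sum(coreScores(core)$selected), 10L)
  exported <- exportCore(core, sifPath = withr::local_tempfile(fileext = ".sif"),
                         graphmlPath = withr::local_tempfile(fileext = ".graphml"))
  expect_true(all(file.exists(exported)))
})
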