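test_that("network load validates endpoints and round-trips through save/load", {
  nodes <- data.frame(node_id = c("P1", "P2", "G1", "T1"),
                      node_class = c("protein", "protein", "gene", "TF"))
  net <- candidateNetwork(nodes,
                          ppi = data.frame(protein_a = "P2", protein_b = "P1"),
                          reg = data.frame(regulator = "T1", target = "G1"))
  expect_equal(nrow(ppiEdges(net)), 1L)
  expect_equal(ppiEdges(net)$protein_a, "P1")  # canonicalised order
  expect_equal(nrow(regEdges(net)), 1L)

  dir <- withr::local_tempdir()
  saveNetwork(net, dir)
  net2 <- loadNetwork(file.path(dir, "nodes.tsv"), file.path(dir, "ppi.tsv"),
                      file.path(dir, "reg.tsv"))
  expect_equal(nodeTable(net2), nodeTable(net))
  expect_equal(ppiEdges(net2), ppiEdges(net))
  expect_equal(regEdges(net2), regEdges(net))

  # unknown node in an edge file is named in the error
  bad <- file.path(dir, "bad_ppi.tsv")
  writeLines(c("protein_a\tprotein_b", "P1\tX9"), bad)
  expect_error(loadNetwork(file.path(dir, "nodes.tsv"), bad,
                           file.path(dir, "reg.tsv")), "X9")
})

test_that("invalid networks are rejected", {
  nodes <- data.frame(node_id = c("P1", "P2", "G1"),
                      node_class = c("protein", "protein", "gene"))
  expect_error(candidateNetwork(rbind(nodes, nodes[1, ])), "duplicate node_id")
  expect_error(candidateNetwork(nodes, ppi = data.frame(protein_a = "P1",
                                                        protein_b = "P1")),
               "self PPI")
  expect_error(candidateNetwork(nodes,
                                reg = data.frame(regulator = c("G1"),
                                                 target = c("G1"))),
               "self-regulation")
  expect_error(candidateNetwork(nodes,
                                reg = data.frame(regulator = "P1", target = "G1",
                                                 regulator_class = "protein",
                                                 target_class = "gene")),
               "regulator_class")
})

test_that("synthetic generator output round-trips unchanged", {
  tr <- generateTruth(seed = 42)
  net <- asCandidateNetwork(tr)
  dir <- withr::local_tempdir()
  saveNetwork(net, dir)
  net2 <- loadNetwork(file.path(dir, "nodes.tsv"), file.path(dir, "ppi.tsv"),
                      file.path(dir, "reg.tsv"))
  expect_equal(nodeTable(net2), nodeTable(net))
  expect_equal(ppiEdges(net2), ppiEdges(net))
  expect_equal(regEdges(net2), regEdges(net))
})

test_that("design matrix layout follows the regression rewrite", {
  nodes <- data.frame(node_id = c("G1", "T1", "M1"),
                      node_class = c("gene", "TF", "miRNA"))
  net <- candidateNetwork(nodes,
                          reg = data.frame(regulator = c("T1", "M1"),
                                           target = c("G1", "G1")))
  E <- rbind(G1 = c(1, 2, 3, 4), T1 = c(2, 2, 1, 1), M1 = c(1, 0, 1, 0))
  pr <- buildRegression(net, E, "G1")
  expect_equal(dim(pr@X), c(4L, 3L))
  expect_equal(colnames(pr@X), c("T1", "M1", "(basal)"))
  expect_equal(pr@X[, "T1"], E["T1", ])              # TF column: raw expression
  expect_equal(pr@X[, "M1"], E["M1", ] * E["G1", ])  # miRNA column: product with target
  expect_equal(pr@constraintMask, c(FALSE, TRUE, FALSE))
  expect_equal(pr@y, as.numeric(E["G1", ]))
})

test_that("protein design columns are bilinear products", {
  nodes <- data.frame(node_id = c("P1", "P2"),
                      node_class = c("protein", "protein"))
  net <- candidateNetwork(nodes, ppi = data.frame(protein_a = "P1",
                                                  protein_b = "P2"))
  E <- rbind(P1 = c(1, 2), P2 = c(3, 4))
  pr <- buildRegression(net, E, "P1")
  expect_equal(unname(pr@X[, "P2"]), c(3, 8))
  expect_false(any(pr@constraintMask))
})

test_that("a target with no candidates is an intercept-only problem", {
  nodes <- data.frame(node_id = c("G1", "T1"), node_class = c("gene", "TF"))
  net <- candidateNetwork(nodes)
  E <- rbind(G1 = c(1, 2, 3), T1 = c(1, 1, 1))
  pr <- buildRegression(net, E, "G1")
  expect_true(pr@noRegression)
  expect_equal(ncol(pr@X), 1L)
})

test_that("design times true parameters reproduces response minus stored noise", {
  tr <- generateTruth(seed = 5)
  se <- simulateExpression(tr, nSamples = 40, noiseSd = 0.1, seed = 6)
  lam <- S4Vectors::metadata(se)$noise
  net <- asCandidateNetwork(tr)
  ed <- trueEdges(tr)
  for (tid in sample(rownames(lam), 5)) {
    pr <- buildRegression(net, se, tid)
    e <- ed[ed$target == tid, ]
    theta <- stats::setNames(numeric(ncol(pr@X)), colnames(pr@X))
    theta[e$regulator] <- e$ability
    theta["(basal)"] <- tr@basal[tid]
    expect_equal(pr@y - drop(pr@X %*% theta), unname(lam[tid, ]),
                 tolerance = 1e-10)
  }
})
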