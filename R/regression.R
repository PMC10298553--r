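#' Candidate regulators of a target node
#'
#' For a protein-like target, its candidate PPI partners (edge type
#' \code{"ppi"}); for gene/lncRNA/miRNA targets, the candidate TF, lncRNA and
#' miRNA regulators, ordered TF < lncRNA < miRNA and lexicographically within
#' each block so design-matrix columns are deterministic.
#'
#' @param network a \code{CandidateNetwork}.
#' @param targetId node id.
#' @return data.frame with columns \code{regulator}, \code{edge_type}.
#' @export
candidateRegulators <- function(network, targetId) {
  stopifnot(is(network, "CandidateNetwork"))
  nd <- network@nodes
  if (!targetId %in% nd$node_id) stop("unknown target ", targetId)
  cls <- nd$node_class[nd$node_id == targetId]
  if (cls %in% .PROTEIN_LIKE) {
    pp <- network@ppi
    partners <- sort(unique(c(pp$protein_b[pp$protein_a == targetId],
                              pp$protein_a[pp$protein_b == targetId])))
    return(data.frame(regulator = partners,
                      edge_type = rep("ppi", length(partners)),
                      stringsAsFactors = FALSE))
  }
  rg <- network@reg[network@reg$target == targetId, , drop = FALSE]
  blocks <- lapply(c("TF", "lncRNA", "miRNA"), function(b)
    sort(rg$regulator[rg$regulator_class == b]))
  data.frame(regulator = unlist(blocks),
             edge_type = rep(c("TF", "lncRNA", "miRNA"),
                             vapply(blocks, length, integer(1))),
             stringsAsFactors = FALSE)
}

#' Assemble the per-target regression problem
#'
#' Rewrites the target's steady-state model into linear-regression form.
#' For a protein target a with partner r, column r holds the bilinear product
#' p_a[n] * p_r[n]; for gene/lncRNA/miRNA targets, TF and lncRNA columns hold
#' the regulator expression and miRNA columns hold the product
#' m_j[n] * target[n] (the post-transcriptional repression term). The last
#' column is the intercept carrying the basal level. miRNA-product columns
#' are flagged in the constraint mask (coefficients restricted to <= 0).
#'
#' @param network a \code{CandidateNetwork}.
#' @param expr expression data (\code{SummarizedExperiment} or matrix with
#'   node_id rownames).
#' @param targetId node id of the target.
#' @return a \code{RegressionProblem}. A target with no candidate regulators
#'   is returned as an intercept-only problem with \code{noRegression} set.
#' @export
buildRegression <- function(network, expr, targetId) {
  E <- .exprMatrix(expr)
  regs <- candidateRegulators(network, targetId)
  missing <- setdiff(c(targetId, regs$regulator), rownames(E))
  if (length(missing))
    stop("expression missing for node(s): ", paste(missing, collapse = ", "))
  y <- as.numeric(E[targetId, ])
  N <- length(y)
  cls <- network@nodes$node_class[network@nodes$node_id == targetId]
  if (nrow(regs) == 0L) {
    X <- matrix(1, N, 1, dimnames = list(NULL, "(basal)"))
    return(new("RegressionProblem", targetId = targetId, targetClass = cls,
               y = y, X = X, regulators = regs,
               constraintMask = FALSE, noRegression = TRUE))
  }
  cols <- lapply(seq_len(nrow(regs)), function(i) {
    r <- as.numeric(E[regs$regulator[i], ])
    if (regs$edge_type[i] %in% c("ppi", "miRNA")) r * y else r
  })
  X <- cbind(do.call(cbind, cols), 1)
  colnames(X) <- c(regs$regulator, "(basal)")
  new("RegressionProblem", targetId = targetId, targetClass = cls,
      y = y, X = X, regulators = regs,
      constraintMask = c(regs$edge_type == "miRNA", FALSE),
      noRegression = FALSE)
}

#' Reduce candidate regulators to avoid overfitting
#'
#' When the design has more columns than half the sample count, candidate
#' regulators are pre-screened down to the floor(N/2) - 1 columns with the
#' largest absolute Pearson correlation to the response (intercept always
#' kept). Otherwise the problem is returned unchanged.
#'
#' @param problem a \code{RegressionProblem}.
#' @return a \code{RegressionProblem}.
#' @export
guardOverfitting <- function(problem) {
  stopifnot(is(problem, "RegressionProblem"))
  N <- length(problem@y)
  p <- ncol(problem@X)
  if (p <= N / 2) return(problem)
  keep <- max(1L, floor(N / 2) - 1L)
  k <- p - 1L
  cc <- abs(suppressWarnings(
    apply(problem@X[, seq_len(k), drop = FALSE], 2, cor, y = problem@y)))
  cc[is.na(cc)] <- 0
  sel <- sort(order(cc, decreasing = TRUE)[seq_len(min(keep, k))])
  new("RegressionProblem", targetId = problem@targetId,
      targetClass = problem@targetClass, y = problem@y,
      X = problem@X[, c(sel, p), drop = FALSE],
      regulators = problem@regulators[sel, , drop = FALSE],
      constraintMask = problem@constraintMask[c(sel, p)],
      noRegression = problem@noRegression)
}
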