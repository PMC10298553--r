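#' Assemble the network ability matrix W
#'
#' One row per node of the identified network, ordered protein-like (protein,
#' receptor, TF), gene, lncRNA, miRNA blocks and lexicographically within each
#' block; one column per regulator role actually exercised somewhere in the
#' network (PPI partner, TF, lncRNA, miRNA; a node in several roles gets one
#' column per role), ordered ppi < TF < lncRNA < miRNA then lexicographically.
#' Entries are the estimated abilities; PPI abilities fill both endpoint rows
#' (each endpoint's own estimate where available, mirrored otherwise); all
#' other entries are zero. Nodes with no identified edges keep an all-zero
#' row and score zero downstream.
#'
#' @param identified an \code{IdentifiedNetwork} with at least one edge.
#' @return a \code{NetworkMatrix}.
#' @export
assembleW <- function(identified) {
  stopifnot(is(identified, "IdentifiedNetwork"))
  ed <- identified@edges
  if (!nrow(ed)) stop("identified network has no edges")
  nd <- identified@nodes
  blockOf <- function(cls) ifelse(cls %in% .PROTEIN_LIKE, 1L,
                           ifelse(cls == "gene", 2L, ifelse(cls == "lncRNA", 3L, 4L)))
  ord <- order(blockOf(nd$node_class), nd$node_id)
  rows <- nd$node_id[ord]
  rowClass <- nd$node_class[ord]

  roleRank <- c(ppi = 1L, TF = 2L, lncRNA = 3L, miRNA = 4L)
  colKey <- unique(paste(ed$edge_type, ed$regulator, sep = "|"))
  # ppi columns must exist for both endpoints of a mirrored pair
  ppiPairsTab <- unique(ed[ed$edge_type == "ppi", c("target", "regulator")])
  if (nrow(ppiPairsTab))
    colKey <- unique(c(colKey, paste("ppi", ppiPairsTab$target, sep = "|")))
  parts <- strsplit(colKey, "|", fixed = TRUE)
  colRole <- vapply(parts, `[`, character(1), 1)
  colNode <- vapply(parts, `[`, character(1), 2)
  ordc <- order(roleRank[colRole], colNode)
  colRole <- colRole[ordc]; colNode <- colNode[ordc]; colKey <- colKey[ordc]

  W <- matrix(0, length(rows), length(colKey),
              dimnames = list(rows, colKey))
  reg <- ed[ed$edge_type != "ppi", , drop = FALSE]
  if (nrow(reg))
    W[cbind(match(reg$target, rows),
            match(paste(reg$edge_type, reg$regulator, sep = "|"), colKey))] <-
      reg$ability
  ppi <- ed[ed$edge_type == "ppi", , drop = FALSE]
  if (nrow(ppi)) {
    # own-row estimates first, then mirror to the partner row when that
    # endpoint did not select the pair itself
    W[cbind(match(ppi$target, rows),
            match(paste("ppi", ppi$regulator, sep = "|"), colKey))] <- ppi$ability
    own <- paste(ppi$target, ppi$regulator)
    for (i in seq_len(nrow(ppi))) {
      if (!paste(ppi$regulator[i], ppi$target[i]) %in% own)
        W[match(ppi$regulator[i], rows),
          match(paste("ppi", ppi$target[i], sep = "|"), colKey)] <- ppi$ability[i]
    }
  }
  new("NetworkMatrix", W = W, rowClass = rowClass,
      colNode = colNode, colRole = colRole)
}

.asW <- function(x) {
  if (is(x, "NetworkMatrix")) x@W else as.matrix(x)
}

#' Energy rank of a network matrix
#'
#' K is the smallest number of leading singular values whose squared sum
#' reaches at least \code{threshold} of the total squared spectrum (the
#' network "energy"); E_K is the attained fraction.
#'
#' @param W a \code{NetworkMatrix} or plain matrix, not all zero.
#' @param threshold energy fraction to retain (default 0.85).
#' @return list with \code{K}, \code{EK} and the singular values \code{d}.
#' @export
energyRank <- function(W, threshold = 0.85) {
  M <- .asW(W)
  if (all(M == 0)) stop("network matrix is all zero")
  d <- svd(M, nu = 0, nv = 0)$d
  frac <- cumsum(d^2) / sum(d^2)
  K <- which(frac >= threshold)[1]
  list(K = as.integer(K), EK = frac[K], d = d)
}

#' Projection scores of network nodes
#'
#' Projects every row of W (one node) onto the top-K right singular vectors.
#' Mode \code{"l2"} (default) returns the 2-norm of the K projection values,
#' i.e. the length of the row's component inside the dominant energy
#' subspace; mode \code{"sum"} returns their signed sum.
#'
#' @param W a \code{NetworkMatrix} or matrix.
#' @param K number of singular vectors to project on (defaults to the
#'   energy rank at \code{threshold}).
#' @param mode \code{"l2"} or \code{"sum"}.
#' @param threshold energy threshold used when \code{K} is NULL.
#' @return named numeric vector of scores per node (row).
#' @export
projectionScores <- function(W, K = NULL, mode = c("l2", "sum"), threshold = 0.85) {
  mode <- match.arg(mode)
  M <- .asW(W)
  if (is.null(K)) K <- energyRank(M, threshold)$K
  sv <- svd(M)
  if (K > ncol(sv$v)) stop("K exceeds the number of singular vectors")
  proj <- M %*% sv$v[, seq_len(K), drop = FALSE]
  out <- if (mode == "l2") sqrt(rowSums(proj^2)) else rowSums(proj)
  stats::setNames(as.numeric(out), rownames(M))
}

#' Extract the core network from projection scores
#'
#' Selects the top-M nodes by descending projection score (ties broken
#' lexicographically by node id) and induces the subnetwork of identified
#' edges whose two endpoints are both selected.
#'
#' @param identified an \code{IdentifiedNetwork}.
#' @param scores named numeric vector of projection scores (all nodes).
#' @param M core size (default 6000); when M exceeds the node count all
#'   nodes are selected with a warning.
#' @return data.frame of scores with \code{rank} and \code{selected}
#'   columns, ordered by rank; the induced edges are in
#'   \code{attr(, "edges")}.
#' @export
extractCore <- function(identified, scores, M = 6000L) {
  stopifnot(is(identified, "IdentifiedNetwork"), M >= 1)
  ids <- names(scores)
  ord <- order(-scores, ids)
  n <- length(scores)
  if (M > n) {
    warning("core size ", M, " exceeds node count ", n, "; selecting all nodes")
    M <- n
  }
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  df <- data.frame(node_id = ids[ord],
                   node_class = identified@nodes$node_class[
                     match(ids[ord], identified@nodes$node_id)],
                   projection_score = as.numeric(scores[ord]),
                   rank = seq_len(n),
                   selected = seq_len(n) <= M,
                   stringsAsFactors = FALSE)
  selIds <- df$node_id[df$selected]
  ed <- identified@edges
  ed <- ed[ed$target %in% selIds & ed$regulator %in% selIds, , drop = FALSE]
  rownames(ed) <- NULL
  attr(df, "edges") <- ed
  df
}

#' Principal network projection: full core-extraction pipeline
#'
#' Assembles W from an identified network, truncates the SVD at the energy
#' threshold, scores every node by projection onto the retained singular
#' vectors, and extracts the top-M core subnetwork.
#'
#' @param identified an \code{IdentifiedNetwork}.
#' @param M core size (default 6000).
#' @param threshold energy fraction (default 0.85).
#' @param mode projection mode, \code{"l2"} (default) or \code{"sum"}.
#' @return a \code{CoreNetwork}.
#' @export
pnpCore <- function(identified, M = 6000L, threshold = 0.85, mode = c("l2", "sum")) {
  mode <- match.arg(mode)
  nm <- assembleW(identified)
  er <- energyRank(nm, threshold)
  scores <- projectionScores(nm, K = er$K, mode = mode)
  df <- extractCore(identified, scores, M = M)
  new("CoreNetwork", scores = df, edges = attr(df, "edges"),
      singularValues = er$d, K = er$K, energyFraction = er$EK,
      threshold = threshold, mode = mode)
}
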