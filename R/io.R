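#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Construct a candidate network from node and edge tables
#'
#' Canonicalises PPI pairs (lexicographically smaller id first), validates
#' classes and endpoints, and rejects duplicate or self edges. Regulation
#' classes default to the node table's classes when not supplied.
#'
#' @param nodes data.frame with columns \code{node_id}, \code{node_class}.
#' @param ppi data.frame with columns \code{protein_a}, \code{protein_b};
#'   may be empty.
#' @param reg data.frame with columns \code{regulator}, \code{target}
#'   (classes optional); may be empty.
#' @return a \code{CandidateNetwork}.
#' @export
candidateNetwork <- function(nodes,
                             ppi = data.frame(protein_a = character(0),
                                              protein_b = character(0)),
                             reg = data.frame(regulator = character(0),
                                              target = character(0))) {
  nodes <- data.frame(node_id = as.character(nodes$node_id),
                      node_class = as.character(nodes$node_class),
                      stringsAsFactors = FALSE)
  cls <- stats::setNames(nodes$node_class, nodes$node_id)
  ppi <- data.frame(protein_a = as.character(ppi$protein_a),
                    protein_b = as.character(ppi$protein_b),
                    stringsAsFactors = FALSE)
  if (nrow(ppi)) {
    swap <- ppi$protein_a > ppi$protein_b
    tmp <- ppi$protein_a[swap]
    ppi$protein_a[swap] <- ppi$protein_b[swap]
    ppi$protein_b[swap] <- tmp
    ppi <- ppi[order(ppi$protein_a, ppi$protein_b), , drop = FALSE]
    rownames(ppi) <- NULL
  }
  reg <- data.frame(regulator = as.character(reg$regulator),
                    regulator_class = if ("regulator_class" %in% names(reg))
                      as.character(reg$regulator_class) else unname(cls[as.character(reg$regulator)]),
                    target = as.character(reg$target),
                    target_class = if ("target_class" %in% names(reg))
                      as.character(reg$target_class) else unname(cls[as.character(reg$target)]),
                    stringsAsFactors = FALSE)
  if (nrow(reg)) {
    reg <- reg[order(reg$target, reg$regulator), , drop = FALSE]
    rownames(reg) <- NULL
  }
  new("CandidateNetwork", nodes = nodes, ppi = ppi, reg = reg)
}

#' Load a candidate network from TSV files
#'
#' @param nodePath node table TSV (\code{node_id}, \code{node_class}).
#' @param ppiPath PPI TSV (\code{protein_a}, \code{protein_b}).
#' @param regPath regulation TSV (\code{regulator}, \code{regulator_class},
#'   \code{target}, \code{target_class}).
#' @return a \code{CandidateNetwork}.
#' @export
loadNetwork <- function(nodePath, ppiPath, regPath) {
  for (p in c(nodePath, ppiPath, regPath))
    if (!file.exists(p)) stop("file not found: ", p)
  nodes <- .readTsv(nodePath)
  ppi <- .readTsv(ppiPath)
  reg <- .readTsv(regPath)
  ids <- as.character(nodes$node_id)
  .checkEdgeIds <- function(df, cols, path) {
    for (col in cols) {
      bad <- which(!(as.character(df[[col]]) %in% ids))
      if (length(bad))
        stop(sprintf("unknown node '%s' in %s (line %d)",
                     df[[col]][bad[1]], path, bad[1] + 1L))
    }
  }
  if (nrow(ppi)) .checkEdgeIds(ppi, c("protein_a", "protein_b"), ppiPath)
  if (nrow(reg)) .checkEdgeIds(reg, c("regulator", "target"), regPath)
  candidateNetwork(nodes, ppi, reg)
}

#' Save a candidate network as TSV files
#'
#' @param network a \code{CandidateNetwork}.
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
saveNetwork <- function(network, dir) {
  stopifnot(is(network, "CandidateNetwork"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("nodes.tsv", "ppi.tsv", "reg.tsv"))
  .writeTsv(network@nodes, paths[1])
  .writeTsv(network@ppi, paths[2])
  .writeTsv(network@reg, paths[3])
  invisible(paths)
}

#' Build a SummarizedExperiment from an expression matrix
#'
#' @param values numeric matrix, rows = nodes (rownames required),
#'   columns = samples.
#' @param condition character condition label per sample (recycled if
#'   length 1).
#' @return a \code{SummarizedExperiment} with assay \code{"expr"}.
#' @export
expressionData <- function(values, condition = "case") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix needs node_id rownames")
  if (ncol(values) < 2) stop("need at least 2 samples")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  condition <- rep_len(as.character(condition), ncol(values))
  SummarizedExperiment(assays = list(expr = values),
                       colData = DataFrame(condition = condition,
                                           row.names = colnames(values)))
}

#' Read expression values and a sample-condition map from CSV
#'
#' Expression CSV: first column \code{node_id}, remaining columns samples.
#' Condition CSV: columns \code{sample_id}, \code{condition}.
#'
#' @param exprPath expression CSV path.
#' @param conditionPath optional condition-map CSV path.
#' @return a \code{SummarizedExperiment}.
#' @export
readExpression <- function(exprPath, conditionPath = NULL) {
  df <- utils::read.csv(exprPath, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  cond <- "case"
  if (!is.null(conditionPath)) {
    cm <- utils::read.csv(conditionPath, stringsAsFactors = FALSE)
    cond <- stats::setNames(as.character(cm$condition), cm$sample_id)[colnames(m)]
    if (anyNA(cond)) stop("condition map missing samples: ",
                          paste(colnames(m)[is.na(cond)], collapse = ", "))
  }
  expressionData(m, cond)
}

#' Write expression values (and the condition map) to CSV
#'
#' @param se \code{SummarizedExperiment} from \code{expressionData}.
#' @param exprPath,conditionPath output CSV paths.
#' @return invisibly, \code{exprPath}.
#' @export
writeExpression <- function(se, exprPath, conditionPath = NULL) {
  m <- assay(se, "expr")
  df <- data.frame(node_id = rownames(m), round(m, 10), check.names = FALSE)
  utils::write.csv(df, exprPath, row.names = FALSE, quote = FALSE)
  if (!is.null(conditionPath))
    utils::write.csv(data.frame(sample_id = colnames(m),
                                condition = colData(se)$condition),
                     conditionPath, row.names = FALSE, quote = FALSE)
  invisible(exprPath)
}

.exprMatrix <- function(expr) {
  if (is(expr, "SummarizedExperiment")) return(assay(expr, 1))
  as.matrix(expr)
}

#' Write / read an identified network as TSV
#'
#' Two files: an edge table (\code{target}, \code{regulator},
#' \code{edge_type}, \code{ability}) and a per-target summary
#' (\code{target_id}, \code{target_class}, \code{basal_level},
#' \code{residual_variance}, \code{aic}, \code{n_candidates},
#' \code{n_selected}).
#'
#' @param identified an \code{IdentifiedNetwork}.
#' @param dir directory for \code{edges.tsv} and \code{targets.tsv}.
#' @return \code{writeIdentifiedNetwork}: invisibly, the file paths;
#'   \code{readIdentifiedNetwork}: an \code{IdentifiedNetwork} (without AIC
#'   traces).
#' @export
writeIdentifiedNetwork <- function(identified, dir) {
  stopifnot(is(identified, "IdentifiedNetwork"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("edges.tsv", "targets.tsv", "nodes.tsv"))
  .writeTsv(identified@edges, paths[1])
  .writeTsv(identified@targets, paths[2])
  .writeTsv(identified@nodes, paths[3])
  invisible(paths)
}

#' @rdname writeIdentifiedNetwork
#' @export
readIdentifiedNetwork <- function(dir) {
  new("IdentifiedNetwork",
      nodes = .readTsv(file.path(dir, "nodes.tsv")),
      edges = .readTsv(file.path(dir, "edges.tsv")),
      targets = .readTsv(file.path(dir, "targets.tsv")),
      traces = list())
}

#' Export a core network for Cytoscape
#'
#' SIF uses the edge type as the interaction word; GraphML goes through
#' igraph and carries ability and projection-score attributes.
#'
#' @param core a \code{CoreNetwork}.
#' @param sifPath,graphmlPath output paths (either may be NULL).
#' @return invisibly, the written paths.
#' @export
exportCore <- function(core, sifPath = NULL, graphmlPath = NULL) {
  stopifnot(is(core, "CoreNetwork"))
  ed <- core@edges
  written <- character(0)
  if (!is.null(sifPath)) {
    lines <- if (nrow(ed)) paste(ed$regulator, ed$edge_type, ed$target) else character(0)
    writeLines(lines, sifPath)
    written <- c(written, sifPath)
  }
  if (!is.null(graphmlPath)) {
    sel <- core@scores[core@scores$selected, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      d = if (nrow(ed)) data.frame(from = ed$regulator, to = ed$target,
                                   edge_type = ed$edge_type, ability = ed$ability)
          else data.frame(from = character(0), to = character(0)),
      directed = TRUE,
      vertices = data.frame(name = sel$node_id, node_class = sel$node_class,
                            projection_score = sel$projection_score))
    igraph::write_graph(g, graphmlPath, format = "graphml")
    written <- c(written, graphmlPath)
  }
  invisible(written)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}
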