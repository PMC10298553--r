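#' @import methods
NULL

.NODE_CLASSES <- c("protein", "receptor", "TF", "gene", "miRNA", "lncRNA")
.REGULATOR_CLASSES <- c("TF", "lncRNA", "miRNA")
.TARGET_CLASSES <- c("gene", "lncRNA", "miRNA")
# receptors and TFs act as proteins for PPI purposes
.PROTEIN_LIKE <- c("protein", "receptor", "TF")

#' CandidateNetwork: typed candidate interaction/regulation structure
#'
#' A candidate genome-wide genetic and epigenetic network (GWGEN): a binary
#' structure over typed nodes, holding undirected candidate protein-protein
#' interaction (PPI) edges and directed candidate regulation edges from
#' TFs/lncRNAs/miRNAs onto genes/lncRNAs/miRNAs. Edge presence means "this
#' interaction is possible according to prior evidence"; data-driven
#' identification decides which edges are real.
#'
#' @slot nodes data.frame with columns \code{node_id}, \code{node_class}.
#' @slot ppi data.frame with columns \code{protein_a}, \code{protein_b}
#'   (canonicalised so \code{protein_a < protein_b}).
#' @slot reg data.frame with columns \code{regulator}, \code{regulator_class},
#'   \code{target}, \code{target_class}.
#' @export
setClass("CandidateNetwork",
  representation(nodes = "data.frame", ppi = "data.frame", reg = "data.frame"))

setValidity("CandidateNetwork", function(object) {
  nd <- object@nodes; pp <- object@ppi; rg <- object@reg
  msgs <- character(0)
  if (anyDuplicated(nd$node_id)) msgs <- c(msgs, "duplicate node_id in node table")
  if (!all(nd$node_class %in% .NODE_CLASSES))
    msgs <- c(msgs, "unknown node_class in node table")
  ids <- nd$node_id
  if (nrow(pp)) {
    bad <- setdiff(c(pp$protein_a, pp$protein_b), ids)
    if (length(bad)) msgs <- c(msgs, paste0("PPI edge references unknown node ", bad[1]))
    if (any(pp$protein_a == pp$protein_b)) msgs <- c(msgs, "self PPI edge")
    if (anyDuplicated(paste(pp$protein_a, pp$protein_b))) msgs <- c(msgs, "duplicate PPI edge")
  }
  if (nrow(rg)) {
    bad <- setdiff(c(rg$regulator, rg$target), ids)
    if (length(bad)) msgs <- c(msgs, paste0("regulation edge references unknown node ", bad[1]))
    if (!all(rg$regulator_class %in% .REGULATOR_CLASSES))
      msgs <- c(msgs, "regulator_class must be TF, lncRNA or miRNA")
    if (!all(rg$target_class %in% .TARGET_CLASSES))
      msgs <- c(msgs, "target_class must be gene, lncRNA or miRNA")
    if (any(rg$regulator == rg$target)) msgs <- c(msgs, "self-regulation edge")
    if (anyDuplicated(paste(rg$regulator, rg$target))) msgs <- c(msgs, "duplicate regulation edge")
  }
  if (length(msgs)) msgs else TRUE
})

#' GroundTruth: a known-parameter network for simulation
#'
#' Output of the synthetic generator: node table (with a driver flag for
#' exogenous nodes), the true edge set with true abilities, and per-target
#' basal levels. Expression simulated from it satisfies the steady-state
#' interaction/regulation equations exactly, so parameter recovery can be
#' tested to machine precision.
#'
#' @slot nodes data.frame: \code{node_id}, \code{node_class}, \code{is_driver}.
#' @slot edges data.frame: \code{regulator}, \code{target}, \code{edge_type}
#'   (\code{ppi}, \code{TF}, \code{lncRNA}, \code{miRNA}), \code{ability}
#'   (signed; miRNA repression entries are negative).
#' @slot basal named numeric, one entry per non-driver target.
#' @slot seed integer generator seed.
#' @slot config list of generator settings.
#' @export
setClass("GroundTruth",
  representation(nodes = "data.frame", edges = "data.frame", basal = "numeric",
                 seed = "integer", config = "list"))

setValidity("GroundTruth", function(object) {
  mir <- object@edges$edge_type == "miRNA"
  if (any(mir) && any(object@edges$ability[mir] > 0))
    return("miRNA repression abilities must be <= 0 (stored signed)")
  TRUE
})

#' RegressionProblem: per-target linear regression form
#'
#' The per-target rewrite of the steady-state model: response y is the
#' target's expression over N samples; design columns are, for a protein
#' target, the bilinear products p_target * p_partner, and for gene/lncRNA/
#' miRNA targets the TF and lncRNA expressions plus the bilinear
#' miRNA * target products; the final column is the intercept (basal level).
#'
#' @slot targetId character.
#' @slot targetClass character.
#' @slot y numeric response (length N).
#' @slot X numeric design matrix N x (k+1), intercept last.
#' @slot regulators data.frame: \code{regulator}, \code{edge_type}, one row per
#'   non-intercept column, in column order.
#' @slot constraintMask logical per column; TRUE marks miRNA-product columns
#'   whose coefficients are constrained <= 0.
#' @slot noRegression logical; TRUE when the target had no candidate
#'   regulators and only an intercept model is fit.
#' @export
setClass("RegressionProblem",
  representation(targetId = "character", targetClass = "character",
                 y = "numeric", X = "matrix", regulators = "data.frame",
                 constraintMask = "logical", noRegression = "logical"))

setValidity("RegressionProblem", function(object) {
  if (ncol(object@X) != nrow(object@regulators) + 1L)
    return("design must have one column per regulator plus intercept")
  if (length(object@constraintMask) != ncol(object@X))
    return("constraint mask length must equal column count")
  if (object@constraintMask[length(object@constraintMask)])
    return("intercept column cannot be constrained")
  TRUE
})

#' ParameterEstimate: fitted abilities and basal level for one target
#'
#' @slot targetId character.
#' @slot coefficients named numeric, names matching design columns
#'   (intercept named \code{"(basal)"}); miRNA-product coefficients <= 0.
#' @slot constraintMask logical per coefficient.
#' @slot residuals numeric.
#' @slot rho2 numeric residual variance, RSS / N.
#' @slot rankDeficient logical, TRUE if a minimum-norm solution was used.
#' @export
setClass("ParameterEstimate",
  representation(targetId = "character", coefficients = "numeric",
                 constraintMask = "logical", residuals = "numeric",
                 rho2 = "numeric", rankDeficient = "logical"))

setValidity("ParameterEstimate", function(object) {
  if (any(object@constraintMask & object@coefficients > 1e-12))
    return("constrained coefficients must be <= 0")
  if (object@rho2 < 0) return("residual variance must be nonnegative")
  TRUE
})

#' AICTrace: record of the system-order search for one target
#'
#' @slot targetId character.
#' @slot visited data.frame: \code{subset} (comma-joined regulator ids),
#'   \code{k}, \code{rho2}, \code{aic}, one row per model visited.
#' @slot selected character vector of selected regulator ids.
#' @slot aic numeric AIC of the selected model.
#' @slot exhaustive logical; TRUE when all subsets were enumerated.
#' @export
setClass("AICTrace",
  representation(targetId = "character", visited = "data.frame",
                 selected = "character", aic = "numeric", exhaustive = "logical"))

setValidity("AICTrace", function(object) {
  if (nrow(object@visited) && object@aic > min(object@visited$aic) + 1e-9)
    return("selected AIC must be minimal among visited models")
  TRUE
})

#' IdentifiedNetwork: the real network surviving AIC pruning
#'
#' Per-target selected edges with refit abilities, basal levels, residual
#' variances and AIC traces. PPI rows are directed records (target, partner)
#' of each endpoint's own regression; an undirected PPI edge is considered
#' identified only when both endpoint regressions selected it, since the
#' interaction is bidirectional.
#'
#' @slot nodes data.frame as in \code{CandidateNetwork}.
#' @slot edges data.frame: \code{target}, \code{regulator}, \code{edge_type},
#'   \code{ability}.
#' @slot targets data.frame: \code{target_id}, \code{target_class},
#'   \code{basal_level}, \code{residual_variance}, \code{aic},
#'   \code{n_candidates}, \code{n_selected}.
#' @slot traces list of \code{AICTrace} keyed by target id.
#' @export
setClass("IdentifiedNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 targets = "data.frame", traces = "list"))

#' NetworkMatrix: the ability matrix W used by principal network projection
#'
#' Rows are target nodes (protein-like block, then gene, lncRNA, miRNA
#' blocks); columns are regulator roles (PPI partner, TF, lncRNA, miRNA), a
#' node acting in several roles getting one column per role. Entries are
#' estimated abilities, zero where no identified edge.
#'
#' @slot W numeric matrix.
#' @slot rowClass character per row.
#' @slot colNode character regulator node id per column.
#' @slot colRole character per column: \code{ppi}, \code{TF}, \code{lncRNA},
#'   \code{miRNA}.
#' @export
setClass("NetworkMatrix",
  representation(W = "matrix", rowClass = "character",
                 colNode = "character", colRole = "character"))

setValidity("NetworkMatrix", function(object) {
  if (length(object@rowClass) != nrow(object@W)) return("rowClass length mismatch")
  if (length(object@colNode) != ncol(object@W) ||
      length(object@colRole) != ncol(object@W)) return("column annotation mismatch")
  mir <- object@colRole == "miRNA"
  if (any(mir) && any(object@W[, mir] > 1e-12))
    return("miRNA-block entries must be <= 0")
  TRUE
})

#' CoreNetwork: the principal-network-projection core
#'
#' @slot scores data.frame: \code{node_id}, \code{node_class},
#'   \code{projection_score}, \code{rank}, \code{selected}.
#' @slot edges data.frame: identified edges with both endpoints selected.
#' @slot singularValues numeric, non-increasing.
#' @slot K integer energy rank.
#' @slot energyFraction numeric, cumulative energy at K.
#' @slot threshold numeric energy threshold used.
#' @slot mode character projection mode, \code{"l2"} or \code{"sum"}.
#' @export
setClass("CoreNetwork",
  representation(scores = "data.frame", edges = "data.frame",
                 singularValues = "numeric", K = "integer",
                 energyFraction = "numeric", threshold = "numeric",
                 mode = "character"))

setValidity("CoreNetwork", function(object) {
  d <- object@singularValues
  if (length(d) > 1 && any(diff(d) > 1e-9)) return("singular values must be non-increasing")
  if (object@K < 1L) return("energy rank must be >= 1")
  TRUE
})

#' DTIDataset: labelled drug-target feature vectors
#'
#' Each row is one drug-target pair: a drug-feature block (columns prefixed
#' \code{d_}) concatenated with a target-feature block (prefix \code{t_}),
#' plus a binary interaction label (1 proven, 0 unproven).
#'
#' @slot features numeric matrix, rows = pairs.
#' @slot labels integer 0/1 per row.
#' @slot pairIds character per row.
#' @slot drugCols,targetCols character column names of the two blocks.
#' @slot truth list; for synthetic data, the planted rule (\code{w}, \code{b}).
#' @export
setClass("DTIDataset",
  representation(features = "matrix", labels = "integer", pairIds = "character",
                 drugCols = "character", targetCols = "character", truth = "list"))

setValidity("DTIDataset", function(object) {
  if (nrow(object@features) != length(object@labels)) return("label length mismatch")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (!setequal(colnames(object@features), c(object@drugCols, object@targetCols)))
    return("feature columns must be the union of drug and target blocks")
  TRUE
})

#' DTIModel: trained feed-forward drug-target-interaction classifier
#'
#' Fully connected network with ReLU hidden layers and a sigmoid output,
#' trained with Adam on binary cross-entropy. Carries the preprocessing
#' transforms (standardizer + PCA basis, fitted on training data only) so
#' prediction on raw features is one call.
#'
#' @slot weights list of weight matrices (input to output order).
#' @slot biases list of bias vectors.
#' @slot config list of hyperparameters.
#' @slot standardizer list: \code{mean}, \code{sd}, \code{kept}.
#' @slot basis list: \code{center}, \code{rotation}, \code{explained}.
#' @slot cv data.frame of per-fold validation/testing loss and accuracy.
#' @slot history list of per-fold learning curves.
#' @slot schema list: \code{drugCols}, \code{targetCols} expected at predict.
#' @export
setClass("DTIModel",
  representation(weights = "list", biases = "list", config = "list",
                 standardizer = "list", basis = "list", cv = "data.frame",
                 history = "list", schema = "list"))

setMethod("show", "CandidateNetwork", function(object) {
  cat("CandidateNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@ppi), "candidate PPI edges,",
      nrow(object@reg), "candidate regulation edges\n")
  print(table(object@nodes$node_class))
})

setMethod("show", "IdentifiedNetwork", function(object) {
  cat("IdentifiedNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "identified directed edge records\n")
  if (nrow(object@edges)) print(table(object@edges$edge_type))
})

setMethod("show", "CoreNetwork", function(object) {
  cat("CoreNetwork: rank K =", object@K,
      sprintf("(energy %.3f, threshold %.2f),", object@energyFraction, object@threshold),
      sum(object@scores$selected), "of", nrow(object@scores), "nodes selected\n")
})

setMethod("show", "DTIModel", function(object) {
  sizes <- vapply(object@weights, ncol, integer(1))
  cat("DTIModel: layers", paste(c(nrow(object@weights[[1]]), sizes), collapse = " -> "), "\n")
  if (nrow(object@cv)) {
    cat(sprintf("  mean test accuracy %.4f (sd %.4f) over %d folds\n",
                mean(object@cv$test_accuracy), stats::sd(object@cv$test_accuracy),
                nrow(object@cv)))
  }
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@nodes), "nodes,", nrow(object@edges),
      "true edges, seed", object@seed, "\n")
})
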