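#' Accessors for network objects
#'
#' \code{nodeTable} returns the typed node table; \code{ppiEdges} and
#' \code{regEdges} the candidate edge tables; \code{identifiedEdges} the
#' selected edge table of an identified network; \code{targetSummary} the
#' per-target fit summary; \code{coreScores} the projection-score table and
#' \code{coreEdges} the induced core subnetwork.
#'
#' @param object a network object.
#' @return a data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(object) standardGeneric("nodeTable"))
#' @rdname accessors
#' @export
setGeneric("ppiEdges", function(object) standardGeneric("ppiEdges"))
#' @rdname accessors
#' @export
setGeneric("regEdges", function(object) standardGeneric("regEdges"))
#' @rdname accessors
#' @export
setGeneric("identifiedEdges", function(object) standardGeneric("identifiedEdges"))
#' @rdname accessors
#' @export
setGeneric("targetSummary", function(object) standardGeneric("targetSummary"))
#' @rdname accessors
#' @export
setGeneric("coreScores", function(object) standardGeneric("coreScores"))
#' @rdname accessors
#' @export
setGeneric("coreEdges", function(object) standardGeneric("coreEdges"))
#' @rdname accessors
#' @export
setGeneric("trueEdges", function(object) standardGeneric("trueEdges"))

#' @rdname accessors
#' @export
setMethod("nodeTable", "CandidateNetwork", function(object) object@nodes)
#' @rdname accessors
#' @export
setMethod("nodeTable", "IdentifiedNetwork", function(object) object@nodes)
#' @rdname accessors
#' @export
setMethod("nodeTable", "GroundTruth", function(object) object@nodes)
#' @rdname accessors
#' @export
setMethod("ppiEdges", "CandidateNetwork", function(object) object@ppi)
#' @rdname accessors
#' @export
setMethod("regEdges", "CandidateNetwork", function(object) object@reg)
#' @rdname accessors
#' @export
setMethod("identifiedEdges", "IdentifiedNetwork", function(object) object@edges)
#' @rdname accessors
#' @export
setMethod("targetSummary", "IdentifiedNetwork", function(object) object@targets)
#' @rdname accessors
#' @export
setMethod("coreScores", "CoreNetwork", function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("coreEdges", "CoreNetwork", function(object) object@edges)
#' @rdname accessors
#' @export
setMethod("trueEdges", "GroundTruth", function(object) object@edges)

#' Accessors for DTI objects
#'
#' @param object a \code{DTIDataset} or \code{DTIModel}.
#' @return \code{dtiFeatures}: the feature matrix; \code{dtiLabels}: the 0/1
#'   label vector; \code{cvReport}: per-fold validation/testing metrics.
#' @name dti-accessors
NULL

#' @rdname dti-accessors
#' @export
setGeneric("dtiFeatures", function(object) standardGeneric("dtiFeatures"))
#' @rdname dti-accessors
#' @export
setGeneric("dtiLabels", function(object) standardGeneric("dtiLabels"))
#' @rdname dti-accessors
#' @export
setGeneric("cvReport", function(object) standardGeneric("cvReport"))

#' @rdname dti-accessors
#' @export
setMethod("dtiFeatures", "DTIDataset", function(object) object@features)
#' @rdname dti-accessors
#' @export
setMethod("dtiLabels", "DTIDataset", function(object) object@labels)
#' @rdname dti-accessors
#' @export
setMethod("cvReport", "DTIModel", function(object) object@cv)
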