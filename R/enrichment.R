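#' Gene-set over-representation test for a core network
#'
#' One-sided hypergeometric tail test per set: the p-value is
#' P(X >= overlap) for X ~ Hypergeometric(set size, universe - set size,
#' core size), with Benjamini-Hochberg adjustment across sets. This is the
#' generic stand-in for annotating a core network against curated pathway
#' collections.
#'
#' @param coreNodes character vector of selected node ids (must be a subset
#'   of the universe).
#' @param sets named list of character vectors (e.g. from \code{readGMT}).
#' @param universe character vector of all node ids under consideration;
#'   defaults to the union of the sets and the core.
#' @return data.frame with columns \code{set}, \code{set_size},
#'   \code{overlap}, \code{p_value}, \code{p_adjust}, sorted ascending by
#'   p-value. Empty collection gives an empty table.
#' @export
enrichCore <- function(coreNodes, sets, universe = NULL) {
  if (is.null(universe)) universe <- unique(c(unlist(sets), coreNodes))
  coreNodes <- unique(coreNodes)
  if (!all(coreNodes %in% universe))
    stop("core nodes must be contained in the universe")
  if (!length(sets))
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      p_adjust = numeric(0)))
  bad <- vapply(sets, function(s) !all(s %in% universe), logical(1))
  if (any(bad))
    stop("set(s) not contained in universe: ",
         paste(names(sets)[bad], collapse = ", "))
  nU <- length(universe)
  nC <- length(coreNodes)
  rows <- lapply(names(sets), function(nm) {
    s <- unique(sets[[nm]])
    ov <- length(intersect(s, coreNodes))
    p <- stats::phyper(ov - 1L, length(s), nU - length(s), nC,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = ov, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
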