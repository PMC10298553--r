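#' Akaike information criterion for a fitted target model
#'
#' AIC = log(rho^2) + 2 (k + 1) / N, natural log, where rho^2 is the residual
#' variance (RSS / N), k the number of selected regulators and the +1 counts
#' the basal-level intercept. rho^2 is floored at 1e-12 (with a warning) so a
#' perfectly fit target does not produce -Inf.
#'
#' @param rho2 residual variance.
#' @param k number of regulators in the model.
#' @param N sample count.
#' @return numeric AIC value.
#' @export
aicScore <- function(rho2, k, N) {
  stopifnot(k >= 0, N >= 1)
  if (rho2 < 1e-12) {
    warning("residual variance floored at 1e-12 for AIC")
    rho2 <- 1e-12
  }
  log(rho2) + 2 * (k + 1) / N
}

# fit the model restricted to the given regressor columns (intercept kept)
.fitSubset <- function(problem, subset) {
  p <- ncol(problem@X)
  cols <- c(subset, p)
  fit <- .clsFit(problem@X[, cols, drop = FALSE], problem@y,
                 problem@constraintMask[cols])
  res <- problem@y - drop(problem@X[, cols, drop = FALSE] %*% fit$theta)
  rho2 <- sum(res^2) / length(problem@y)
  aic <- log(max(rho2, 1e-12)) + 2 * (length(subset) + 1) / length(problem@y)
  list(theta = stats::setNames(fit$theta, colnames(problem@X)[cols]),
       res = res, rho2 = rho2, aic = aic, rankDeficient = fit$rankDeficient)
}

#' Select the system order of one target by AIC minimisation
#'
#' Chooses the regulator subset minimising
#' AIC = log(rho^2) + 2(k+1)/N, refitting the constrained least-squares
#' problem for every candidate subset. With at most \code{exhaustiveLimit}
#' candidate regulators the search is exhaustive over all subsets (ties
#' broken toward the smaller subset, then enumeration order); beyond the
#' limit a greedy backward elimination is used: repeatedly drop the regulator
#' whose removal most decreases AIC, stopping when no single removal helps.
#'
#' @param problem a \code{RegressionProblem}, ideally after
#'   \code{guardOverfitting}.
#' @param exhaustiveLimit maximum candidate count for exhaustive search
#'   (default 12, i.e. 4096 refits).
#' @return list with elements \code{estimate} (a \code{ParameterEstimate} for
#'   the selected model; unselected regulators get coefficient 0) and
#'   \code{trace} (an \code{AICTrace}).
#' @export
selectOrder <- function(problem, exhaustiveLimit = 12L) {
  stopifnot(is(problem, "RegressionProblem"))
  N <- length(problem@y)
  k <- ncol(problem@X) - 1L
  regs <- colnames(problem@X)[seq_len(k)]
  visited <- list()
  best <- NULL
  bestSubset <- integer(0)
  consider <- function(subset) {
    f <- .fitSubset(problem, subset)
    visited[[length(visited) + 1L]] <<- data.frame(
      subset = paste(colnames(problem@X)[subset], collapse = ","),
      k = length(subset), rho2 = f$rho2, aic = f$aic, stringsAsFactors = FALSE)
    if (is.null(best) || f$aic < best$aic - 1e-12) {
      best <<- f
      bestSubset <<- subset
    }
    f
  }
  exhaustive <- k <= exhaustiveLimit
  if (exhaustive) {
    for (size in 0:k)
      for (s in if (size == 0) list(integer(0)) else
           asplit(utils::combn(k, size), 2))
        consider(as.integer(s))
  } else {
    current <- seq_len(k)
    cur <- consider(current)
    repeat {
      trials <- lapply(current, function(j) .fitSubset(problem, setdiff(current, j)))
      aics <- vapply(trials, `[[`, numeric(1), "aic")
      if (!length(aics) || min(aics) >= cur$aic - 1e-12) break
      j <- which.min(aics)
      current <- setdiff(current, current[j])
      cur <- consider(current)
    }
    if (length(current)) consider(integer(0))
  }
  coef <- stats::setNames(numeric(k + 1L), colnames(problem@X))
  coef[names(best$theta)] <- best$theta
  estimate <- new("ParameterEstimate", targetId = problem@targetId,
                  coefficients = coef, constraintMask = problem@constraintMask,
                  residuals = best$res, rho2 = best$rho2,
                  rankDeficient = best$rankDeficient)
  trace <- new("AICTrace", targetId = problem@targetId,
               visited = do.call(rbind, visited),
               selected = colnames(problem@X)[bestSubset],
               aic = best$aic, exhaustive = exhaustive)
  list(estimate = estimate, trace = trace)
}

#' Prune a candidate network to the identified (real) network
#'
#' Runs the full system-identification and system-order-detection loop: for
#' every target node, assembles the regression problem, applies the
#' overfitting guard, minimises AIC over regulator subsets under the
#' miRNA sign constraint, and keeps only the selected edges with their refit
#' abilities. Targets without expression rows are excluded with a message.
#'
#' @param network a \code{CandidateNetwork}.
#' @param expr expression data (\code{SummarizedExperiment} or matrix).
#' @param exhaustiveLimit passed to \code{selectOrder}.
#' @param keepTraces logical; store per-target \code{AICTrace}s (default TRUE).
#' @return an \code{IdentifiedNetwork}.
#' @export
pruneNetwork <- function(network, expr, exhaustiveLimit = 12L, keepTraces = TRUE) {
  stopifnot(is(network, "CandidateNetwork"))
  E <- .exprMatrix(expr)
  nd <- network@nodes
  skip <- setdiff(nd$node_id, rownames(E))
  if (length(skip))
    message("excluding ", length(skip), " target(s) without expression: ",
            paste(utils::head(skip, 5), collapse = ", "))
  targets <- nd$node_id[!nd$node_id %in% skip]
  edgeRows <- list()
  tgtRows <- list()
  traces <- list()
  for (tid in targets) {
    prob <- guardOverfitting(buildRegression(network, E, tid))
    sel <- selectOrder(prob, exhaustiveLimit = exhaustiveLimit)
    est <- sel$estimate
    chosen <- sel$trace@selected
    if (length(chosen)) {
      ri <- match(chosen, prob@regulators$regulator)
      edgeRows[[tid]] <- data.frame(
        target = tid, regulator = chosen,
        edge_type = prob@regulators$edge_type[ri],
        ability = unname(est@coefficients[chosen]),
        stringsAsFactors = FALSE)
    }
    tgtRows[[tid]] <- data.frame(
      target_id = tid,
      target_class = prob@targetClass,
      basal_level = basalLevel(est),
      residual_variance = est@rho2,
      aic = sel$trace@aic,
      n_candidates = nrow(prob@regulators),
      n_selected = length(chosen),
      stringsAsFactors = FALSE)
    if (keepTraces) traces[[tid]] <- sel$trace
  }
  edges <- if (length(edgeRows)) do.call(rbind, edgeRows) else
    data.frame(target = character(0), regulator = character(0),
               edge_type = character(0), ability = numeric(0))
  rownames(edges) <- NULL
  # a PPI edge is bidirectional: keep it only when both endpoint
  # regressions retain it, which suppresses one-sided spurious selections
  if (nrow(edges)) {
    isPpi <- edges$edge_type == "ppi"
    fwd <- paste(edges$target, edges$regulator)
    rev <- paste(edges$regulator, edges$target)
    drop <- isPpi & !(rev %in% fwd[isPpi])
    edges <- edges[!drop, , drop = FALSE]
    rownames(edges) <- NULL
  }
  tgt <- do.call(rbind, tgtRows)
  rownames(tgt) <- NULL
  new("IdentifiedNetwork", nodes = nd, edges = edges, targets = tgt,
      traces = traces)
}

#' Per-edge-type counts of an identified network
#'
#' PPI edges are counted once per unordered pair (identified when selected in
#' at least one endpoint's regression); regulation edges once per directed
#' (regulator, target) pair.
#'
#' @param identified an \code{IdentifiedNetwork}.
#' @return named integer vector over edge types.
#' @export
edgeCounts <- function(identified) {
  keys <- .edgeKeys(identified@edges)
  tab <- table(sub("\\|.*", "", unique(keys)))
  out <- stats::setNames(integer(4), c("ppi", "TF", "lncRNA", "miRNA"))
  out[names(tab)] <- as.integer(tab)
  out
}

# canonical edge keys: ppi unordered, regulation directed
.edgeKeys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  ifelse(edges$edge_type == "ppi",
         paste0("ppi|", pmin(edges$target, edges$regulator), "|",
                pmax(edges$target, edges$regulator)),
         paste0(edges$edge_type, "|", edges$regulator, ">", edges$target))
}
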