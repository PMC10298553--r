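#' Generate a ground-truth network with known abilities
#'
#' Builds a typed network whose steady-state equations can be solved in
#' closed form, so simulated expression satisfies the interaction/regulation
#' models exactly. Proteins are split into exogenous hubs (about a third)
#' and leaf targets whose PPI partners are hubs; lncRNAs and miRNAs are
#' split into exogenous driver halves and regulated target halves; TFs are
#' all exogenous. Regulators of genes and of target lncRNAs/miRNAs are drawn
#' from TFs + driver lncRNAs + driver miRNAs. Free-signed abilities are
#' drawn from +/- Uniform(0.1, 1); miRNA repression strengths from
#' Uniform(0.1, 1) and stored with negative sign; PPI abilities are rescaled
#' per protein so the steady-state denominator 1 - sum(tau p_r) stays within
#' [0.5, 1.5] for typical driver levels.
#'
#' @param nProteins,nTfs,nGenes,nLnc,nMirna node counts per class.
#' @param edgesPerTarget incoming edges per non-driver target.
#' @param seed integer seed.
#' @return a \code{GroundTruth}.
#' @export
generateTruth <- function(nProteins = 8L, nTfs = 6L, nGenes = 12L,
                          nLnc = 4L, nMirna = 4L, edgesPerTarget = 2L,
                          seed = 1L) {
  stopifnot(edgesPerTarget >= 1)
  withSeed(seed, {
    mk <- function(prefix, n) if (n > 0) sprintf("%s%02d", prefix, seq_len(n)) else character(0)
    prot <- mk("P", nProteins); tfs <- mk("T", nTfs); genes <- mk("G", nGenes)
    lnc <- mk("L", nLnc); mir <- mk("M", nMirna)
    hubs <- if (nProteins > 1) prot[seq_len(max(1L, ceiling(nProteins / 3)))] else prot
    leaves <- setdiff(prot, hubs)
    lncDrv <- if (nLnc > 0) lnc[seq_len(ceiling(nLnc / 2))] else character(0)
    lncTgt <- setdiff(lnc, lncDrv)
    mirDrv <- if (nMirna > 0) mir[seq_len(ceiling(nMirna / 2))] else character(0)
    mirTgt <- setdiff(mir, mirDrv)
    pool <- c(tfs, lncDrv, mirDrv)
    cls <- c(stats::setNames(rep("protein", length(prot)), prot),
             stats::setNames(rep("TF", length(tfs)), tfs),
             stats::setNames(rep("gene", length(genes)), genes),
             stats::setNames(rep("lncRNA", length(lnc)), lnc),
             stats::setNames(rep("miRNA", length(mir)), mir))
    drivers <- c(hubs, tfs, lncDrv, mirDrv)
    freeAbility <- function(n) sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.1, 1)
    edges <- list()
    basal <- numeric(0)
    for (lv in leaves) {
      if (edgesPerTarget > length(hubs))
        stop("impossible degree request: leaf proteins need ", edgesPerTarget,
             " hub partners but only ", length(hubs), " exist")
      partners <- sort(sample(hubs, edgesPerTarget))
      tau <- freeAbility(length(partners))
      if (sum(abs(tau)) > 0.4) tau <- tau * 0.4 / sum(abs(tau))
      edges[[length(edges) + 1L]] <- data.frame(
        regulator = partners, target = lv, edge_type = "ppi", ability = tau,
        stringsAsFactors = FALSE)
      basal[lv] <- runif(1, 0.5, 1.5)
    }
    regTargets <- c(genes, lncTgt, mirTgt)
    mirPool <- mirDrv
    otherPool <- c(tfs, lncDrv)
    for (tg in regTargets) {
      if (edgesPerTarget > length(pool))
        stop("impossible degree request: ", edgesPerTarget,
             " regulators requested but the driver pool has ", length(pool))
      # at most one miRNA repressor per target: several repressors of the
      # same target enter the regression as nearly collinear m * target
      # products and are not separately identifiable at desk scale
      nMir <- if (length(mirPool) && length(otherPool) >= edgesPerTarget - 1L)
        rbinom(1, 1, 0.5) else max(0L, edgesPerTarget - length(otherPool))
      nMir <- min(nMir, length(mirPool), edgesPerTarget)
      regs <- sort(c(if (nMir > 0) sample(mirPool, nMir),
                     sample(otherPool, edgesPerTarget - nMir)))
      ab <- numeric(length(regs))
      isMir <- cls[regs] == "miRNA"
      ab[isMir] <- -runif(sum(isMir), 0.1, 1)
      ab[!isMir] <- freeAbility(sum(!isMir))
      edges[[length(edges) + 1L]] <- data.frame(
        regulator = regs, target = tg, edge_type = unname(cls[regs]),
        ability = ab, stringsAsFactors = FALSE)
      # basal large enough that the steady state stays positive for typical
      # driver levels (drivers rarely exceed ~2.2 under truncated N(1, 0.3))
      neg <- !isMir & ab < 0
      basal[tg] <- 0.5 + 2.4 * sum(abs(ab[neg]))
    }
    edf <- if (length(edges)) do.call(rbind, edges) else
      data.frame(regulator = character(0), target = character(0),
                 edge_type = character(0), ability = numeric(0))
    rownames(edf) <- NULL
    nodes <- data.frame(node_id = names(cls), node_class = unname(cls),
                        is_driver = names(cls) %in% drivers,
                        stringsAsFactors = FALSE)
    new("GroundTruth", nodes = nodes, edges = edf, basal = basal,
        seed = as.integer(seed),
        config = list(nProteins = nProteins, nTfs = nTfs, nGenes = nGenes,
                      nLnc = nLnc, nMirna = nMirna,
                      edgesPerTarget = edgesPerTarget,
                      hubs = hubs, leaves = leaves, lncDrivers = lncDrv,
                      mirDrivers = mirDrv, pool = pool))
  })
}

#' The candidate network containing exactly the true edges
#'
#' @param truth a \code{GroundTruth}.
#' @return a \code{CandidateNetwork} (binary; abilities dropped).
#' @export
asCandidateNetwork <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  ed <- truth@edges
  ppi <- ed[ed$edge_type == "ppi", , drop = FALSE]
  reg <- ed[ed$edge_type != "ppi", , drop = FALSE]
  candidateNetwork(truth@nodes[, c("node_id", "node_class")],
                   ppi = data.frame(protein_a = ppi$regulator,
                                    protein_b = ppi$target),
                   reg = data.frame(regulator = reg$regulator,
                                    target = reg$target))
}

#' Simulate expression satisfying the steady-state models exactly
#'
#' Per sample, exogenous drivers (TFs, driver lncRNAs/miRNAs, hub proteins)
#' are drawn from a truncated-positive Normal(1, 0.3); every regulated
#' target is then solved in closed form from its equation, e.g. a gene
#' g = (sum(alpha t) + sum(beta l) + basal + noise) / (1 + sum(delta m)),
#' and a leaf protein p = (basal + noise) / (1 - sum(tau p_hub)). Samples
#' whose protein denominator leaves [0.5, 1.5] or whose expression would go
#' negative have their drivers redrawn (up to 50 tries). The noise draws are
#' stored in the metadata so the regression residual can be compared to them
#' exactly.
#'
#' @param truth a \code{GroundTruth}.
#' @param nSamples number of samples (>= 2).
#' @param noiseSd standard deviation of the additive noise.
#' @param seed integer seed.
#' @param condition condition label for all samples.
#' @return a \code{SummarizedExperiment}; \code{metadata(se)$noise} holds the
#'   per-target noise draws, \code{metadata(se)$seed} the seed.
#' @export
simulateExpression <- function(truth, nSamples = 120L, noiseSd = 0.05,
                               seed = 1L, condition = "case") {
  stopifnot(is(truth, "GroundTruth"), nSamples >= 2)
  nd <- truth@nodes
  ed <- truth@edges
  drivers <- nd$node_id[nd$is_driver]
  eqTargets <- names(truth@basal)
  byTarget <- split(ed, ed$target)
  withSeed(seed, {
    lam <- matrix(rnorm(length(eqTargets) * nSamples, 0, noiseSd),
                  length(eqTargets), nSamples,
                  dimnames = list(eqTargets, NULL))
    E <- matrix(NA_real_, nrow(nd), nSamples,
                dimnames = list(nd$node_id, paste0("s", seq_len(nSamples))))
    truncPos <- function(n) {
      x <- rnorm(n, 1, 0.3)
      while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), 1, 0.3)
      x
    }
    for (s in seq_len(nSamples)) {
      ok <- FALSE
      for (try in seq_len(50L)) {
        drv <- stats::setNames(truncPos(length(drivers)), drivers)
        vals <- drv
        feasible <- TRUE
        for (tg in eqTargets) {
          e <- byTarget[[tg]]
          isMir <- e$edge_type == "miRNA"
          isPpi <- e$edge_type == "ppi"
          if (any(isPpi)) {
            denom <- 1 - sum(e$ability[isPpi] * vals[e$regulator[isPpi]])
            if (denom < 0.5 || denom > 1.5) { feasible <- FALSE; break }
            x <- (truth@basal[tg] + lam[tg, s]) / denom
          } else {
            num <- sum(e$ability[!isMir] * vals[e$regulator[!isMir]]) +
              truth@basal[tg] + lam[tg, s]
            denom <- 1 - sum(e$ability[isMir] * vals[e$regulator[isMir]])
            x <- num / denom
          }
          if (x < 0) { feasible <- FALSE; break }
          vals[tg] <- unname(x)
        }
        if (feasible) { E[names(vals), s] <- vals; ok <- TRUE; break }
      }
      if (!ok) stop("could not draw a feasible sample after 50 tries; ",
                    "reduce abilities or noise")
    }
    se <- expressionData(E, condition = condition)
    S4Vectors::metadata(se)$noise <- lam
    S4Vectors::metadata(se)$seed <- as.integer(seed)
    se
  })
}

#' Corrupt the true network with decoy candidate edges
#'
#' Adds ceiling(decoyFraction * n_true) class-compatible decoy edges (never
#' duplicating a true edge, never self edges), drawn uniformly from the
#' possible non-edges, to emulate the false positives a database-derived
#' candidate network carries.
#'
#' @param truth a \code{GroundTruth}.
#' @param decoyFraction nonnegative decoy-to-true ratio.
#' @param seed integer seed.
#' @return a \code{CandidateNetwork} containing true and decoy edges.
#' @export
corruptCandidate <- function(truth, decoyFraction = 0.5, seed = 1L) {
  stopifnot(is(truth, "GroundTruth"), decoyFraction >= 0)
  base <- asCandidateNetwork(truth)
  nDecoy <- ceiling(decoyFraction * nrow(truth@edges))
  if (nDecoy == 0) return(base)
  nd <- truth@nodes
  prot <- nd$node_id[nd$node_class %in% .PROTEIN_LIKE]
  regulators <- nd$node_id[nd$node_class %in% .REGULATOR_CLASSES]
  targets <- nd$node_id[nd$node_class %in% .TARGET_CLASSES]
  trueKeys <- .edgeKeys(truth@edges)
  ppiPool <- if (length(prot) > 1) {
    cmb <- t(utils::combn(sort(prot), 2))
    keys <- paste0("ppi|", cmb[, 1], "|", cmb[, 2])
    cmb[!keys %in% trueKeys, , drop = FALSE]
  } else matrix(character(0), 0, 2)
  regPool <- expand.grid(regulator = regulators, target = targets,
                         stringsAsFactors = FALSE)
  regPool <- regPool[regPool$regulator != regPool$target, , drop = FALSE]
  cls <- stats::setNames(nd$node_class, nd$node_id)
  keys <- paste0(cls[regPool$regulator], "|", regPool$regulator, ">", regPool$target)
  regPool <- regPool[!keys %in% trueKeys, , drop = FALSE]
  total <- nrow(ppiPool) + nrow(regPool)
  if (nDecoy > total)
    stop("requested ", nDecoy, " decoys but only ", total, " non-edges exist")
  withSeed(seed, {
    pick <- sort(sample(total, nDecoy))
    ppiPick <- pick[pick <= nrow(ppiPool)]
    regPick <- pick[pick > nrow(ppiPool)] - nrow(ppiPool)
    ppi <- rbind(base@ppi,
                 data.frame(protein_a = ppiPool[ppiPick, 1],
                            protein_b = ppiPool[ppiPick, 2],
                            stringsAsFactors = FALSE))
    reg <- rbind(base@reg[, c("regulator", "target")],
                 regPool[regPick, , drop = FALSE])
    candidateNetwork(nd[, c("node_id", "node_class")], ppi = ppi, reg = reg)
  })
}

#' Edge-level recovery of an identified network against the truth
#'
#' PPI edges are compared as unordered pairs; regulation edges as directed
#' pairs.
#'
#' @param identified an \code{IdentifiedNetwork}.
#' @param truth a \code{GroundTruth}.
#' @return list with \code{precision}, \code{recall}, \code{tp}, \code{fp},
#'   \code{fn}.
#' @export
edgeRecovery <- function(identified, truth) {
  found <- unique(.edgeKeys(identified@edges))
  want <- unique(.edgeKeys(truth@edges))
  tp <- length(intersect(found, want))
  list(precision = if (length(found)) tp / length(found) else NA_real_,
       recall = if (length(want)) tp / length(want) else NA_real_,
       tp = tp, fp = length(found) - tp, fn = length(want) - tp)
}

#' Generate a planted-rule drug-target interaction dataset
#'
#' Features are standard normal; labels are Bernoulli with success
#' probability sigmoid(x . w + b), where w is sparse (about 40% of features
#' active, random signs, rescaled to \code{signalScale}) and b is tuned by
#' bisection so the expected positive fraction equals
#' imbalanceRatio / (1 + imbalanceRatio). The default ratio emulates a
#' proven:unproven imbalance of roughly 0.8.
#'
#' @param nPairs number of drug-target pairs (>= 20).
#' @param mDrugFeats,nTargetFeats feature counts of the two blocks.
#' @param imbalanceRatio positive-to-negative ratio to aim for.
#' @param seed integer seed.
#' @param signalScale 2-norm of the planted weight vector; the default makes
#'   the rule effectively linearly separable (Bayes error about 1%), so a
#'   well-trained classifier and a linear baseline can both learn it.
#' @return a \code{DTIDataset}; the planted rule is stored in \code{@truth}.
#' @export
generateDTI <- function(nPairs = 2000L, mDrugFeats = 10L, nTargetFeats = 10L,
                        imbalanceRatio = 0.803, seed = 1L, signalScale = 60) {
  stopifnot(nPairs >= 20)
  withSeed(seed, {
    p <- mDrugFeats + nTargetFeats
    X <- matrix(rnorm(nPairs * p), nPairs, p)
    colnames(X) <- c(sprintf("d_%03d", seq_len(mDrugFeats)),
                     sprintf("t_%03d", seq_len(nTargetFeats)))
    w <- numeric(p)
    nz <- sample(p, max(1L, ceiling(0.4 * p)))
    w[nz] <- runif(length(nz), 0.5, 1.5) * sample(c(-1, 1), length(nz), TRUE)
    w <- w * signalScale / sqrt(sum(w^2))
    s <- drop(X %*% w)
    targetFrac <- imbalanceRatio / (1 + imbalanceRatio)
    lo <- -30; hi <- 30
    for (i in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (mean(.sigmoid(s + mid)) < targetFrac) lo <- mid else hi <- mid
    }
    b <- (lo + hi) / 2
    labels <- rbinom(nPairs, 1, .sigmoid(s + b))
    ds <- dtiDataset(X, labels)
    ds@truth <- list(w = stats::setNames(w, colnames(X)), b = b,
                     signalScale = signalScale)
    ds
  })
}
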