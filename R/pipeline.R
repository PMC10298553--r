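#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run. Defaults equal the
#' reference values where the method states them (energy threshold 0.85,
#' core size 6000, the DTI hyperparameters in \code{dtiConfig}); the
#' synthetic-data sizes are desk-scale study conditions.
#'
#' @param nProteins,nTfs,nGenes,nLnc,nMirna synthetic network sizes.
#' @param edgesPerTarget true incoming edges per regulated node.
#' @param nSamples samples per condition.
#' @param noiseSd expression noise standard deviation.
#' @param decoyFraction decoy-to-true candidate edge ratio.
#' @param exhaustiveLimit AIC search exhaustive-enumeration cap.
#' @param energyThreshold SVD energy fraction for the core.
#' @param coreSize core node count M (capped at the node count).
#' @param projectionMode \code{"l2"} or \code{"sum"}.
#' @param geneSets optional named list of gene sets for enrichment.
#' @param dti logical; train the DTI classifier stage.
#' @param dtiPairs synthetic DTI pairs when \code{dti} is TRUE.
#' @param dtiSettings from \code{dtiConfig()}.
#' @param screenSettings from \code{screenConfig()}.
#' @return a config list.
#' @export
pipelineConfig <- function(nProteins = 8L, nTfs = 6L, nGenes = 12L,
                           nLnc = 4L, nMirna = 4L, edgesPerTarget = 2L,
                           nSamples = 120L, noiseSd = 0.05,
                           decoyFraction = 0.5, exhaustiveLimit = 12L,
                           energyThreshold = 0.85, coreSize = 6000L,
                           projectionMode = "l2", geneSets = NULL,
                           dti = FALSE, dtiPairs = 2000L,
                           dtiSettings = dtiConfig(hidden = c(128L, 64L, 32L, 16L)),
                           screenSettings = screenConfig()) {
  list(nProteins = nProteins, nTfs = nTfs, nGenes = nGenes, nLnc = nLnc,
       nMirna = nMirna, edgesPerTarget = edgesPerTarget,
       nSamples = nSamples, noiseSd = noiseSd,
       decoyFraction = decoyFraction, exhaustiveLimit = exhaustiveLimit,
       energyThreshold = energyThreshold, coreSize = coreSize,
       projectionMode = projectionMode, geneSets = geneSets, dti = dti,
       dtiPairs = dtiPairs, dtiSettings = dtiSettings,
       screenSettings = screenSettings)
}

# union of two candidate networks over the same node table
.unionCandidate <- function(a, b) {
  ppi <- unique(rbind(a@ppi, b@ppi))
  reg <- unique(rbind(a@reg[, c("regulator", "target")],
                      b@reg[, c("regulator", "target")]))
  candidateNetwork(a@nodes, ppi = ppi, reg = reg)
}

#' Run the full pipeline on synthetic two-condition data
#'
#' Simulate -> identify -> prune -> principal network projection ->
#' (optional) enrichment -> (optional) DTI training -> drug screen. Two
#' condition-specific ground truths ("case", "control") share one decoy-
#' corrupted candidate network; each condition's expression prunes it to a
#' condition-specific identified network and core. The packaged candidate-
#' drug table feeds the screen. Every artifact is written as rounded TSV/CSV
#' plus a JSON manifest of stage seeds and counts, so reruns with the same
#' config and seed are byte-identical.
#'
#' @param config from \code{pipelineConfig()}.
#' @param outdir output directory (created; files overwritten).
#' @param seed global seed; per-stage seeds derive from it via
#'   \code{stageSeed}.
#' @return invisibly, a list with the in-memory artifacts and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir, seed = 1L) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  conditions <- c("case", "control")
  truths <- list(); exprs <- list(); cands <- list()
  for (cond in conditions) {
    truths[[cond]] <- generateTruth(
      config$nProteins, config$nTfs, config$nGenes, config$nLnc,
      config$nMirna, config$edgesPerTarget,
      seed = stageSeed(seed, paste0("truth_", cond)))
    cands[[cond]] <- corruptCandidate(
      truths[[cond]], config$decoyFraction,
      seed = stageSeed(seed, paste0("decoy_", cond)))
    exprs[[cond]] <- simulateExpression(
      truths[[cond]], config$nSamples, config$noiseSd,
      seed = stageSeed(seed, paste0("expr_", cond)), condition = cond)
  }
  candidate <- .unionCandidate(cands$case, cands$control)
  saveNetwork(candidate, file.path(outdir, "candidate"))
  manifest <- list(
    seed = as.integer(seed),
    stage_seeds = stats::setNames(
      lapply(c(paste0("truth_", conditions), paste0("decoy_", conditions),
               paste0("expr_", conditions)),
             function(s) stageSeed(seed, s)),
      c(paste0("truth_", conditions), paste0("decoy_", conditions),
        paste0("expr_", conditions))),
    candidate_edges = list(ppi = nrow(candidate@ppi),
                           regulation = nrow(candidate@reg)),
    conditions = list(), files = character(0))
  identified <- list(); cores <- list()
  for (cond in conditions) {
    dirC <- file.path(outdir, cond)
    writeExpression(exprs[[cond]], file.path(outdir, paste0("expr_", cond, ".csv")),
                    file.path(outdir, paste0("samples_", cond, ".csv")))
    idn <- pruneNetwork(candidate, exprs[[cond]],
                        exhaustiveLimit = config$exhaustiveLimit,
                        keepTraces = FALSE)
    writeIdentifiedNetwork(idn, dirC)
    core <- suppressWarnings(
      pnpCore(idn, M = config$coreSize, threshold = config$energyThreshold,
              mode = config$projectionMode))
    .writeTsv(coreScores(core), file.path(dirC, "core_scores.tsv"))
    exportCore(core, sifPath = file.path(dirC, "core.sif"),
               graphmlPath = file.path(dirC, "core.graphml"))
    identified[[cond]] <- idn; cores[[cond]] <- core
    manifest$conditions[[cond]] <- list(
      identified_edges = as.list(edgeCounts(idn)),
      energy_rank = core@K,
      energy_fraction = round(core@energyFraction, 10),
      core_nodes = sum(coreScores(core)$selected))
    if (!is.null(config$geneSets)) {
      sel <- coreScores(core)
      enr <- enrichCore(sel$node_id[sel$selected], config$geneSets,
                        universe = sel$node_id)
      .writeTsv(enr, file.path(dirC, "enrichment.tsv"))
    }
  }
  dtiModel <- NULL
  if (isTRUE(config$dti)) {
    ds <- generateDTI(config$dtiPairs, seed = stageSeed(seed, "dti_data"))
    bal <- balanceDownsample(ds, seed = stageSeed(seed, "dti_balance"))
    dtiModel <- trainDTI(bal, config$dtiSettings,
                         seed = stageSeed(seed, "dti_train"))
    .writeTsv(cvReport(dtiModel), file.path(outdir, "dti_cv.tsv"))
    .writeTsv(do.call(rbind, lapply(seq_along(dtiModel@history), function(f)
      cbind(fold = f, dtiModel@history[[f]]))),
      file.path(outdir, "dti_learning_curves.tsv"))
    ev <- evaluateDTI(dtiModel, bal)
    manifest$dti <- list(test_accuracy = round(ev$accuracy, 10),
                         test_auc = round(ev$auc, 10))
  }
  screenOut <- screenDrugs(candidateDrugTable(), biomarkerDirections(),
                           config$screenSettings)
  utils::write.csv(.roundNumeric(screenOut), file.path(outdir, "screen.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$screen_selected <- screenOut$drug[screenOut$selected]
  manifest$files <- sort(list.files(outdir, recursive = TRUE))
  manifest$files <- setdiff(manifest$files, "manifest.json")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(truths = truths, candidate = candidate,
                 identified = identified, cores = cores,
                 dti = dtiModel, screen = screenOut, manifest = manifest))
}
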