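#' Drug design-specification screen
#'
#' Thresholds implementing the three qualitative design specifications:
#' the drug must counter-regulate at least \code{minBiomarkers} dysregulated
#' biomarkers, have an LC50 of at least \code{lc50Min} (higher LC50 = lower
#' toxicity) and a cell-viability sensitivity within
#' \code{sensitivityAbsMax} of zero (the compound should not kill the
#' assayed cells).
#'
#' @param minBiomarkers minimum biomarkers counter-regulated (default 2).
#' @param lc50Min minimum LC50 in mol/kg (default 5.7).
#' @param sensitivityAbsMax maximum absolute sensitivity (default 0.15).
#' @return a config list.
#' @export
screenConfig <- function(minBiomarkers = 2L, lc50Min = 5.7,
                         sensitivityAbsMax = 0.15) {
  stopifnot(minBiomarkers >= 1, is.finite(lc50Min), is.finite(sensitivityAbsMax))
  list(minBiomarkers = as.integer(minBiomarkers), lc50Min = lc50Min,
       sensitivityAbsMax = sensitivityAbsMax)
}

#' Does a drug's regulation ability counter the biomarker's dysregulation?
#'
#' An upregulated biomarker needs a negatively correlated (downregulating)
#' compound; a downregulated biomarker needs a positively correlated one.
#' Zero ability counters nothing.
#'
#' @param ability signed regulation ability (perturbation-profiling effect).
#' @param direction biomarker dysregulation, \code{"up"} or \code{"down"}.
#' @return logical (vectorised).
#' @export
regulationOk <- function(ability, direction) {
  stopifnot(all(direction %in% c("up", "down")))
  (direction == "up" & ability < 0) | (direction == "down" & ability > 0)
}

#' Screen candidate drugs into a multi-molecule combination
#'
#' A drug is selected iff (i) it counter-regulates at least
#' \code{minBiomarkers} distinct biomarkers, (ii) its LC50 is at least
#' \code{lc50Min}, and (iii) its absolute sensitivity is at most
#' \code{sensitivityAbsMax}. LC50 and sensitivity are drug-level properties;
#' when a drug appears in several rows the most favourable value (largest
#' LC50, smallest |sensitivity|) is used. The screen is deterministic and
#' independent of input row order.
#'
#' @param table data.frame with columns \code{drug}, \code{biomarker},
#'   \code{regulation_ability}, \code{sensitivity}, \code{lc50}.
#' @param specs data.frame with columns \code{biomarker}, \code{direction}
#'   (\code{"up"}/\code{"down"}), one row per screened biomarker.
#' @param config from \code{screenConfig()}.
#' @return data.frame with one row per drug: \code{drug},
#'   \code{n_biomarkers} (counter-regulated count), \code{biomarkers}
#'   (semicolon-joined), \code{lc50}, \code{sensitivity}, \code{selected};
#'   sorted selected-first then alphabetically. The biomarker-coverage
#'   indicator matrix is attached as \code{attr(, "coverage")}.
#' @export
screenDrugs <- function(table, specs, config = screenConfig()) {
  need <- c("drug", "biomarker", "regulation_ability", "sensitivity", "lc50")
  if (!all(need %in% names(table)))
    stop("drug table must have columns: ", paste(need, collapse = ", "))
  if (any(table$lc50 <= 0)) stop("lc50 must be positive")
  if (anyDuplicated(paste(table$drug, table$biomarker)))
    stop("one row per (drug, biomarker) pair expected")
  dir <- stats::setNames(as.character(specs$direction),
                         as.character(specs$biomarker))
  if (any(!table$biomarker %in% names(dir)))
    stop("no dysregulation direction for biomarker(s): ",
         paste(setdiff(unique(table$biomarker), names(dir)), collapse = ", "))
  if (!nrow(table)) {
    out <- data.frame(drug = character(0), n_biomarkers = integer(0),
                      biomarkers = character(0), lc50 = numeric(0),
                      sensitivity = numeric(0), selected = logical(0))
    attr(out, "coverage") <- matrix(FALSE, 0, 0)
    return(out)
  }
  ok <- regulationOk(table$regulation_ability, dir[table$biomarker])
  drugs <- sort(unique(table$drug))
  biomarkers <- sort(unique(table$biomarker))
  coverage <- matrix(FALSE, length(drugs), length(biomarkers),
                     dimnames = list(drugs, biomarkers))
  coverage[cbind(match(table$drug[ok], drugs),
                 match(table$biomarker[ok], biomarkers))] <- TRUE
  lc50 <- tapply(table$lc50, table$drug, max)[drugs]
  sens <- tapply(abs(table$sensitivity), table$drug, min)[drugs]
  sensSigned <- vapply(drugs, function(d) {
    v <- table$sensitivity[table$drug == d]
    v[which.min(abs(v))]
  }, numeric(1))
  nCov <- rowSums(coverage)
  selected <- nCov >= config$minBiomarkers &
    lc50 >= config$lc50Min & sens <= config$sensitivityAbsMax
  out <- data.frame(
    drug = drugs,
    n_biomarkers = as.integer(nCov),
    biomarkers = vapply(drugs, function(d)
      paste(biomarkers[coverage[d, ]], collapse = ";"), character(1)),
    lc50 = as.numeric(lc50),
    sensitivity = as.numeric(sensSigned),
    selected = unname(selected),
    stringsAsFactors = FALSE)
  out <- out[order(!out$selected, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coverage") <- coverage
  out
}

#' Packaged candidate-drug pharmacology table and biomarker directions
#'
#' The package ships a pharmacology table for five psoriasis biomarkers
#' (STAT3, CEBPB, ERK1/2 and NF-kB overexpressed; FOXO1 underexpressed):
#' per (drug, biomarker) pair a signed regulation ability from perturbation
#' profiling, a cell-viability sensitivity and an LC50 toxicity value.
#' \code{candidateDrugTable()} loads the table,
#' \code{biomarkerDirections()} the dysregulation directions.
#'
#' @return a data.frame.
#' @export
candidateDrugTable <- function() {
  utils::read.csv(system.file("extdata", "candidate_drugs.csv",
                              package = "gwgenKit"),
                  stringsAsFactors = FALSE)
}

#' @rdname candidateDrugTable
#' @export
biomarkerDirections <- function() {
  utils::read.csv(system.file("extdata", "biomarker_directions.csv",
                              package = "gwgenKit"),
                  stringsAsFactors = FALSE)
}
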