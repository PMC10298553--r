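#' @importFrom stats rnorm runif rbinom cor sd qnorm phyper p.adjust
#' @importFrom utils read.delim read.csv write.csv combn head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded at \code{seed}, restoring the
#' caller's RNG state afterwards so library calls never perturb user sessions.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @export
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Deterministic per-stage seed fan-out
#'
#' Derives a stage-specific seed from one global seed and the stage name, so
#' each pipeline stage is independently reproducible. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629 + 1)
}

# round floating columns to 10 decimals for byte-stable TSV diffs
.roundNumeric <- function(df, digits = 10L) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  df
}

.writeTsv <- function(df, path) {
  df <- .roundNumeric(as.data.frame(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.clipProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)
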