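# Constrained linear least squares: min 0.5*||X theta - y||^2 subject to
# theta_j <= 0 on the columns flagged by cmask (miRNA-product columns).
# Primal active-set method: clamp the worst sign violator, release a clamped
# coefficient whose gradient shows the constraint is not binding at the
# optimum (KKT multiplier mu_j = -g_j must be >= 0).
.clsFit <- function(X, y, cmask, tol = 1e-10) {
  p <- ncol(X)
  rankDef <- FALSE
  lsmin <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    sv <- svd(Xs)
    keep <- sv$d > max(dim(Xs)) * .Machine$double.eps * max(sv$d[1], 1e-300)
    if (sum(keep) < length(sv$d)) rankDef <<- TRUE
    drop(sv$v[, keep, drop = FALSE] %*%
           (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep]))
  }
  active <- rep(FALSE, p)
  theta <- numeric(p)
  for (iter in seq_len(20L * p + 50L)) {
    theta <- numeric(p)
    freei <- which(!active)
    if (length(freei)) theta[freei] <- lsmin(freei)
    viol <- which(cmask & !active & theta > tol)
    if (length(viol)) {
      active[viol[which.max(theta[viol])]] <- TRUE
      next
    }
    g <- drop(crossprod(X, X %*% theta - y))
    gtol <- tol * max(1, max(abs(g)), sum(abs(y)))
    rel <- which(active & g > gtol)
    if (length(rel)) {
      active[rel[which.max(g[rel])]] <- FALSE
      next
    }
    theta[cmask & theta > 0] <- 0
    return(list(theta = theta, rankDeficient = rankDef))
  }
  warning("constrained least squares reached iteration cap; returning last iterate")
  theta[cmask & theta > 0] <- 0
  list(theta = theta, rankDeficient = rankDef)
}

#' Fit the constrained least-squares parameter estimate for one target
#'
#' Solves min 0.5 * ||Phi theta - y||^2 subject to every miRNA-product
#' coefficient being <= 0 (post-transcriptional repression can only lower
#' expression); PPI, TF, lncRNA and intercept coefficients are free-signed.
#' The residual variance is rho^2 = RSS / N (divisor N, matching the AIC
#' definition used for order selection). Rank-deficient designs fall back to
#' the minimum-norm solution with a warning.
#'
#' @param problem a \code{RegressionProblem}.
#' @return a \code{ParameterEstimate}.
#' @export
fitConstrainedLSQ <- function(problem) {
  stopifnot(is(problem, "RegressionProblem"))
  N <- length(problem@y)
  if (N < 2) stop("need at least 2 samples")
  fit <- .clsFit(problem@X, problem@y, problem@constraintMask)
  if (fit$rankDeficient)
    warning("rank-deficient design for target ", problem@targetId,
            "; minimum-norm solution used")
  theta <- stats::setNames(fit$theta, colnames(problem@X))
  res <- problem@y - drop(problem@X %*% fit$theta)
  new("ParameterEstimate", targetId = problem@targetId,
      coefficients = theta, constraintMask = problem@constraintMask,
      residuals = res, rho2 = sum(res^2) / N,
      rankDeficient = fit$rankDeficient)
}

#' Basal level of a fitted target
#'
#' @param estimate a \code{ParameterEstimate}.
#' @return the intercept coefficient.
#' @export
basalLevel <- function(estimate) {
  unname(estimate@coefficients["(basal)"])
}

#' Residual variance of a fitted target
#'
#' @param estimate a \code{ParameterEstimate}.
#' @return RSS / N.
#' @export
residualVariance <- function(estimate) estimate@rho2
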