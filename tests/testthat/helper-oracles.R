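# Independent oracles used to cross-check the implementation. These share no
# code with the package internals.

# minimum-norm least squares via SVD
.olsMin <- function(X, y) {
  sv <- svd(X)
  keep <- sv$d > 1e-10 * max(sv$d[1], 1e-300)
  drop(sv$v[, keep, drop = FALSE] %*%
         (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep]))
}

# constrained LS oracle: enumerate all 2^J active-set patterns over the
# constrained (<= 0) columns, solve the equality-constrained LS for each,
# keep the feasible pattern with the smallest objective.
oracleCLS <- function(X, y, cmask) {
  cidx <- which(cmask)
  p <- ncol(X)
  patterns <- if (length(cidx)) {
    unlist(lapply(0:length(cidx), function(k)
      if (k == 0) list(integer(0)) else
        asplit(utils::combn(cidx, k), 2)), recursive = FALSE)
  } else list(integer(0))
  best <- NULL
  for (S in patterns) {
    free <- setdiff(seq_len(p), S)
    th <- numeric(p)
    if (length(free)) th[free] <- .olsMin(X[, free, drop = FALSE], y)
    if (all(th[cidx] <= 1e-9)) {
      obj <- sum((X %*% th - y)^2)
      if (is.null(best) || obj < best$obj - 1e-12) best <- list(theta = th, obj = obj)
    }
  }
  best$theta
}

# exhaustive AIC oracle: enumerate every regulator subset, fit with the
# enumeration oracle, return the subset with minimal AIC (ties -> smaller
# subset, then enumeration order).
oracleAIC <- function(X, y, cmask) {
  k <- ncol(X) - 1L
  N <- length(y)
  best <- NULL
  for (size in 0:k) {
    subs <- if (size == 0) list(integer(0)) else asplit(utils::combn(k, size), 2)
    for (s in subs) {
      cols <- c(as.integer(s), k + 1L)
      th <- oracleCLS(X[, cols, drop = FALSE], y, cmask[cols])
      rho2 <- sum((X[, cols, drop = FALSE] %*% th - y)^2) / N
      aic <- log(max(rho2, 1e-12)) + 2 * (size + 1) / N
      if (is.null(best) || aic < best$aic - 1e-12)
        best <- list(subset = as.integer(s), aic = aic)
    }
  }
  best
}

# small hand-assembled identified network used by PNP tests
tinyIdentified <- function() {
  nodes <- data.frame(
    node_id = c("P1", "P2", "T1", "G1"),
    node_class = c("protein", "protein", "TF", "gene"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    target = c("P1", "P2", "G1"),
    regulator = c("P2", "P1", "T1"),
    edge_type = c("ppi", "ppi", "TF"),
    ability = c(0.5, 0.5, 1.2),
    stringsAsFactors = FALSE)
  targets <- data.frame(
    target_id = nodes$node_id, target_class = nodes$node_class,
    basal_level = 0, residual_variance = 0.1, aic = 0,
    n_candidates = 1L, n_selected = 1L, stringsAsFactors = FALSE)
  new("IdentifiedNetwork", nodes = nodes, edges = edges,
      targets = targets, traces = list())
}
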