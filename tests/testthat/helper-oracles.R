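# Independent oracles used across the suite.

# Brute-force solver for min ||X b - y||^2 s.t. b[neg] <= 0:
# enumerate every subset of the constrained slots clamped to zero, solve the
# remaining unconstrained problem by normal equations, keep the feasible
# solution with the smallest objective.
qpOracle <- function(X, y, neg) {
  cIdx <- which(neg)
  best <- NULL
  bestObj <- Inf
  for (mask in 0:(2^length(cIdx) - 1L)) {
    clamped <- cIdx[bitwAnd(mask, 2^(seq_along(cIdx) - 1L)) > 0]
    free <- setdiff(seq_len(ncol(X)), clamped)
    b <- numeric(ncol(X))
    Xf <- X[, free, drop = FALSE]
    bf <- tryCatch(solve(crossprod(Xf), crossprod(Xf, y)),
                   error = function(e) NULL)
    if (is.null(bf)) next
    b[free] <- as.numeric(bf)
    if (any(b[neg] > 1e-9)) next
    obj <- sum((X %*% b - y)^2)
    if (obj < bestObj) { bestObj <- obj; best <- b }
  }
  list(coef = best, obj = bestObj)
}

# KKT check for the same problem (convex, so sufficient): gradient zero on
# free/inactive coordinates, non-positive on active constrained ones.
kktHolds <- function(X, y, neg, b, tol = 1e-6) {
  g <- as.numeric(crossprod(X, X %*% b - y))
  scale <- max(1, max(abs(crossprod(X, y))))
  ok <- TRUE
  for (j in seq_along(b)) {
    if (!neg[j] || b[j] < -1e-10) ok <- ok && abs(g[j]) / scale < tol
    else ok <- ok && g[j] / scale < tol
  }
  ok
}

# Exhaustive AIC minimum over all regulator subsets of a problem.
exhaustiveAicMin <- function(problem, base = 10) {
  K <- ncol(problem@regressors) - 1L
  n <- length(problem@response)
  best <- Inf
  for (mask in 0:(2^K - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(K) - 1L)) > 0)
    fit <- solveLeastSquares(problem, columns = sel)
    aic <- computeAIC(fit$rss, n, length(sel) + 1L, base = base)
    if (aic < best) best <- aic
  }
  best
}

edgeKeys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  ifelse(edges$edge_type == "ppi",
         paste(pmin(edges$source_id, edges$target_id),
               pmax(edges$source_id, edges$target_id), "ppi", sep = "|"),
         paste(edges$source_id, edges$target_id, edges$edge_type, sep = "|"))
}

# Brute-force minimum set cover size (targets covered by drug -> targets map).
minCoverSize <- function(coverMap, targets) {
  drugs <- names(coverMap)
  for (k in seq_along(drugs)) {
    combos <- utils::combn(drugs, k, simplify = FALSE)
    for (cmb in combos) {
      if (all(targets %in% unlist(coverMap[cmb]))) return(k)
    }
  }
  Inf
}
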