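## Identification module: per-node (constrained) least squares on the
## candidate network followed by AIC model-order selection.
##
## Each protein's interaction model is fitted in regression form with
## constructed bilinear regressors p_i * p_j; each gene/lncRNA/miRNA target
## is fitted on its TF and lncRNA regulator series plus bilinear
## miRNA-repression terms m_v * g_x whose coefficients are constrained
## non-positive.  The AIC over a ranked nested model family prunes false
## positives from the candidate network.

.kindOfEdgeType <- function(edgeType) {
  ifelse(edgeType == "ppi", "protein-like",
         unname(.edgeTypeSourceKind[edgeType]))
}

.orderByKind <- function(edgeTypes, nodes, regulators) {
  kind <- stats::setNames(nodes$kind, nodes$node_id)
  k <- kind[regulators]
  tab <- table(factor(k, levels = .regulatorKinds))
  stats::setNames(as.integer(tab), names(tab))
}

#' Build a protein's PPI regression problem
#'
#' The i-th protein's interaction model regresses `p_i[n]` on the
#' constructed bilinear regressors `p_i[n] * p_j[n]` over its candidate
#' partners j plus a basal ones column; no sign constraints.
#'
#' @param i protein node id.
#' @param net a [CandidateGWGEN][CandidateGWGEN-class] (degree cap already
#'   applied if needed).
#' @param data an [ExpressionDataset][ExpressionDataset-class].
#' @return A [RegressionProblem][RegressionProblem-class].
#' @export
buildProteinRegression <- function(i, net, data) {
  m <- exprValues(data)
  nd <- networkNodes(net)
  kind <- nd$kind[match(i, nd$node_id)]
  if (is.na(kind) || kind != "protein")
    stop(sprintf("'%s' is not a protein-kind node", i))
  cand <- candidateRegulators(net, i)
  miss <- setdiff(cand$regulator_id, rownames(m))
  if (length(miss))
    stop(sprintf("partner(s) missing from data: %s",
                 paste(miss, collapse = ", ")))
  y <- m[i, ]
  k <- nrow(cand)
  X <- matrix(1, length(y), k + 1L)
  if (k)
    X[, seq_len(k)] <- t(m[cand$regulator_id, , drop = FALSE] *
                           rep(y, each = k))
  labels <- c(cand$regulator_id, "basal")
  colnames(X) <- labels
  kindLookup <- stats::setNames(nd$kind, nd$node_id)
  methods::new("RegressionProblem", targetId = i, response = unname(y),
               regressors = X, labels = labels,
               constrained = rep(FALSE, k + 1L),
               regulatorKinds = stats::setNames(
                 unname(kindLookup[cand$regulator_id]), cand$regulator_id),
               edgeTypes = stats::setNames(cand$edge_type,
                                           cand$regulator_id))
}

#' Build a gene/lncRNA/miRNA target's regression problem
#'
#' Regressor blocks follow the model layout: TF series, lncRNA series, then
#' bilinear miRNA terms `response * m_v`, then the basal ones column.  The
#' miRNA block carries the non-positivity constraint (repression).
#'
#' @param x target node id (kind gene, lncRNA or miRNA).
#' @inheritParams buildProteinRegression
#' @return A [RegressionProblem][RegressionProblem-class].
#' @export
buildTargetRegression <- function(x, net, data) {
  m <- exprValues(data)
  nd <- networkNodes(net)
  kind <- nd$kind[match(x, nd$node_id)]
  if (is.na(kind) || !kind %in% c("gene", "lncRNA", "miRNA"))
    stop(sprintf("'%s' is not a gene/lncRNA/miRNA-kind node", x))
  cand <- candidateRegulators(net, x)
  miss <- setdiff(cand$regulator_id, rownames(m))
  if (length(miss))
    stop(sprintf("regulator(s) missing from data: %s",
                 paste(miss, collapse = ", ")))
  kindLookup <- stats::setNames(nd$kind, nd$node_id)
  rkind <- kindLookup[cand$regulator_id]
  ## block order: TFs, lncRNAs, miRNAs (within block: id order from
  ## candidateRegulators)
  ord <- order(match(rkind, c("TF", "lncRNA", "miRNA")))
  cand <- cand[ord, , drop = FALSE]
  rkind <- rkind[ord]
  y <- m[x, ]
  k <- nrow(cand)
  X <- matrix(1, length(y), k + 1L)
  mirna <- rkind == "miRNA"
  if (k) {
    reg <- t(m[cand$regulator_id, , drop = FALSE])
    reg[, mirna] <- reg[, mirna, drop = FALSE] * y
    X[, seq_len(k)] <- reg
  }
  labels <- c(cand$regulator_id, "basal")
  colnames(X) <- labels
  methods::new("RegressionProblem", targetId = x, response = unname(y),
               regressors = X, labels = labels,
               constrained = c(unname(mirna), FALSE),
               regulatorKinds = stats::setNames(unname(rkind),
                                                cand$regulator_id),
               edgeTypes = stats::setNames(cand$edge_type,
                                           cand$regulator_id))
}

## minimum-norm least squares on a column subset; flags rank deficiency
.lsqSolve <- function(A, y) {
  qrA <- qr(A)
  if (qrA$rank == ncol(A)) {
    b <- qr.coef(qrA, y)
  } else {
    sv <- svd(A)
    pos <- sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-10
    b <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], y) / sv$d[pos])
    b <- as.numeric(b)
    attr(b, "rankDeficient") <- TRUE
  }
  b
}

## active-set (Lawson-Hanson with free variables) solver for
##   min ||A b - y||^2  s.t.  b[neg] <= 0
.solveConstrainedLS <- function(A, y, neg) {
  p <- ncol(A)
  s <- ifelse(neg, -1, 1)                 # b = s * z, constraints z[neg] >= 0
  Az <- sweep(A, 2L, s, `*`)
  z <- numeric(p)
  passive <- !neg
  rankFlag <- FALSE
  innerSolve <- function(idx) {
    zt <- numeric(p)
    b <- .lsqSolve(Az[, idx, drop = FALSE], y)
    if (isTRUE(attr(b, "rankDeficient"))) rankFlag <<- TRUE
    zt[idx] <- as.numeric(b)
    zt
  }
  stepBack <- function(z) {
    repeat {
      idx <- which(passive)
      if (!length(idx)) return(numeric(p))
      zt <- innerSolve(idx)
      bad <- idx[neg[idx] & zt[idx] < -1e-12]
      if (!length(bad)) return(zt)
      alpha <- min(z[bad] / (z[bad] - zt[bad]))
      alpha <- max(0, min(1, alpha))
      z <- z + alpha * (zt - z)
      dropIdx <- idx[neg[idx] & z[idx] <= 1e-11]
      if (!length(dropIdx)) dropIdx <- bad[1L]  # degenerate guard
      passive[dropIdx] <<- FALSE
      z[dropIdx] <- 0
    }
  }
  if (any(passive)) z <- stepBack(z)
  tol <- 1e-9 * max(1, sqrt(sum(y^2))) * max(1, sqrt(sum(Az^2)))
  maxOuter <- 10L * p + 10L
  for (iter in seq_len(maxOuter)) {
    w <- as.numeric(crossprod(Az, y - Az %*% z))
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    z <- stepBack(z)
    if (iter == maxOuter) {  # fall back to exhaustive active-set search
      return(.enumerateConstrainedLS(A, y, neg))
    }
  }
  b <- s * z
  attr(b, "rankDeficient") <- rankFlag
  b
}

## brute-force fallback/oracle: try every subset of constrained slots
## clamped to zero, keep the feasible solution with smallest objective
.enumerateConstrainedLS <- function(A, y, neg) {
  cIdx <- which(neg)
  best <- NULL
  bestObj <- Inf
  for (mask in 0:(2^length(cIdx) - 1L)) {
    clamped <- cIdx[bitwAnd(mask, 2^(seq_along(cIdx) - 1L)) > 0]
    idx <- setdiff(seq_len(ncol(A)), clamped)
    b <- numeric(ncol(A))
    if (length(idx))
      b[idx] <- as.numeric(.lsqSolve(A[, idx, drop = FALSE], y))
    if (any(b[neg] > 1e-9)) next
    obj <- sum((A %*% b - y)^2)
    if (obj < bestObj - 1e-12) { bestObj <- obj; best <- b }
  }
  best
}

#' Solve a node's (constrained) least-squares problem
#'
#' Unconstrained problems (PPI models) are solved by QR; problems with
#' miRNA-repression slots minimise the same objective subject to those
#' coefficients being non-positive, via an active-set method.
#' Rank-deficient designs fall back to the minimum-norm solution and are
#' flagged with a message.
#'
#' @param problem a [RegressionProblem][RegressionProblem-class].
#' @param columns optional index/logical vector selecting a subset of
#'   regulator columns (the basal column is always retained).
#' @return `list(coef = named numeric, rss = numeric)`.
#' @export
solveLeastSquares <- function(problem, columns = NULL) {
  stopifnot(methods::is(problem, "RegressionProblem"))
  X <- problem@regressors
  y <- problem@response
  keep <- seq_len(ncol(X))
  if (!is.null(columns)) {
    k <- ncol(X) - 1L
    sel <- if (is.logical(columns)) which(columns) else as.integer(columns)
    keep <- c(intersect(seq_len(k), sel), ncol(X))
  }
  Xs <- X[, keep, drop = FALSE]
  neg <- problem@constrained[keep]
  if (nrow(Xs) < ncol(Xs))
    stop(sprintf("node '%s': more parameters (%d) than samples (%d); apply the degree cap first",
                 problem@targetId, ncol(Xs), nrow(Xs)))
  if (any(neg)) {
    b <- .solveConstrainedLS(Xs, y, neg)
  } else {
    b <- .lsqSolve(Xs, y)
  }
  if (isTRUE(attr(b, "rankDeficient")))
    message(sprintf("node '%s': rank-deficient design, minimum-norm solution used",
                    problem@targetId))
  b <- as.numeric(b)
  rss <- sum((Xs %*% b - y)^2)
  list(coef = stats::setNames(b, problem@labels[keep]), rss = rss)
}

#' Akaike information criterion for a node model
#'
#' `AIC = log10(max(rss/n, floor)) + 2 * delta / n`, where `delta` is the
#' parameter count (selected regulators + basal) and the floor keeps
#' perfect fits comparable so the parsimony penalty decides among them.
#' The logarithm base is configurable; the common-log default gives the
#' order-selection behaviour the package's recovery guarantees are stated
#' for (see the methods vignette).
#'
#' @param rss residual sum of squares.
#' @param n sample count.
#' @param delta parameter count (>= 1).
#' @param base logarithm base (default 10).
#' @param floor lower bound applied to `rss/n` (default 1e-12).
#' @return numeric AIC value.
#' @examples
#' computeAIC(rss = 4, n = 4, delta = 2)  # log(1) + 2*2/4 = 1
#' @export
computeAIC <- function(rss, n, delta, base = 10, floor = 1e-12) {
  if (n <= 0) stop("'n' must be positive")
  if (delta < 1) stop("'delta' must be >= 1")
  log(max(rss / n, floor), base = base) + 2 * delta / n
}

#' Select a node's model order by AIC over a ranked nested family
#'
#' Fits the full candidate model, ranks regressors by the magnitude of
#' standardised influence (absolute coefficient times regressor standard
#' deviation, ties by lexicographic regulator id), then refits the nested
#' family k = 0..K and returns the order minimising the AIC (ties to the
#' smaller k).  Regulators outside the selected order are pruned.
#'
#' @inheritParams solveLeastSquares
#' @param nodes node table (used to report per-kind orders).
#' @param base,floor AIC settings, see [computeAIC()].
#' @return A [NodeModel][NodeModel-class].
#' @export
selectOrder <- function(problem, nodes = NULL, base = 10, floor = 1e-12) {
  stopifnot(methods::is(problem, "RegressionProblem"))
  n <- length(problem@response)
  K <- ncol(problem@regressors) - 1L
  if (K > 0L) {
    full <- solveLeastSquares(problem)
    sds <- apply(problem@regressors[, seq_len(K), drop = FALSE], 2L,
                 stats::sd)
    score <- abs(full$coef[seq_len(K)]) * sds
    ranked <- order(-score, problem@labels[seq_len(K)])
  } else {
    ranked <- integer(0)
  }
  best <- NULL
  bestAIC <- Inf
  bestK <- -1L
  for (k in 0:K) {
    sel <- ranked[seq_len(k)]
    fit <- solveLeastSquares(problem, columns = sel)
    aic <- computeAIC(fit$rss, n, k + 1L, base = base, floor = floor)
    if (aic < bestAIC - 1e-12) {
      bestAIC <- aic; bestK <- k; best <- list(fit = fit, sel = sel)
    }
  }
  sel <- best$sel
  regs <- problem@labels[sel]
  ord <- order(regs)
  regs <- regs[ord]; sel <- sel[ord]
  abilities <- best$fit$coef[match(regs, names(best$fit$coef))]
  edgeTypes <- problem@edgeTypes[regs]
  if (is.null(nodes))
    nodes <- data.frame(node_id = names(problem@regulatorKinds),
                        kind = unname(problem@regulatorKinds))
  methods::new("NodeModel", nodeId = problem@targetId, regulators = regs,
               abilities = stats::setNames(as.numeric(abilities), regs),
               edgeTypes = stats::setNames(unname(edgeTypes), regs),
               basal = unname(best$fit$coef[["basal"]]),
               rss = best$fit$rss, sigma2 = best$fit$rss / n,
               aic = bestAIC, order = as.integer(bestK),
               orderByKind = .orderByKind(edgeTypes, nodes, regs))
}

#' Identify the real GWGEN from a candidate network and expression data
#'
#' Fits every target node's model equation (protein-kind nodes via the PPI
#' model, gene/lncRNA/miRNA-kind nodes via the regulatory model) by
#' constrained least squares, prunes false-positive candidate edges by AIC
#' order selection, and assembles the identified network.  Identification
#' only prunes: the result's edges are a subset of the candidate edges.
#'
#' @param net a [CandidateGWGEN][CandidateGWGEN-class]; apply
#'   [applyDegreeCap()] first if any equation could exceed the sample
#'   count.
#' @param data an [ExpressionDataset][ExpressionDataset-class].
#' @param base,floor AIC settings, see [computeAIC()].
#' @return A [RealGWGEN][RealGWGEN-class].
#' @export
identifyGWGEN <- function(net, data, base = 10, floor = 1e-12) {
  stopifnot(methods::is(net, "CandidateGWGEN"))
  nd <- networkNodes(net)
  models <- list()
  edgeRows <- list()
  for (tg in .equationNodes(net)) {
    kind <- nd$kind[match(tg, nd$node_id)]
    problem <- tryCatch(
      if (kind == "protein") buildProteinRegression(tg, net, data)
      else buildTargetRegression(tg, net, data),
      error = function(e)
        stop(sprintf("node '%s': %s", tg, conditionMessage(e)), call. = FALSE))
    model <- selectOrder(problem, nodes = nd, base = base, floor = floor)
    models[[tg]] <- model
    if (model@order > 0L)
      edgeRows[[tg]] <- data.frame(
        source_id = model@regulators, target_id = tg,
        edge_type = unname(model@edgeTypes),
        ability = unname(model@abilities),
        basal = model@basal, aic = model@aic, order = model@order,
        stringsAsFactors = FALSE)
  }
  edges <- if (length(edgeRows)) do.call(rbind, edgeRows) else
    .emptyEdgeTable(c("ability", "basal", "aic", "order"))
  rownames(edges) <- NULL
  methods::new("RealGWGEN", nodes = nd[, c("node_id", "kind")],
               models = models, edges = edges)
}

#' Per-node models of a RealGWGEN
#'
#' @param x a [RealGWGEN][RealGWGEN-class].
#' @return named list of [NodeModel][NodeModel-class] objects.
#' @export
nodeModels <- function(x) {
  stopifnot(methods::is(x, "RealGWGEN"))
  x@models
}

setMethod("show", "RealGWGEN", function(object) {
  cat(sprintf("RealGWGEN: %d nodes, %d identified equations, %d selected edges\n",
              nrow(object@nodes), length(object@models),
              nrow(object@edges)))
})

setMethod("show", "NodeModel", function(object) {
  cat(sprintf("NodeModel '%s': order %d, basal %.4g, AIC %.4g\n",
              object@nodeId, object@order, object@basal, object@aic))
  if (object@order > 0L) {
    df <- data.frame(regulator = object@regulators,
                     ability = unname(object@abilities),
                     edge_type = unname(object@edgeTypes))
    print(df, row.names = FALSE)
  }
})

#' Edge and parameter recovery against a planted truth
#'
#' Compares an identified network's directed edge set (PPI edges as
#' partner-to-protein pairs, matched irrespective of orientation) to the
#' planted edges of a [GroundTruthModel][GroundTruthModel-class], and the
#' estimated abilities/basals to the generating values on the recovered
#' edges.
#'
#' @param real a [RealGWGEN][RealGWGEN-class].
#' @param truth a [GroundTruthModel][GroundTruthModel-class].
#' @return list with `precision`, `recall`, `f1`, `nTrue`, `nIdentified`,
#'   `maxAbilityError`, `maxBasalError`.
#' @export
evaluateRecovery <- function(real, truth) {
  idEdges <- networkEdges(real)
  trEdges <- trueEdges(truth)
  idKey <- .edgeKey(idEdges)
  trKey <- .edgeKey(trEdges)
  tp <- sum(idKey %in% trKey)
  precision <- if (length(idKey)) tp / length(idKey) else NA_real_
  recall <- if (length(trKey)) tp / length(trKey) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  common <- intersect(idKey, trKey)
  abilityErr <- if (length(common)) {
    est <- idEdges$ability[match(common, idKey)]
    tru <- trEdges$ability[match(common, trKey)]
    max(abs(est - tru))
  } else NA_real_
  tgts <- intersect(names(truth@basal), names(real@models))
  basalErr <- if (length(tgts)) {
    est <- vapply(real@models[tgts], function(mm) mm@basal, numeric(1L))
    max(abs(est - truth@basal[tgts]))
  } else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       nTrue = length(trKey), nIdentified = length(idKey),
       maxAbilityError = abilityErr, maxBasalError = basalErr)
}
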