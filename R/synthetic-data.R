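## Synthetic-data module: planted ground-truth GWGENs plus expression
## samples that satisfy the static network models exactly (up to the drawn
## noise term), so identification, projection and comparison can be
## validated by recovery of planted structure.
##
## Generation is two-layer: "source" nodes (TFs, receptors, a subset of
## miRNAs/lncRNAs) are drawn i.i.d. log-normal and act only as regressors;
## "target" nodes (proteins, genes, remaining miRNAs/lncRNAs) are computed
## from the rearranged closed forms of the model equations, so every target
## equation holds exactly without solving a coupled fixed point.

## distribution constants of the generator
.SRC_LOG_SD <- 0.5      # log-scale sd of source expression draws
.SRC_CAP <- 4.5         # truncation of source draws (upper ~0.1% tail)
.PPI_DENOM_MARGIN <- 0.85   # |sum lambda_j p_j| is kept <= this bound
.STABILITY_FLOOR <- 0.1 # minimum allowed |1 - sum lambda_j p_j|
.ABILITY_LO <- 0.2      # ability magnitudes drawn U(.ABILITY_LO, .ABILITY_HI)
.ABILITY_HI <- 1.0

## node table with source/target roles; n_proteins is split 40% TF /
## 20% receptor / 40% protein (PPI targets); miRNAs and lncRNAs are split
## ceiling(n/2) sources vs targets
.makeNodeTable <- function(nProteins, nGenes, nMirnas, nLncrnas) {
  nTF <- max(1L, round(0.4 * nProteins))
  nRec <- round(0.2 * nProteins)
  nProt <- nProteins - nTF - nRec
  if (nProt < 0L) { nRec <- max(0L, nProteins - nTF); nProt <- nProteins - nTF - nRec }
  ids <- function(prefix, n) if (n > 0L) sprintf("%s%03d", prefix, seq_len(n)) else character(0)
  nMiSrc <- ceiling(nMirnas / 2); nLnSrc <- ceiling(nLncrnas / 2)
  nodes <- rbind(
    data.frame(node_id = ids("P", nProt), kind = "protein", role = "target"),
    data.frame(node_id = ids("R", nRec), kind = "receptor", role = "source"),
    data.frame(node_id = ids("TF", nTF), kind = "TF", role = "source"),
    data.frame(node_id = ids("G", nGenes), kind = "gene", role = "target"),
    data.frame(node_id = ids("MIR", nMirnas), kind = "miRNA",
               role = rep(c("source", "target"), c(nMiSrc, nMirnas - nMiSrc))),
    data.frame(node_id = ids("LNC", nLncrnas), kind = "lncRNA",
               role = rep(c("source", "target"), c(nLnSrc, nLncrnas - nLnSrc))))
  rownames(nodes) <- NULL
  nodes
}

## every kind-legal (regulator -> target) pair, in a fixed deterministic
## order; true and decoy edges are both drawn from this frame
.allowedPairs <- function(nodes) {
  srcOf <- function(kinds, role = "source")
    nodes$node_id[nodes$kind %in% kinds & nodes$role %in% role]
  tgts <- nodes[nodes$role == "target", , drop = FALSE]
  ppiPartners <- srcOf(c("receptor", "TF"))
  grnRegs <- rbind(
    data.frame(regulator_id = srcOf("TF"), rkind = "TF"),
    data.frame(regulator_id = srcOf("lncRNA"), rkind = "lncRNA"),
    data.frame(regulator_id = srcOf("miRNA"), rkind = "miRNA"))
  out <- vector("list", nrow(tgts))
  for (i in seq_len(nrow(tgts))) {
    tg <- tgts[i, ]
    if (tg$kind == "protein") {
      if (!length(ppiPartners)) next
      out[[i]] <- data.frame(regulator_id = ppiPartners, target_id = tg$node_id,
                             edge_type = "ppi", stringsAsFactors = FALSE)
    } else {
      if (!nrow(grnRegs)) next
      out[[i]] <- data.frame(regulator_id = grnRegs$regulator_id,
                             target_id = tg$node_id,
                             edge_type = .edgeTypeFor(grnRegs$rkind, tg$kind),
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(regulator_id = character(0),
                                      target_id = character(0),
                                      edge_type = character(0))
  out <- out[order(out$target_id, out$regulator_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## signed abilities for a set of planted edges (RNG must be active):
## TF/lncRNA regulators get +/- U(lo, hi); miRNA regulators get -U(lo, hi)
## (the signed repression coefficient); PPI abilities get +/- U(lo, hi)
## rescaled per protein so the rearranged denominator stays off zero for
## every in-range source draw
.drawAbilities <- function(edges) {
  n <- nrow(edges)
  if (!n) return(numeric(0))
  mag <- stats::runif(n, .ABILITY_LO, .ABILITY_HI)
  sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
  ability <- mag * sgn
  mi <- grepl("^mirna_", edges$edge_type)
  ability[mi] <- -mag[mi]
  ppi <- edges$edge_type == "ppi"
  if (any(ppi)) {
    for (tg in unique(edges$target_id[ppi])) {
      idx <- which(ppi & edges$target_id == tg)
      scl <- min(1, .PPI_DENOM_MARGIN / (.SRC_CAP * sum(abs(ability[idx]))))
      ability[idx] <- ability[idx] * scl
    }
  }
  ability
}

## basal levels (RNG must be active); Eq.-2-type targets get an offset that
## keeps the numerator positive for all in-range source draws, so miRNA
## targets stay non-negative
.drawBasal <- function(nodes, coef) {
  tgts <- nodes[nodes$role == "target", , drop = FALSE]
  basal <- numeric(nrow(tgts))
  names(basal) <- tgts$node_id
  for (i in seq_len(nrow(tgts))) {
    id <- tgts$node_id[i]
    if (tgts$kind[i] == "protein") {
      basal[i] <- stats::runif(1, 1, 3)
    } else {
      rows <- coef$target_id == id & !grepl("^mirna_", coef$edge_type)
      basal[i] <- stats::runif(1, 0.5, 1.5) +
        .SRC_CAP * sum(abs(coef$ability[rows]))
    }
  }
  basal
}

.truthFromParts <- function(nodes, edges, ability, basal, noiseSd) {
  coef <- data.frame(target_id = edges$target_id,
                     regulator_id = edges$regulator_id,
                     edge_type = edges$edge_type,
                     ability = ability, stringsAsFactors = FALSE)
  coef <- coef[order(coef$target_id, coef$regulator_id), , drop = FALSE]
  rownames(coef) <- NULL
  methods::new("GroundTruthModel", nodes = nodes, coef = coef,
               basal = basal, noiseSd = noiseSd)
}

.candidateFromPairs <- function(nodes, pairs) {
  CandidateGWGEN(nodes[, c("node_id", "kind")],
                 data.frame(source_id = pairs$regulator_id,
                            target_id = pairs$target_id,
                            edge_type = pairs$edge_type,
                            stringsAsFactors = FALSE))
}

#' Generate a candidate GWGEN with a planted true sub-network
#'
#' Builds a multipartite candidate network (PPI + GRN Boolean hypothesis
#' space) containing a planted ground-truth network plus kind-respecting
#' decoy edges, together with the generating model
#' ([GroundTruthModel][GroundTruthModel-class]).  Every kind-legal
#' regulator/target pair becomes a true edge independently with probability
#' `trueDensity`; `round(decoyRatio * n_true)` decoys are then sampled from
#' the remaining legal pairs.  Deterministic given `seed`.
#'
#' @param nProteins,nGenes,nMirnas,nLncrnas node counts per molecular
#'   species.  Proteins are split into PPI-target proteins, receptors and
#'   TFs; miRNAs/lncRNAs into regulator (source) and regulated (target)
#'   subsets.
#' @param trueDensity per-pair probability of a planted edge, in (0, 1].
#' @param decoyRatio decoy edges per true edge, >= 0.
#' @param noiseSd default noise standard deviation recorded in the truth.
#' @param seed integer RNG seed.
#'
#' @return `list(candidate = CandidateGWGEN, truth = GroundTruthModel)`.
#' @examples
#' gw <- generateCandidateGWGEN(20, 30, 8, 4, trueDensity = 0.08,
#'                              decoyRatio = 2, seed = 1)
#' gw$candidate
#' gw$truth
#' @export
generateCandidateGWGEN <- function(nProteins, nGenes, nMirnas, nLncrnas,
                                   trueDensity = 0.05, decoyRatio = 2,
                                   noiseSd = 0, seed) {
  nProteins <- .assertCount(nProteins, "nProteins")
  nGenes <- .assertCount(nGenes, "nGenes", min = 0L)
  nMirnas <- .assertCount(nMirnas, "nMirnas", min = 0L)
  nLncrnas <- .assertCount(nLncrnas, "nLncrnas", min = 0L)
  trueDensity <- .assertFraction(trueDensity, "trueDensity", loOpen = TRUE)
  if (!is.numeric(decoyRatio) || decoyRatio < 0)
    stop("'decoyRatio' must be >= 0")
  .withSeed(seed, {
    nodes <- .makeNodeTable(nProteins, nGenes, nMirnas, nLncrnas)
    pairs <- .allowedPairs(nodes)
    isTrue <- stats::runif(nrow(pairs)) < trueDensity
    trueE <- pairs[isTrue, , drop = FALSE]
    nDecoy <- round(decoyRatio * nrow(trueE))
    pool <- which(!isTrue)
    if (nDecoy > length(pool))
      stop(sprintf(paste("parameter error: %d decoy edges requested but only",
                         "%d non-true kind-legal pairs exist"),
                   nDecoy, length(pool)))
    decoyE <- pairs[sort(sample(pool, nDecoy)), , drop = FALSE]
    ability <- .drawAbilities(trueE)
    basal <- .drawBasal(nodes, data.frame(target_id = trueE$target_id,
                                          edge_type = trueE$edge_type,
                                          ability = ability))
    truth <- .truthFromParts(nodes, trueE, ability, basal, noiseSd)
    candidate <- .candidateFromPairs(nodes, rbind(trueE, decoyE))
    list(candidate = candidate, truth = truth)
  })
}

## truncated log-normal source draws
.drawSources <- function(n) {
  x <- stats::rlnorm(n, 0, .SRC_LOG_SD)
  bad <- which(x > .SRC_CAP)
  while (length(bad)) {
    x[bad] <- stats::rlnorm(length(bad), 0, .SRC_LOG_SD)
    bad <- bad[x[bad] > .SRC_CAP]
  }
  x
}

#' Simulate expression samples from a ground-truth model
#'
#' Draws source-node expression i.i.d. log-normal (location 0, log-scale sd
#' 0.5, truncated at the upper ~0.1% tail) and computes every target node
#' from the rearranged closed form of its model equation, with Gaussian
#' noise added to the basal level inside the numerator — so the generating
#' equation holds exactly with the drawn noise term: a protein satisfies
#' `p = (psi + theta) / (1 - sum(lambda_j p_j))` and an Eq.-2-type target
#' `g = (sum(alpha t) + sum(beta l) + psi + theta) / (1 + sum(gamma m))`.
#' Noise draws that would push a miRNA target negative are resampled (they
#' are essentially impossible at realistic noise levels).
#'
#' @param truth a [GroundTruthModel][GroundTruthModel-class].
#' @param nSamples number of samples N.
#' @param seed integer RNG seed.
#' @param noiseSd noise standard deviation: `NULL` (use the truth's
#'   default), a scalar, or a named per-target vector.
#' @param condition optional condition label stored in the dataset.
#'
#' @return An [ExpressionDataset][ExpressionDataset-class] over all nodes.
#' @seealso [modelResiduals()] to verify model consistency, [signalSd()]
#'   for noise calibration relative to the noiseless signal.
#' @export
simulateExpression <- function(truth, nSamples, seed, noiseSd = NULL,
                               condition = NA_character_) {
  stopifnot(methods::is(truth, "GroundTruthModel"))
  nSamples <- .assertCount(nSamples, "nSamples")
  nodes <- truth@nodes
  tgtIds <- nodes$node_id[nodes$role == "target"]
  if (is.null(noiseSd)) noiseSd <- truth@noiseSd
  sdVec <- if (length(noiseSd) == 1L && is.null(names(noiseSd))) {
    stats::setNames(rep(as.numeric(noiseSd), length(tgtIds)), tgtIds)
  } else {
    miss <- setdiff(tgtIds, names(noiseSd))
    if (length(miss))
      stop(sprintf("noiseSd missing for target(s): %s",
                   paste(utils::head(miss, 5L), collapse = ", ")))
    noiseSd[tgtIds]
  }
  if (any(sdVec < 0)) stop("noise sd must be >= 0")
  .withSeed(seed, {
    srcIds <- nodes$node_id[nodes$role == "source"]
    m <- matrix(NA_real_, nrow(nodes), nSamples,
                dimnames = list(nodes$node_id,
                                paste0("S", seq_len(nSamples))))
    m[srcIds, ] <- matrix(.drawSources(length(srcIds) * nSamples),
                          length(srcIds), nSamples)
    cf <- truth@coef
    kind <- stats::setNames(nodes$kind, nodes$node_id)
    for (id in tgtIds) {
      rows <- cf[cf$target_id == id, , drop = FALSE]
      psi <- truth@basal[[id]]
      theta <- stats::rnorm(nSamples, 0, sdVec[[id]])
      if (kind[[id]] == "protein") {
        denom <- rep(1, nSamples)
        if (nrow(rows)) {
          reg <- m[rows$regulator_id, , drop = FALSE]
          denom <- 1 - as.numeric(crossprod(reg, rows$ability))
        }
        if (any(abs(denom) < .STABILITY_FLOOR))
          stop(sprintf(paste("stability floor violated for protein '%s':",
                             "|1 - sum(lambda_j p_j)| = %.3g"),
                       id, min(abs(denom))))
        m[id, ] <- (psi + theta) / denom
      } else {
        miR <- grepl("^mirna_", rows$edge_type)
        num <- rep(psi, nSamples)
        if (any(!miR)) {
          reg <- m[rows$regulator_id[!miR], , drop = FALSE]
          num <- num + as.numeric(crossprod(reg, rows$ability[!miR]))
        }
        denom <- rep(1, nSamples)
        if (any(miR)) {
          reg <- m[rows$regulator_id[miR], , drop = FALSE]
          denom <- 1 - as.numeric(crossprod(reg, rows$ability[miR]))
        }
        val <- (num + theta) / denom
        if (kind[[id]] == "miRNA" && any(val < 0)) {
          for (j in which(val < 0)) {
            tries <- 0L
            while (val[j] < 0) {
              tries <- tries + 1L
              if (tries > 100L)
                stop(sprintf(paste("could not draw a non-negative value for",
                                   "miRNA '%s' (sample %d); noise sd too",
                                   "large for its basal level"), id, j))
              theta[j] <- stats::rnorm(1, 0, sdVec[[id]])
              val[j] <- (num[j] + theta[j]) / denom[j]
            }
          }
        }
        m[id, ] <- val
      }
    }
    ExpressionDataset(m, stats::setNames(nodes$kind, nodes$node_id),
                      condition = condition)
  })
}

#' Residuals of the generating model on a dataset
#'
#' For every target node, evaluates the model equation at the truth's
#' parameters and returns the per-sample residual (which equals the drawn
#' noise term for data produced by [simulateExpression()]; exactly zero at
#' noise sd 0).
#'
#' @param truth a [GroundTruthModel][GroundTruthModel-class].
#' @param data an [ExpressionDataset][ExpressionDataset-class] covering the
#'   truth's nodes.
#' @return numeric matrix, target nodes x samples.
#' @export
modelResiduals <- function(truth, data) {
  stopifnot(methods::is(truth, "GroundTruthModel"))
  m <- exprValues(data)
  nodes <- truth@nodes
  tgtIds <- nodes$node_id[nodes$role == "target"]
  miss <- setdiff(nodes$node_id, rownames(m))
  if (length(miss))
    stop(sprintf("dataset is missing node(s): %s",
                 paste(utils::head(miss, 5L), collapse = ", ")))
  cf <- truth@coef
  kind <- stats::setNames(nodes$kind, nodes$node_id)
  out <- matrix(NA_real_, length(tgtIds), ncol(m),
                dimnames = list(tgtIds, colnames(m)))
  for (id in tgtIds) {
    rows <- cf[cf$target_id == id, , drop = FALSE]
    pred <- rep(truth@basal[[id]], ncol(m))
    if (nrow(rows)) {
      bilinear <- rows$edge_type == "ppi" | grepl("^mirna_", rows$edge_type)
      if (any(!bilinear))
        pred <- pred + as.numeric(
          crossprod(m[rows$regulator_id[!bilinear], , drop = FALSE],
                    rows$ability[!bilinear]))
      if (any(bilinear)) {
        reg <- m[rows$regulator_id[bilinear], , drop = FALSE] *
          rep(m[id, ], each = sum(bilinear))
        pred <- pred + as.numeric(crossprod(reg, rows$ability[bilinear]))
      }
    }
    out[id, ] <- m[id, ] - pred
  }
  out
}

#' Per-target noiseless signal standard deviation
#'
#' Simulates one noiseless dataset and returns the per-target-node standard
#' deviation of the response across samples; used to calibrate relative
#' noise levels (e.g. noise sd = 0.1 x signal sd).
#'
#' @inheritParams simulateExpression
#' @return named numeric vector over target nodes.
#' @export
signalSd <- function(truth, nSamples, seed) {
  data0 <- simulateExpression(truth, nSamples, seed, noiseSd = 0)
  m <- exprValues(data0)
  tgt <- truth@nodes$node_id[truth@nodes$role == "target"]
  apply(m[tgt, , drop = FALSE], 1L, stats::sd)
}

#' Generate a two-condition study sharing one candidate network
#'
#' Plants two ground-truth networks inside a single shared candidate GWGEN
#' (as in a case/control design where both conditions are identified
#' against the same database-derived hypothesis network).  A fraction
#' `sharedTruthFraction` of condition A's true edges is common to both
#' conditions; each condition receives the same number of true edges, the
#' remainder condition-distinctive.  Targets whose regulator set is
#' unchanged between conditions keep identical abilities and basal levels;
#' any target gaining or losing a regulator is redrawn for condition B.
#'
#' @inheritParams generateCandidateGWGEN
#' @param sharedTruthFraction fraction of per-condition true edges common
#'   to both conditions, in \[0, 1\].
#' @return `list(candidate, truthA, truthB)`.
#' @export
generateConditionPair <- function(nProteins, nGenes, nMirnas, nLncrnas,
                                  trueDensity = 0.05, decoyRatio = 2,
                                  sharedTruthFraction = 0.5, noiseSd = 0,
                                  seed) {
  sharedTruthFraction <- .assertFraction(sharedTruthFraction,
                                         "sharedTruthFraction")
  nProteins <- .assertCount(nProteins, "nProteins")
  trueDensity <- .assertFraction(trueDensity, "trueDensity", loOpen = TRUE)
  if (!is.numeric(decoyRatio) || decoyRatio < 0)
    stop("'decoyRatio' must be >= 0")
  .withSeed(seed, {
    nodes <- .makeNodeTable(nProteins, nGenes, nMirnas, nLncrnas)
    pairs <- .allowedPairs(nodes)
    key <- paste(pairs$regulator_id, pairs$target_id, pairs$edge_type)
    idxA <- which(stats::runif(nrow(pairs)) < trueDensity)
    nA <- length(idxA)
    nCommon <- round(sharedTruthFraction * nA)
    common <- sort(sample(idxA, nCommon))
    poolB <- setdiff(seq_len(nrow(pairs)), idxA)
    nNew <- nA - nCommon
    if (nNew > length(poolB))
      stop("parameter error: not enough legal pairs for the distinctive-B edges")
    newB <- sort(sample(poolB, nNew))
    idxB <- sort(c(common, newB))
    edgesA <- pairs[idxA, , drop = FALSE]
    edgesB <- pairs[idxB, , drop = FALSE]
    abilityA <- .drawAbilities(edgesA)
    basalA <- .drawBasal(nodes, data.frame(target_id = edgesA$target_id,
                                           edge_type = edgesA$edge_type,
                                           ability = abilityA))
    ## condition B: copy unchanged targets, redraw changed ones
    abilityB <- numeric(nrow(edgesB))
    basalB <- basalA
    keyA <- key[idxA]; keyB <- key[idxB]
    for (tg in unique(nodes$node_id[nodes$role == "target"])) {
      aRows <- which(edgesA$target_id == tg)
      bRows <- which(edgesB$target_id == tg)
      if (length(aRows) == length(bRows) &&
          setequal(keyA[aRows], keyB[bRows])) {
        abilityB[bRows] <- abilityA[aRows][match(keyB[bRows], keyA[aRows])]
      } else {
        sub <- edgesB[bRows, , drop = FALSE]
        abilityB[bRows] <- .drawAbilities(sub)
        nonMi <- !grepl("^mirna_", sub$edge_type)
        basalB[[tg]] <- if (nodes$kind[nodes$node_id == tg] == "protein")
          stats::runif(1, 1, 3)
        else
          stats::runif(1, 0.5, 1.5) +
            .SRC_CAP * sum(abs(abilityB[bRows][nonMi]))
      }
    }
    unionIdx <- sort(union(idxA, idxB))
    nDecoy <- round(decoyRatio * length(unionIdx))
    poolD <- setdiff(seq_len(nrow(pairs)), unionIdx)
    if (nDecoy > length(poolD))
      stop("parameter error: decoy ratio exceeds available kind-legal pairs")
    decoys <- sort(sample(poolD, nDecoy))
    candidate <- .candidateFromPairs(nodes,
                                     pairs[sort(c(unionIdx, decoys)), ,
                                           drop = FALSE])
    list(candidate = candidate,
         truthA = .truthFromParts(nodes, edgesA, abilityA, basalA, noiseSd),
         truthB = .truthFromParts(nodes, edgesB, abilityB, basalB, noiseSd))
  })
}

#' Synthetic drug catalog fixture
#'
#' Builds a small connectivity-score/LD50 catalog with a designed structure:
#' for every biomarker target there is at least one drug passing both
#' filters (correct score sign, high LD50), one failing the sign rule, and
#' one failing the toxicity filter; two broad-spectrum drugs (`alphacin`,
#' covering the first half of the targets, and `betanol`, covering the
#' rest) are scored so that the greedy set cover provably selects exactly
#' them.  The designed cover is recorded in the catalog metadata.
#'
#' @param targets character vector of biomarker node ids (non-empty).
#' @param seed integer RNG seed (jitters scores and LD50s within their
#'   designed ranges).
#' @param directions optional named or parallel character vector of
#'   signature directions (`up`/`down`) per target; default all `up`.
#'   Passing drugs reverse the signature (negative score for `up` targets,
#'   positive for `down`).
#'
#' @return A [DrugCatalog][DrugCatalog-class]; `metadata` holds
#'   `designed_cover` and `directions`.
#' @export
makeDrugCatalogFixture <- function(targets, seed, directions = NULL) {
  targets <- as.character(targets)
  if (!length(targets)) stop("'targets' must be non-empty")
  if (anyDuplicated(targets)) stop("'targets' must be unique")
  if (is.null(directions)) directions <- rep("up", length(targets))
  if (!is.null(names(directions))) directions <- directions[targets]
  if (length(directions) != length(targets) ||
      !all(directions %in% c("up", "down")))
    stop("'directions' must assign up/down to every target")
  .withSeed(seed, {
    n <- length(targets)
    sgn <- ifelse(directions == "up", -1, 1)   # sign a reversing drug needs
    tab <- list()
    for (i in seq_len(n)) {
      t <- targets[i]; low <- tolower(gsub("[^A-Za-z0-9]", "", t))
      tab[[length(tab) + 1L]] <- data.frame(
        drug = sprintf("agent_%s", low), target = t,
        connectivity_score = sgn[i] * stats::runif(1, 0.55, 0.84),
        ld50_mg_per_kg = stats::runif(1, 600, 1200))
      tab[[length(tab) + 1L]] <- data.frame(
        drug = sprintf("mimic_%s", low), target = t,
        connectivity_score = -sgn[i] * stats::runif(1, 0.55, 0.84),
        ld50_mg_per_kg = stats::runif(1, 600, 1200))
      tab[[length(tab) + 1L]] <- data.frame(
        drug = sprintf("toxin_%s", low), target = t,
        connectivity_score = sgn[i] * stats::runif(1, 0.70, 0.95),
        ld50_mg_per_kg = stats::runif(1, 20, 200))
    }
    firstHalf <- seq_len(ceiling(n / 2))
    for (i in firstHalf)
      tab[[length(tab) + 1L]] <- data.frame(
        drug = "alphacin", target = targets[i],
        connectivity_score = sgn[i] * 0.90,
        ld50_mg_per_kg = 900)
    rest <- setdiff(seq_len(n), firstHalf)
    for (i in rest)
      tab[[length(tab) + 1L]] <- data.frame(
        drug = "betanol", target = targets[i],
        connectivity_score = sgn[i] * 0.85,
        ld50_mg_per_kg = 800)
    table <- do.call(rbind, tab)
    rownames(table) <- NULL
    methods::new("DrugCatalog", table = table,
                 metadata = list(
                   designed_cover = c("alphacin",
                                      if (length(rest)) "betanol"),
                   directions = stats::setNames(directions, targets)))
  })
}
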