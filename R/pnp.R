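## Principal network projection: assemble the combined ability matrix W,
## decompose it by SVD, select the minimal rank covering the eigenexpression
## energy threshold, score every node by the 2-norm of its projection onto
## the principal singular vectors, and cut the top-K core network.

#' Assemble the combined network matrix W
#'
#' Rows are the target nodes of the identified network (kinds protein,
#' gene, lncRNA, miRNA), columns the regulator-capable nodes (protein,
#' receptor, TF, lncRNA, miRNA), both ordered kind-block-first then by node
#' id.  Entry (r, c) holds the estimated ability of the selected edge
#' c -> r (the PPI block occupies the protein-like columns) and zero
#' elsewhere, preserving the block layout of the combined-network picture.
#' Nodes of a kind with no row or column role are excluded with a message.
#'
#' @param real a [RealGWGEN][RealGWGEN-class] with at least one selected
#'   edge.
#' @return A [CombinedMatrix][CombinedMatrix-class].
#' @export
buildCombinedMatrix <- function(real) {
  stopifnot(methods::is(real, "RealGWGEN"))
  ed <- networkEdges(real)
  if (!nrow(ed))
    stop("cannot build a combined matrix from an empty identified network")
  nd <- networkNodes(real)
  rowSel <- nd$kind %in% .equationKinds
  colSel <- nd$kind %in% .regulatorKinds
  orphan <- nd$node_id[!rowSel & !colSel]
  if (length(orphan))
    message(sprintf("excluding %d node(s) with no role in any block",
                    length(orphan)))
  blockOrder <- function(sel, kindsOrder) {
    sub <- nd[sel, , drop = FALSE]
    sub <- sub[order(match(sub$kind, kindsOrder), sub$node_id), ,
               drop = FALSE]
    stats::setNames(sub$kind, sub$node_id)
  }
  rowKinds <- blockOrder(rowSel, .equationKinds)
  colKinds <- blockOrder(colSel, .regulatorKinds)
  W <- Matrix::sparseMatrix(
    i = match(ed$target_id, names(rowKinds)),
    j = match(ed$source_id, names(colKinds)),
    x = ed$ability,
    dims = c(length(rowKinds), length(colKinds)),
    dimnames = list(names(rowKinds), names(colKinds)))
  methods::new("CombinedMatrix", W = W, rowKinds = rowKinds,
               colKinds = colKinds)
}

setMethod("show", "CombinedMatrix", function(object) {
  cat(sprintf("CombinedMatrix W: %d targets x %d regulators, %d non-zero abilities\n",
              nrow(object@W), ncol(object@W),
              Matrix::nnzero(object@W)))
})

#' Singular value decomposition of the combined matrix
#'
#' Returns `W = T D H'` with singular values in descending order and a
#' deterministic sign convention (each right singular vector is flipped so
#' its largest-magnitude entry is positive; projection scores are
#' unaffected).
#'
#' @param cm a [CombinedMatrix][CombinedMatrix-class].
#' @return `list(Tmat, d, Hmat)` with
#'   `W = Tmat %*% diag(d) %*% t(Hmat)`.
#' @export
decomposeNetwork <- function(cm) {
  stopifnot(methods::is(cm, "CombinedMatrix"))
  W <- as.matrix(cm@W)
  if (any(!is.finite(W))) stop("combined matrix has non-finite entries")
  sv <- svd(W)
  for (s in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, s]))
    if (sv$v[j, s] < 0) {
      sv$v[, s] <- -sv$v[, s]
      sv$u[, s] <- -sv$u[, s]
    }
  }
  rownames(sv$u) <- rownames(W)
  rownames(sv$v) <- colnames(W)
  list(Tmat = sv$u, d = sv$d, Hmat = sv$v)
}

#' Eigenexpression fractions of a singular spectrum
#'
#' `E_s = d_s^2 / sum(d^2)`; the energy share of the s-th singular
#' component.
#'
#' @param d non-negative singular values.
#' @return numeric vector summing to 1.
#' @examples
#' eigenexpressionFractions(c(3, 1))  # 0.9 0.1
#' @export
eigenexpressionFractions <- function(d) {
  if (any(d < 0)) stop("singular values must be non-negative")
  tot <- sum(d^2)
  if (tot == 0) stop("all singular values are zero; fractions undefined")
  d^2 / tot
}

#' Minimal rank covering an energy threshold
#'
#' The smallest S with cumulative eigenexpression fraction at least
#' `threshold` (default 0.85, the principal-network-structure criterion).
#'
#' @param E eigenexpression fractions (see [eigenexpressionFractions()]).
#' @param threshold energy threshold in (0, 1].
#' @return integer S.
#' @examples
#' selectRank(c(0.9, 0.1))            # 1
#' selectRank(rep(0.25, 4))           # 4
#' @export
selectRank <- function(E, threshold = 0.85) {
  threshold <- .assertFraction(threshold, "threshold", loOpen = TRUE)
  as.integer(which(cumsum(E) >= threshold - 1e-12)[1L])
}

#' 2-norm projection scores onto the principal network structure
#'
#' Downstream (regulator-role) score of column c:
#' `Q(c) = sqrt(sum_{r<=S} (u_r' w_:,c)^2)`, the 2-norm of the column's
#' projection onto the top-S left singular vectors; the upstream
#' (target-role) score projects each row onto the top-S right singular
#' vectors.  A score near zero marks a node nearly independent of the
#' principal network structure.
#'
#' @param cm a [CombinedMatrix][CombinedMatrix-class].
#' @param decomposition result of [decomposeNetwork()].
#' @param S number of principal singular vectors to project on.
#' @param threshold recorded threshold (metadata only; use [selectRank()]
#'   to derive S from it).
#' @return A [ProjectionResult][ProjectionResult-class].
#' @export
projectionScores <- function(cm, decomposition, S,
                             threshold = NA_real_) {
  stopifnot(methods::is(cm, "CombinedMatrix"))
  d <- decomposition$d
  S <- .assertCount(S, "S")
  if (S > length(d)) stop("'S' exceeds the number of singular values")
  W <- as.matrix(cm@W)
  U <- decomposition$Tmat[, seq_len(S), drop = FALSE]
  V <- decomposition$Hmat[, seq_len(S), drop = FALSE]
  Pd <- crossprod(U, W)              # S x ncol: projections of columns
  Qdown <- sqrt(colSums(Pd^2))
  Pu <- W %*% V                      # nrow x S: projections of rows
  Qup <- sqrt(rowSums(Pu^2))
  methods::new("ProjectionResult", d = d,
               E = eigenexpressionFractions(d), S = S,
               threshold = threshold,
               Qdown = stats::setNames(Qdown, colnames(W)),
               Qup = stats::setNames(Qup, rownames(W)),
               Tmat = decomposition$Tmat, Hmat = decomposition$Hmat)
}

setMethod("show", "ProjectionResult", function(object) {
  cat(sprintf("ProjectionResult: rank %d of %d singular values (cumulative energy %.3f)\n",
              object@S, length(object@d),
              sum(object@E[seq_len(object@S)])))
})

#' Run the principal network projection
#'
#' Convenience wrapper: builds W, decomposes it, selects the minimal rank
#' with cumulative energy at least `threshold`, and computes both
#' projection scores.
#'
#' @param real a [RealGWGEN][RealGWGEN-class].
#' @param threshold energy threshold (default 0.85).
#' @return A [ProjectionResult][ProjectionResult-class].
#' @export
projectNetwork <- function(real, threshold = 0.85) {
  cm <- buildCombinedMatrix(real)
  dec <- decomposeNetwork(cm)
  S <- selectRank(eigenexpressionFractions(dec$d), threshold)
  projectionScores(cm, dec, S, threshold = threshold)
}

#' Extract the core GWGEN by projection ranking
#'
#' Scores every node by the larger of its upstream and downstream
#' projection scores (a node important in either role is core), ranks
#' descending with ties broken by node id, keeps the top
#' `min(topK, n)` nodes, and induces the core edge set (both endpoints in
#' the core).
#'
#' @param real a [RealGWGEN][RealGWGEN-class].
#' @param scores a [ProjectionResult][ProjectionResult-class] for `real`.
#' @param topK number of core nodes to keep (default 2000).
#' @return A [CoreGWGEN][CoreGWGEN-class].
#' @export
extractCore <- function(real, scores, topK = 2000) {
  stopifnot(methods::is(real, "RealGWGEN"),
            methods::is(scores, "ProjectionResult"))
  topK <- .assertCount(topK, "topK")
  nd <- networkNodes(real)
  down <- scores@Qdown[match(nd$node_id, names(scores@Qdown))]
  up <- scores@Qup[match(nd$node_id, names(scores@Qup))]
  down[is.na(down)] <- NA_real_
  score <- pmax(ifelse(is.na(down), -Inf, down),
                ifelse(is.na(up), -Inf, up))
  score[!is.finite(score)] <- 0
  tab <- data.frame(node_id = nd$node_id, kind = nd$kind,
                    score_down = unname(down), score_up = unname(up),
                    score = unname(score), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score, tab$node_id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  keep <- tab[seq_len(min(topK, nrow(tab))), , drop = FALSE]
  rownames(keep) <- NULL
  ed <- networkEdges(real)
  induced <- ed[ed$source_id %in% keep$node_id &
                  ed$target_id %in% keep$node_id, , drop = FALSE]
  rownames(induced) <- NULL
  methods::new("CoreGWGEN", nodes = keep, edges = induced,
               provenance = list(top_k = topK,
                                 threshold = scores@threshold,
                                 S = scores@S,
                                 n_network_nodes = nrow(nd)))
}

setMethod("show", "CoreGWGEN", function(object) {
  cat(sprintf("CoreGWGEN: %d of %d nodes (top_k = %d, S = %s), %d induced edges\n",
              nrow(object@nodes), object@provenance$n_network_nodes,
              object@provenance$top_k,
              as.character(object@provenance$S), nrow(object@edges)))
})

#' Write a core network node table
#'
#' TSV: `node_id`, `kind`, `score_down`, `score_up`, `rank` (plus induced
#' edges in a companion `<stem>_edges.tsv`).
#'
#' @param core a [CoreGWGEN][CoreGWGEN-class].
#' @param path output path.
#' @export
writeCore <- function(core, path) {
  stopifnot(methods::is(core, "CoreGWGEN"))
  tab <- core@nodes
  for (col in c("score_down", "score_up", "score"))
    tab[[col]] <- .fmtNum(tab[[col]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ed <- core@edges
  if (nrow(ed))
    for (col in intersect(c("ability", "basal", "aic"), colnames(ed)))
      ed[[col]] <- .fmtNum(ed[[col]])
  utils::write.table(ed, sub("(\\.[^.]+)?$", "_edges.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
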