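#' Construct a CandidateGWGEN
#'
#' Builds the Boolean hypothesis network from a typed node table and an edge
#' list.  PPI edges may be given in either (or both) orientations; they are
#' symmetrised so that each protein-like node's candidate equation can be
#' read off its in-edges.
#'
#' @param nodes data.frame with columns `node_id`, `kind`.
#' @param edges data.frame with columns `source_id`, `target_id`,
#'   `edge_type` (see [gwgenEdgeTypes()]).
#' @param capped logical; TRUE marks a network whose per-equation degree cap
#'   has been applied (PPI symmetry no longer enforced).
#'
#' @return A [CandidateGWGEN][CandidateGWGEN-class].
#' @seealso [readNetwork()], [applyDegreeCap()]
#' @export
CandidateGWGEN <- function(nodes, edges, capped = FALSE) {
  nodes <- data.frame(node_id = as.character(nodes$node_id),
                      kind = as.character(nodes$kind),
                      stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edges <- data.frame(source_id = as.character(edges$source_id),
                        target_id = as.character(edges$target_id),
                        edge_type = as.character(edges$edge_type),
                        stringsAsFactors = FALSE)
    if (!capped) {
      ppi <- edges[edges$edge_type == "ppi", , drop = FALSE]
      if (nrow(ppi)) {
        sym <- rbind(ppi,
                     data.frame(source_id = ppi$target_id,
                                target_id = ppi$source_id,
                                edge_type = "ppi", stringsAsFactors = FALSE))
        sym <- sym[!duplicated(paste(sym$source_id, sym$target_id)), ,
                   drop = FALSE]
        edges <- rbind(edges[edges$edge_type != "ppi", , drop = FALSE], sym)
      }
    }
    edges <- edges[order(edges$target_id, edges$edge_type, edges$source_id), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- .emptyEdgeTable()
  }
  methods::new("CandidateGWGEN", nodes = nodes, edges = edges,
               capped = capped)
}

#' Accessors for network objects
#'
#' `networkNodes()` and `networkEdges()` return the node and edge tables of
#' candidate, identified, or core networks.
#'
#' @param x a [CandidateGWGEN][CandidateGWGEN-class],
#'   [RealGWGEN][RealGWGEN-class] or [CoreGWGEN][CoreGWGEN-class].
#' @return A data.frame.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

setMethod("networkNodes", "CandidateGWGEN", function(x) x@nodes)
setMethod("networkEdges", "CandidateGWGEN", function(x) x@edges)
setMethod("networkNodes", "RealGWGEN", function(x) x@nodes)
setMethod("networkEdges", "RealGWGEN", function(x) x@edges)
setMethod("networkNodes", "CoreGWGEN", function(x) x@nodes)
setMethod("networkEdges", "CoreGWGEN", function(x) x@edges)
setMethod("networkNodes", "GroundTruthModel", function(x) x@nodes)
setMethod("networkEdges", "GroundTruthModel", function(x) {
  cf <- x@coef
  data.frame(source_id = cf$regulator_id, target_id = cf$target_id,
             edge_type = cf$edge_type, ability = cf$ability,
             stringsAsFactors = FALSE)
})

#' Candidate regulators of one node's equation
#'
#' Returns the candidate regulator table of `target`'s model equation: PPI
#' partners for protein-kind nodes, GRN regulators (TFs, lncRNAs, miRNAs)
#' for gene/lncRNA/miRNA-kind nodes.  Regulator-only kinds (TF, receptor)
#' own no equation and yield an empty table.
#'
#' @param net a [CandidateGWGEN][CandidateGWGEN-class].
#' @param target node id.
#' @return data.frame with columns `regulator_id`, `edge_type`, sorted by
#'   regulator id.
#' @export
candidateRegulators <- function(net, target) {
  stopifnot(methods::is(net, "CandidateGWGEN"))
  kind <- net@nodes$kind[match(target, net@nodes$node_id)]
  if (is.na(kind)) stop(sprintf("unknown node '%s'", target))
  ed <- net@edges
  if (kind %in% c("TF", "receptor") || !nrow(ed))
    return(data.frame(regulator_id = character(0), edge_type = character(0)))
  sel <- if (kind == "protein") {
    ed$target_id == target & ed$edge_type == "ppi"
  } else {
    ed$target_id == target & ed$edge_type != "ppi"
  }
  out <- data.frame(regulator_id = ed$source_id[sel],
                    edge_type = ed$edge_type[sel], stringsAsFactors = FALSE)
  out[order(out$regulator_id), , drop = FALSE]
}

## target nodes that own an equation (kind protein/gene/lncRNA/miRNA)
.equationNodes <- function(net) {
  nd <- networkNodes(net)
  nd$node_id[nd$kind %in% .equationKinds]
}

setMethod("show", "CandidateGWGEN", function(object) {
  tt <- table(factor(object@edges$edge_type, levels = gwgenEdgeTypes()))
  nPPI <- if (object@capped) tt[["ppi"]] else tt[["ppi"]] / 2L
  cat(sprintf("CandidateGWGEN: %d nodes, %d PPI interactions%s, %d regulatory edges%s\n",
              nrow(object@nodes), nPPI,
              if (object@capped) " (directed, capped)" else "",
              sum(tt) - tt[["ppi"]],
              if (object@capped) " (capped)" else ""))
})

setMethod("show", "GroundTruthModel", function(object) {
  cat(sprintf("GroundTruthModel: %d nodes (%d targets), %d planted edges, noise sd %.3g\n",
              nrow(object@nodes), sum(object@nodes$role == "target"),
              nrow(object@coef), object@noiseSd))
})

#' @rdname networkNodes
#' @param x a GroundTruthModel.
#' @export
setGeneric("trueEdges", function(x) standardGeneric("trueEdges"))
setMethod("trueEdges", "GroundTruthModel", function(x) networkEdges(x))
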