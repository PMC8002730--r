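## Class definitions for the GWGEN data model.
##
## A GWGEN (genome-wide genetic and epigenetic network) is the union of an
## undirected protein-protein interaction network (PPIN) over protein-like
## nodes (protein, receptor, TF) and a directed gene regulatory network (GRN)
## whose regulators are TFs, lncRNAs and miRNAs and whose targets are genes,
## lncRNAs and miRNAs.

#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Controlled vocabularies -----------------------------------------------

#' Node kinds and edge types of a GWGEN
#'
#' `gwgenNodeKinds()` returns the node-kind vocabulary; `gwgenEdgeTypes()`
#' the edge-type vocabulary used in all edge-list files.  PPI edges connect
#' protein-like nodes (`protein`, `receptor`, `TF`); every other edge type is
#' a directed regulator-to-target edge named `<regulatorkind>_<targetkind>`.
#'
#' @return A character vector.
#' @examples
#' gwgenNodeKinds()
#' gwgenEdgeTypes()
#' @export
gwgenNodeKinds <- function() {
  c("protein", "receptor", "TF", "gene", "lncRNA", "miRNA")
}

#' @rdname gwgenNodeKinds
#' @export
gwgenEdgeTypes <- function() {
  c("ppi",
    "tf_gene", "tf_lncrna", "tf_mirna",
    "lncrna_gene", "lncrna_lncrna", "lncrna_mirna",
    "mirna_gene", "mirna_lncrna", "mirna_mirna")
}

## kinds allowed as PPI endpoints
.proteinLikeKinds <- c("protein", "receptor", "TF")
## kinds that own a regression equation (identification targets)
.equationKinds <- c("protein", "gene", "lncRNA", "miRNA")
## kinds that can appear as a column of the combined matrix W
.regulatorKinds <- c("protein", "receptor", "TF", "lncRNA", "miRNA")

## regulator / target kind implied by each directed edge type
.edgeTypeSourceKind <- c(
  tf_gene = "TF", tf_lncrna = "TF", tf_mirna = "TF",
  lncrna_gene = "lncRNA", lncrna_lncrna = "lncRNA", lncrna_mirna = "lncRNA",
  mirna_gene = "miRNA", mirna_lncrna = "miRNA", mirna_mirna = "miRNA")
.edgeTypeTargetKind <- c(
  tf_gene = "gene", tf_lncrna = "lncRNA", tf_mirna = "miRNA",
  lncrna_gene = "gene", lncrna_lncrna = "lncRNA", lncrna_mirna = "miRNA",
  mirna_gene = "gene", mirna_lncrna = "lncRNA", mirna_mirna = "miRNA")

.edgeTypeFor <- function(sourceKind, targetKind) {
  pre <- c(TF = "tf", lncRNA = "lncrna", miRNA = "mirna")[sourceKind]
  suf <- c(gene = "gene", lncRNA = "lncrna", miRNA = "mirna")[targetKind]
  paste(pre, suf, sep = "_")
}

.checkNodeTable <- function(nodes) {
  msg <- NULL
  if (!is.data.frame(nodes) ||
      !all(c("node_id", "kind") %in% colnames(nodes)))
    return("'nodes' must be a data.frame with columns node_id and kind")
  if (anyDuplicated(nodes$node_id))
    msg <- c(msg, sprintf("duplicated node_id: %s",
                          paste(unique(nodes$node_id[duplicated(nodes$node_id)]),
                                collapse = ", ")))
  bad <- setdiff(unique(nodes$kind), gwgenNodeKinds())
  if (length(bad))
    msg <- c(msg, sprintf("unknown node kind(s): %s",
                          paste(bad, collapse = ", ")))
  msg
}

.checkEdgeTable <- function(edges, nodes, requireSymmetricPPI = TRUE) {
  msg <- NULL
  need <- c("source_id", "target_id", "edge_type")
  if (!is.data.frame(edges) || !all(need %in% colnames(edges)))
    return("'edges' must be a data.frame with columns source_id, target_id, edge_type")
  if (nrow(edges) == 0L) return(NULL)
  bad <- setdiff(unique(edges$edge_type), gwgenEdgeTypes())
  if (length(bad))
    msg <- c(msg, sprintf("unknown edge_type(s): %s", paste(bad, collapse = ", ")))
  kind <- stats::setNames(nodes$kind, nodes$node_id)
  unknown <- setdiff(unique(c(edges$source_id, edges$target_id)), nodes$node_id)
  if (length(unknown))
    return(c(msg, sprintf("edge references unknown node(s): %s",
                          paste(utils::head(unknown, 5L), collapse = ", "))))
  ppi <- edges$edge_type == "ppi"
  if (any(ppi)) {
    if (any(edges$source_id[ppi] == edges$target_id[ppi]))
      msg <- c(msg, "PPI self-interactions are not allowed")
    okKind <- kind[edges$source_id[ppi]] %in% .proteinLikeKinds &
      kind[edges$target_id[ppi]] %in% .proteinLikeKinds
    if (!all(okKind))
      msg <- c(msg, "PPI edges must connect protein-like nodes (protein/receptor/TF)")
    if (requireSymmetricPPI) {
      fwd <- paste(edges$source_id[ppi], edges$target_id[ppi])
      rev <- paste(edges$target_id[ppi], edges$source_id[ppi])
      if (!all(fwd %in% rev))
        msg <- c(msg, "PPI edges must be stored symmetrically")
    }
  }
  dir <- !ppi & edges$edge_type %in% names(.edgeTypeSourceKind)
  if (any(dir)) {
    t <- edges$edge_type[dir]
    okS <- kind[edges$source_id[dir]] == .edgeTypeSourceKind[t]
    okT <- kind[edges$target_id[dir]] == .edgeTypeTargetKind[t]
    if (!all(okS & okT)) {
      i <- which(!(okS & okT))[1L]
      e <- edges[dir, ][i, ]
      msg <- c(msg, sprintf(
        "edge %s -> %s incompatible with edge_type '%s' (kinds %s -> %s)",
        e$source_id, e$target_id, e$edge_type,
        kind[e$source_id], kind[e$target_id]))
    }
  }
  key <- paste(edges$source_id, edges$target_id, edges$edge_type)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicated edges")
  msg
}

## ExpressionDataset ------------------------------------------------------

#' ExpressionDataset: node-by-sample expression levels
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] wrapper holding one
#' assay `"expr"` (nodes in rows, samples in columns, microarray-style log
#' intensities), a `kind` column in `rowData`, and an optional condition
#' label in `metadata(x)$condition`.  Values must be finite; miRNA rows must
#' be non-negative so that the bilinear repression term of the gene model
#' acts as a repression when its coefficient is non-positive.
#'
#' @name ExpressionDataset-class
#' @aliases ExpressionDataset-class
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- NULL
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    return("assay 'expr' is missing")
  m <- SummarizedExperiment::assay(object, "expr")
  if (!is.numeric(m) || any(!is.finite(m)))
    msg <- c(msg, "expression values must be finite numerics (no NA)")
  rd <- SummarizedExperiment::rowData(object)
  if (!"kind" %in% colnames(rd))
    return(c(msg, "rowData column 'kind' is missing"))
  bad <- setdiff(unique(rd$kind), gwgenNodeKinds())
  if (length(bad))
    msg <- c(msg, sprintf("unknown node kind(s): %s", paste(bad, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "node ids (rownames) must be unique and non-NULL")
  mi <- rd$kind == "miRNA"
  if (any(mi) && is.numeric(m) && any(m[mi, , drop = FALSE] < 0))
    msg <- c(msg, "miRNA expression values must be >= 0")
  if (is.null(msg)) TRUE else msg
})

## CandidateGWGEN ---------------------------------------------------------

#' CandidateGWGEN: the Boolean hypothesis network
#'
#' Candidate PPI adjacency plus candidate regulator-to-target incidence,
#' stored as a directed edge list over a typed node table.  PPI edges are
#' symmetrised at construction (both orientations stored) so each node's
#' candidate equation can be read off its in-edges.  After
#' [applyDegreeCap()] the PPI part may be asymmetric: an interaction can
#' survive as a candidate term in one endpoint's equation and be dropped
#' from the other's; such capped networks carry `capped = TRUE`.
#'
#' @slot nodes data.frame with columns `node_id`, `kind`.
#' @slot edges data.frame with columns `source_id`, `target_id`, `edge_type`.
#' @slot capped logical scalar; TRUE once a per-equation degree cap has been
#'   applied (relaxes the PPI symmetry invariant).
#' @name CandidateGWGEN-class
#' @aliases CandidateGWGEN-class
#' @exportClass CandidateGWGEN
setClass("CandidateGWGEN",
         representation(nodes = "data.frame", edges = "data.frame",
                        capped = "logical"),
         prototype(capped = FALSE))

setValidity("CandidateGWGEN", function(object) {
  msg <- .checkNodeTable(object@nodes)
  if (is.null(msg))
    msg <- .checkEdgeTable(object@edges, object@nodes,
                           requireSymmetricPPI = !isTRUE(object@capped))
  if (is.null(msg)) TRUE else msg
})

## GroundTruthModel -------------------------------------------------------

#' GroundTruthModel: planted network and model parameters
#'
#' The generating model of a synthetic study: per-target regulator sets with
#' signed abilities, per-target basal levels, and the noise standard
#' deviation.  Abilities in miRNA-regulator slots are stored as the signed
#' model coefficient (i.e. minus the repression magnitude), hence are always
#' `<= 0`.  The node table carries a `role` column: `source` nodes are drawn
#' i.i.d. and act only as regressors; `target` nodes are computed from the
#' rearranged model equations and own an identifiable equation.
#'
#' @slot nodes data.frame with columns `node_id`, `kind`, `role`.
#' @slot coef data.frame with columns `target_id`, `regulator_id`,
#'   `edge_type`, `ability` (signed real).
#' @slot basal named numeric, basal level per target node.
#' @slot noiseSd non-negative numeric scalar (default noise level).
#' @name GroundTruthModel-class
#' @aliases GroundTruthModel-class
#' @exportClass GroundTruthModel
setClass("GroundTruthModel",
         representation(nodes = "data.frame", coef = "data.frame",
                        basal = "numeric", noiseSd = "numeric"))

setValidity("GroundTruthModel", function(object) {
  msg <- .checkNodeTable(object@nodes)
  if (!is.null(msg)) return(msg)
  if (!"role" %in% colnames(object@nodes) ||
      !all(object@nodes$role %in% c("source", "target")))
    msg <- c(msg, "nodes must carry a role column with values source/target")
  cf <- object@coef
  need <- c("target_id", "regulator_id", "edge_type", "ability")
  if (!all(need %in% colnames(cf)))
    return(c(msg, "coef must have columns target_id, regulator_id, edge_type, ability"))
  if (nrow(cf)) {
    kind <- stats::setNames(object@nodes$kind, object@nodes$node_id)
    miSlot <- kind[cf$regulator_id] == "miRNA" & cf$edge_type != "ppi"
    if (any(cf$ability[miSlot] > 0))
      msg <- c(msg, "miRNA repression coefficients must be <= 0")
    if (any(cf$edge_type == "ppi" & cf$target_id == cf$regulator_id))
      msg <- c(msg, "protein self-interaction is not allowed")
  }
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single non-negative number")
  if (is.null(msg)) TRUE else msg
})

## RegressionProblem ------------------------------------------------------

#' RegressionProblem: one node's constrained least-squares problem
#'
#' Response vector and regressor matrix for a single node's model equation.
#' The regressor matrix carries one column per candidate regulator plus a
#' trailing all-ones column for the basal level.  `constrained` marks the
#' miRNA-repression slots whose coefficients must satisfy `<= 0`.
#'
#' @slot targetId the node whose equation this is.
#' @slot response numeric response vector (length N).
#' @slot regressors N x (k+1) matrix; last column is the basal ones column.
#' @slot labels parameter labels (regulator node ids, then "basal").
#' @slot constrained logical mask over columns (TRUE = coefficient <= 0).
#' @slot regulatorKinds named character, kind of each regulator column.
#' @slot edgeTypes named character, candidate edge type of each regulator.
#' @name RegressionProblem-class
#' @aliases RegressionProblem-class
#' @exportClass RegressionProblem
setClass("RegressionProblem",
         representation(targetId = "character", response = "numeric",
                        regressors = "matrix", labels = "character",
                        constrained = "logical", regulatorKinds = "character",
                        edgeTypes = "character"))

setValidity("RegressionProblem", function(object) {
  msg <- NULL
  if (nrow(object@regressors) != length(object@response))
    msg <- c(msg, "regressor rows must match response length")
  if (ncol(object@regressors) != length(object@labels) ||
      length(object@labels) != length(object@constrained))
    msg <- c(msg, "labels/constrained must align with regressor columns")
  if (length(object@labels) && utils::tail(object@labels, 1L) != "basal")
    msg <- c(msg, "last column must be the basal term")
  if (length(object@constrained) && utils::tail(object@constrained, 1L))
    msg <- c(msg, "the basal term cannot be sign-constrained")
  k <- object@regulatorKinds
  if (any(object@constrained[seq_along(k)] & k != "miRNA"))
    msg <- c(msg, "only miRNA-repression slots may be constrained")
  if (is.null(msg)) TRUE else msg
})

## NodeModel & RealGWGEN --------------------------------------------------

#' NodeModel: one node's identified model
#'
#' Selected regulators with estimated abilities, the basal estimate, the
#' residual variance `rss/N`, the AIC at the selected order, and the
#' selected order (number of retained regulators).
#'
#' @slot nodeId character scalar.
#' @slot regulators character vector of selected regulator ids.
#' @slot abilities named numeric, estimated signed abilities.
#' @slot edgeTypes named character, edge type per selected regulator.
#' @slot basal numeric scalar, estimated basal level.
#' @slot rss numeric scalar, residual sum of squares at the selected order.
#' @slot sigma2 numeric scalar, `rss/N`.
#' @slot aic numeric scalar.
#' @slot order integer scalar, number of selected regulators.
#' @slot orderByKind named integer, selected order split by regulator kind.
#' @name NodeModel-class
#' @aliases NodeModel-class
#' @exportClass NodeModel
setClass("NodeModel",
         representation(nodeId = "character", regulators = "character",
                        abilities = "numeric", edgeTypes = "character",
                        basal = "numeric", rss = "numeric", sigma2 = "numeric",
                        aic = "numeric", order = "integer",
                        orderByKind = "integer"))

setValidity("NodeModel", function(object) {
  msg <- NULL
  if (object@order != length(object@regulators))
    msg <- c(msg, "order must equal the number of selected regulators")
  mi <- object@edgeTypes != "ppi" &
    grepl("^mirna_", object@edgeTypes)
  if (any(object@abilities[mi] > 0))
    msg <- c(msg, "estimated miRNA-slot coefficients must be <= 0")
  if (is.null(msg)) TRUE else msg
})

#' RealGWGEN: the identified network
#'
#' One [NodeModel][NodeModel-class] per target node plus the derived signed
#' edge list.  Identification only prunes: every edge here exists in the
#' candidate network it was identified from.
#'
#' @slot nodes data.frame (`node_id`, `kind`).
#' @slot models named list of `NodeModel` objects (one per target node).
#' @slot edges data.frame with columns `source_id`, `target_id`,
#'   `edge_type`, `ability`, `basal`, `aic`, `order`.
#' @name RealGWGEN-class
#' @aliases RealGWGEN-class
#' @exportClass RealGWGEN
setClass("RealGWGEN",
         representation(nodes = "data.frame", models = "list",
                        edges = "data.frame"))

## PNP objects ------------------------------------------------------------

#' CombinedMatrix: the ability matrix W of a RealGWGEN
#'
#' Rows are target nodes (protein, gene, lncRNA, miRNA); columns are
#' regulator-capable nodes (protein, receptor, TF, lncRNA, miRNA), ordered
#' by kind block then node id.  Entry (r, c) is the estimated ability of the
#' selected edge c -> r (or the PPI ability identified in r's equation) and
#' zero where no edge was selected.
#'
#' @slot W sparse numeric matrix ([Matrix::dgCMatrix-class]).
#' @slot rowKinds named character, kind per row node.
#' @slot colKinds named character, kind per column node.
#' @name CombinedMatrix-class
#' @aliases CombinedMatrix-class
#' @exportClass CombinedMatrix
setClass("CombinedMatrix",
         representation(W = "Matrix", rowKinds = "character",
                        colKinds = "character"))

#' ProjectionResult: principal network projection scores
#'
#' Singular spectrum of W, eigenexpression fractions, the selected rank S
#' (minimal cumulative energy >= threshold), and the per-node 2-norm
#' projection scores: downstream (columns, regulator role) and upstream
#' (rows, target role).
#'
#' @slot d numeric, singular values in descending order.
#' @slot E numeric, eigenexpression fractions d_s^2 / sum(d^2).
#' @slot S integer, selected rank.
#' @slot threshold numeric, energy threshold used to select S (NA if S was
#'   supplied directly).
#' @slot Qdown named numeric, downstream projection score per column node.
#' @slot Qup named numeric, upstream projection score per row node.
#' @slot Tmat,Hmat left/right singular vector matrices (sign-fixed).
#' @name ProjectionResult-class
#' @aliases ProjectionResult-class
#' @exportClass ProjectionResult
setClass("ProjectionResult",
         representation(d = "numeric", E = "numeric", S = "integer",
                        threshold = "numeric", Qdown = "numeric",
                        Qup = "numeric", Tmat = "matrix", Hmat = "matrix"))

#' CoreGWGEN: the core network extracted by projection ranking
#'
#' The top-ranked nodes by projection score with the induced signed edges.
#'
#' @slot nodes data.frame: `node_id`, `kind`, `score_down`, `score_up`,
#'   `score`, `rank`.
#' @slot edges data.frame, induced edges (both endpoints in the core).
#' @slot provenance list: `top_k`, `threshold`, `S`, `n_network_nodes`.
#' @name CoreGWGEN-class
#' @aliases CoreGWGEN-class
#' @exportClass CoreGWGEN
setClass("CoreGWGEN",
         representation(nodes = "data.frame", edges = "data.frame",
                        provenance = "list"))

## Comparison -------------------------------------------------------------

#' ComparisonReport: common and distinctive core structure
#'
#' @slot nameA,nameB condition labels.
#' @slot commonNodes,distinctiveA,distinctiveB character vectors of node ids.
#' @slot commonEdges,distinctiveEdgesA,distinctiveEdgesB data.frames.
#' @slot overlap data.frame: `kind`, `overlap_pct_a`, `overlap_pct_b`
#'   (percentage of that condition's core nodes of the kind that also occur
#'   in the other core; NA when the condition has no nodes of the kind).
#' @slot direction named character, per-node expression direction
#'   (`up`/`down`/`unknown`) of case versus control, when computed.
#' @name ComparisonReport-class
#' @aliases ComparisonReport-class
#' @exportClass ComparisonReport
setClass("ComparisonReport",
         representation(nameA = "character", nameB = "character",
                        commonNodes = "character", distinctiveA = "character",
                        distinctiveB = "character", commonEdges = "data.frame",
                        distinctiveEdgesA = "data.frame",
                        distinctiveEdgesB = "data.frame",
                        overlap = "data.frame", direction = "character"))

## Drug design ------------------------------------------------------------

#' DrugCatalog: per-drug per-target connectivity scores and toxicity
#'
#' @slot table data.frame with columns `drug`, `target`,
#'   `connectivity_score` (in \[-1, 1\]), `ld50_mg_per_kg` (> 0);
#'   (drug, target) pairs unique.
#' @slot metadata list (free-form; the synthetic fixture records its
#'   designed cover here).
#' @name DrugCatalog-class
#' @aliases DrugCatalog-class
#' @exportClass DrugCatalog
setClass("DrugCatalog",
         representation(table = "data.frame", metadata = "list"),
         prototype(metadata = list()))

setValidity("DrugCatalog", function(object) {
  tb <- object@table
  need <- c("drug", "target", "connectivity_score", "ld50_mg_per_kg")
  if (!all(need %in% colnames(tb)))
    return(sprintf("catalog must have columns %s", paste(need, collapse = ", ")))
  msg <- NULL
  if (nrow(tb)) {
    if (any(abs(tb$connectivity_score) > 1))
      msg <- c(msg, "connectivity scores must lie in [-1, 1]")
    if (any(tb$ld50_mg_per_kg <= 0))
      msg <- c(msg, "LD50 values must be positive")
    if (anyDuplicated(paste(tb$drug, tb$target)))
      msg <- c(msg, "(drug, target) pairs must be unique")
  }
  if (is.null(msg)) TRUE else msg
})

#' MultiDrugProposal: a minimal multi-molecule drug set
#'
#' Greedy set-cover selection of drugs over the biomarker targets, with the
#' drug-by-target coverage matrix (the checked-matrix layout familiar from
#' drug-repurposing tables) and per-selection justification.
#'
#' @slot drugs character, selected drugs in selection order.
#' @slot coverage logical matrix, drugs x targets.
#' @slot details data.frame of the proposed (drug, target) pairs with
#'   `connectivity_score` and `ld50_mg_per_kg`.
#' @slot uncovered character, targets no surviving drug could cover.
#' @name MultiDrugProposal-class
#' @aliases MultiDrugProposal-class
#' @exportClass MultiDrugProposal
setClass("MultiDrugProposal",
         representation(drugs = "character", coverage = "matrix",
                        details = "data.frame", uncovered = "character"))
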