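## Comparison module: common vs distinctive core structure between two
## conditions, per-kind overlap percentages, and expression direction
## labels.

#' Compare two core GWGENs
#'
#' Splits the two cores' node and edge sets into common and
#' condition-distinctive parts and computes per-kind overlap percentages:
#' for condition A and kind k, `100 * |k-nodes of A that are also in B| /
#' |k-nodes of A|` (the denominator is the named condition's own core).
#' Kinds absent from a condition's core get `NA` rather than 0 (the
#' overlap is undefined, not empty).
#'
#' @param coreA,coreB [CoreGWGEN][CoreGWGEN-class] objects over a shared
#'   node-id namespace.
#' @param nameA,nameB condition labels for reporting.
#' @return A [ComparisonReport][ComparisonReport-class].
#' @export
compareCores <- function(coreA, coreB, nameA = "A", nameB = "B") {
  stopifnot(methods::is(coreA, "CoreGWGEN"), methods::is(coreB, "CoreGWGEN"))
  nA <- coreA@nodes; nB <- coreB@nodes
  common <- sort(intersect(nA$node_id, nB$node_id))
  distA <- sort(setdiff(nA$node_id, nB$node_id))
  distB <- sort(setdiff(nB$node_id, nA$node_id))
  keyA <- .edgeKey(coreA@edges); keyB <- .edgeKey(coreB@edges)
  commonEdges <- coreA@edges[keyA %in% keyB, , drop = FALSE]
  distEdgesA <- coreA@edges[!keyA %in% keyB, , drop = FALSE]
  distEdgesB <- coreB@edges[!keyB %in% keyA, , drop = FALSE]
  kinds <- sort(unique(c(nA$kind, nB$kind)))
  pct <- function(own, other, kind) {
    ownK <- own$node_id[own$kind == kind]
    if (!length(ownK)) return(NA_real_)
    100 * sum(ownK %in% other$node_id) / length(ownK)
  }
  overlap <- data.frame(
    kind = kinds,
    overlap_pct_a = vapply(kinds, function(k) pct(nA, nB, k), numeric(1L)),
    overlap_pct_b = vapply(kinds, function(k) pct(nB, nA, k), numeric(1L)),
    stringsAsFactors = FALSE)
  rownames(overlap) <- NULL
  methods::new("ComparisonReport", nameA = nameA, nameB = nameB,
               commonNodes = common, distinctiveA = distA,
               distinctiveB = distB, commonEdges = commonEdges,
               distinctiveEdgesA = distEdgesA,
               distinctiveEdgesB = distEdgesB, overlap = overlap,
               direction = stats::setNames(character(0), character(0)))
}

#' Label node expression direction between conditions
#'
#' A node is `up` when its mean expression in the case dataset exceeds the
#' control mean, `down` otherwise (ties are `down`, deterministically);
#' optionally a minimum absolute mean difference can be required, below
#' which the label is `down`.  Nodes missing from either dataset are
#' `unknown`.
#'
#' @param core a [CoreGWGEN][CoreGWGEN-class] (or any object with a
#'   `node_id` column in `networkNodes()`).
#' @param dataCase,dataControl [ExpressionDataset][ExpressionDataset-class]
#'   objects.
#' @param minAbsDiff minimum |mean difference| to call `up` (default 0).
#' @return named character vector over the core's nodes.
#' @export
directionLabels <- function(core, dataCase, dataControl, minAbsDiff = 0) {
  ids <- networkNodes(core)$node_id
  mc <- exprValues(dataCase); mk <- exprValues(dataControl)
  out <- stats::setNames(rep("unknown", length(ids)), ids)
  present <- ids %in% rownames(mc) & ids %in% rownames(mk)
  if (any(present)) {
    dd <- rowMeans(mc[ids[present], , drop = FALSE]) -
      rowMeans(mk[ids[present], , drop = FALSE])
    out[present] <- ifelse(dd > minAbsDiff & dd > 0, "up", "down")
  }
  out
}

#' Attach direction labels to a comparison report
#'
#' @param report a [ComparisonReport][ComparisonReport-class].
#' @param direction named character vector from [directionLabels()].
#' @return the updated report.
#' @export
withDirections <- function(report, direction) {
  stopifnot(methods::is(report, "ComparisonReport"))
  report@direction <- direction
  report
}

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport %s vs %s: %d common nodes, %d distinctive-%s, %d distinctive-%s\n",
              object@nameA, object@nameB, length(object@commonNodes),
              length(object@distinctiveA), object@nameA,
              length(object@distinctiveB), object@nameB))
  cat(sprintf("  common edges: %d; distinctive edges: %d (%s) / %d (%s)\n",
              nrow(object@commonEdges), nrow(object@distinctiveEdgesA),
              object@nameA, nrow(object@distinctiveEdgesB), object@nameB))
  print(object@overlap, row.names = FALSE)
})

#' Serialise a comparison report
#'
#' Writes a JSON summary and a TSV node table (membership + direction).
#'
#' @param report a [ComparisonReport][ComparisonReport-class].
#' @param jsonPath,tsvPath output paths.
#' @export
writeComparison <- function(report, jsonPath, tsvPath) {
  stopifnot(methods::is(report, "ComparisonReport"))
  summary <- list(
    condition_a = report@nameA, condition_b = report@nameB,
    n_common_nodes = length(report@commonNodes),
    n_distinctive_a = length(report@distinctiveA),
    n_distinctive_b = length(report@distinctiveB),
    n_common_edges = nrow(report@commonEdges),
    n_distinctive_edges_a = nrow(report@distinctiveEdgesA),
    n_distinctive_edges_b = nrow(report@distinctiveEdgesB),
    overlap = report@overlap)
  jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  ids <- sort(unique(c(report@commonNodes, report@distinctiveA,
                       report@distinctiveB)))
  membership <- ifelse(ids %in% report@commonNodes, "common",
                       ifelse(ids %in% report@distinctiveA,
                              paste0("distinctive_", report@nameA),
                              paste0("distinctive_", report@nameB)))
  dirs <- if (length(report@direction))
    unname(report@direction[ids]) else NA_character_
  utils::write.table(
    data.frame(node_id = ids, membership = membership, direction = dirs),
    tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(jsonPath)
}
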