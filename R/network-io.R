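## TSV readers/writers for expression matrices, networks and drug tables,
## plus the sample-count degree cap applied before identification.
##
## Formats (all tab-separated with header):
##   expression:  node_id, node_kind, <one column per sample>
##   network:     source_id, target_id, edge_type [, is_true] and, for
##                identified networks, ability, basal, aic, order; a
##                companion "<stem>_nodes.tsv" file carries node_id,
##                node_kind
##   drug catalog (CSV or TSV): drug, target, connectivity_score,
##                ld50_mg_per_kg

.nodesPathFor <- function(path) {
  sub("(\\.[^.]+)?$", "_nodes.tsv", path)
}

#' Read / write an expression matrix
#'
#' TSV with columns `node_id`, `node_kind`, then one numeric column per
#' sample.  Writing uses 15 significant digits so a write/read round trip
#' is lossless to well below 1e-12.
#'
#' @param path file path.
#' @param condition optional condition label attached on read.
#' @return `readExpression()` returns an
#'   [ExpressionDataset][ExpressionDataset-class].
#' @export
readExpression <- function(path, condition = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("node_id", "node_kind") %in% colnames(df)))
    stop("expression file must have node_id and node_kind columns")
  dup <- df$node_id[duplicated(df$node_id)]
  if (length(dup))
    stop(sprintf("duplicated node_id '%s' (row %d)", dup[1L],
                 which(df$node_id == dup[1L])[2L]))
  bad <- which(!df$node_kind %in% gwgenNodeKinds())
  if (length(bad))
    stop(sprintf("unknown node_kind '%s' (row %d)",
                 df$node_kind[bad[1L]], bad[1L]))
  sampleCols <- setdiff(colnames(df), c("node_id", "node_kind"))
  if (!length(sampleCols)) stop("expression file has no sample columns")
  m <- matrix(NA_real_, nrow(df), length(sampleCols),
              dimnames = list(df$node_id, sampleCols))
  for (j in seq_along(sampleCols)) {
    v <- suppressWarnings(as.numeric(df[[sampleCols[j]]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in column '%s' (row %d)",
                   sampleCols[j], which(is.na(v))[1L]))
    m[, j] <- v
  }
  ExpressionDataset(m, stats::setNames(df$node_kind, df$node_id),
                    condition = condition)
}

#' @rdname readExpression
#' @param data an [ExpressionDataset][ExpressionDataset-class].
#' @export
writeExpression <- function(data, path) {
  stopifnot(methods::is(data, "ExpressionDataset"))
  m <- exprValues(data)
  out <- data.frame(node_id = rownames(m),
                    node_kind = unname(nodeKinds(data)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) out[[colnames(m)[j]]] <- .fmtNum(m[, j])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a network edge list
#'
#' Edge-list TSV plus a companion node-table TSV (default
#' `<stem>_nodes.tsv`).  PPI edges are re-symmetrised on read, so a capped
#' (asymmetric) network is an in-memory stage object, not an interchange
#' format.  When a [GroundTruthModel][GroundTruthModel-class] is supplied
#' to `writeNetwork()` an `is_true` 0/1 column marks the planted edges.
#'
#' @param path edge-list file path.
#' @param nodesPath node-table file path.
#' @return `readNetwork()` returns a
#'   [CandidateGWGEN][CandidateGWGEN-class].
#' @export
readNetwork <- function(path, nodesPath = .nodesPathFor(path)) {
  nodes <- utils::read.delim(nodesPath, colClasses = "character")
  if (!all(c("node_id", "node_kind") %in% colnames(nodes)))
    stop("node table must have node_id and node_kind columns")
  edges <- utils::read.delim(path, colClasses = "character")
  need <- c("source_id", "target_id", "edge_type")
  if (!all(need %in% colnames(edges)))
    stop("network file must have source_id, target_id, edge_type columns")
  bad <- which(!edges$edge_type %in% gwgenEdgeTypes())
  if (length(bad))
    stop(sprintf("unknown edge_type '%s' (row %d)",
                 edges$edge_type[bad[1L]], bad[1L]))
  CandidateGWGEN(data.frame(node_id = nodes$node_id, kind = nodes$node_kind),
                 edges[, need])
}

#' @rdname readNetwork
#' @param net a [CandidateGWGEN][CandidateGWGEN-class].
#' @param truth optional [GroundTruthModel][GroundTruthModel-class]; adds
#'   the `is_true` flag column.
#' @export
writeNetwork <- function(net, path, nodesPath = .nodesPathFor(path),
                         truth = NULL) {
  stopifnot(methods::is(net, "CandidateGWGEN"))
  ed <- networkEdges(net)
  ## write each symmetric PPI pair once (canonical orientation); a lone
  ## asymmetric row (capped network) is written as-is
  ppi <- ed$edge_type == "ppi"
  fwdKey <- paste(ed$source_id, ed$target_id)
  revPresent <- paste(ed$target_id, ed$source_id) %in% fwdKey[ppi]
  keep <- !ppi | ed$source_id < ed$target_id | !revPresent
  out <- ed[keep, , drop = FALSE]
  if (!is.null(truth)) {
    tk <- .edgeKey(networkEdges(truth))
    out$is_true <- as.integer(.edgeKey(out) %in% tk)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nd <- networkNodes(net)
  utils::write.table(data.frame(node_id = nd$node_id, node_kind = nd$kind),
                     nodesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an identified network
#'
#' Identified-network TSV: one row per selected edge with the estimated
#' `ability` plus the target-node model summary (`basal`, `aic`, `order`),
#' and a companion node table.  Reading back reconstructs the edge list and
#' per-node models (without residual details).
#'
#' @param real a [RealGWGEN][RealGWGEN-class].
#' @param path file path.
#' @param nodesPath node-table path.
#' @return `readRealGWGEN()` returns a [RealGWGEN][RealGWGEN-class].
#' @export
writeRealGWGEN <- function(real, path, nodesPath = .nodesPathFor(path)) {
  stopifnot(methods::is(real, "RealGWGEN"))
  ed <- networkEdges(real)
  out <- ed
  for (col in c("ability", "basal", "aic"))
    out[[col]] <- .fmtNum(ed[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nd <- networkNodes(real)
  utils::write.table(data.frame(node_id = nd$node_id, node_kind = nd$kind),
                     nodesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRealGWGEN
#' @export
readRealGWGEN <- function(path, nodesPath = .nodesPathFor(path)) {
  nodes <- utils::read.delim(nodesPath, colClasses = "character")
  ed <- utils::read.delim(path, colClasses = "character")
  need <- c("source_id", "target_id", "edge_type", "ability", "basal",
            "aic", "order")
  if (!all(need %in% colnames(ed)))
    stop("identified-network file must have columns: ",
         paste(need, collapse = ", "))
  for (col in c("ability", "basal", "aic")) ed[[col]] <- as.numeric(ed[[col]])
  ed$order <- as.integer(ed$order)
  nd <- data.frame(node_id = nodes$node_id, kind = nodes$node_kind,
                   stringsAsFactors = FALSE)
  models <- list()
  for (tg in unique(ed$target_id)) {
    rows <- ed[ed$target_id == tg, , drop = FALSE]
    rows <- rows[order(rows$source_id), , drop = FALSE]
    models[[tg]] <- methods::new(
      "NodeModel", nodeId = tg, regulators = rows$source_id,
      abilities = stats::setNames(rows$ability, rows$source_id),
      edgeTypes = stats::setNames(rows$edge_type, rows$source_id),
      basal = rows$basal[1L], rss = NA_real_, sigma2 = NA_real_,
      aic = rows$aic[1L], order = nrow(rows),
      orderByKind = .orderByKind(rows$edge_type, nd, rows$source_id))
  }
  methods::new("RealGWGEN", nodes = nd, models = models,
               edges = ed[, need])
}

#' Read / write a drug catalog
#'
#' CSV (or TSV, by file extension) with columns `drug`, `target`,
#' `connectivity_score`, `ld50_mg_per_kg`.
#'
#' @param path file path; `.tsv` files are tab-separated, anything else
#'   comma-separated.
#' @return `readDrugCatalog()` returns a [DrugCatalog][DrugCatalog-class].
#' @export
readDrugCatalog <- function(path) {
  if (!file.exists(path))
    stop(sprintf("drug catalog '%s' not found", path))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c("connectivity_score", "ld50_mg_per_kg"))
    df[[col]] <- as.numeric(df[[col]])
  methods::new("DrugCatalog", table = df, metadata = list())
}

#' @rdname readDrugCatalog
#' @param catalog a [DrugCatalog][DrugCatalog-class].
#' @export
writeDrugCatalog <- function(catalog, path) {
  stopifnot(methods::is(catalog, "DrugCatalog"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tb <- catalog@table
  tb$connectivity_score <- .fmtNum(tb$connectivity_score)
  tb$ld50_mg_per_kg <- .fmtNum(tb$ld50_mg_per_kg)
  utils::write.table(tb, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a biomarker signature table
#'
#' TSV with columns `node_id`, `direction` (`up`/`down`).
#'
#' @param path file path.
#' @return named character vector of directions.
#' @export
readSignature <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("node_id", "direction") %in% colnames(df)))
    stop("signature file must have node_id and direction columns")
  bad <- setdiff(unique(df$direction), c("up", "down"))
  if (length(bad))
    stop(sprintf("unknown direction(s): %s", paste(bad, collapse = ", ")))
  stats::setNames(df$direction, df$node_id)
}

## Degree cap -------------------------------------------------------------

#' Cap each node's candidate in-degree below the sample count
#'
#' Before identification, each node's regression must have fewer parameters
#' (candidate regulators + 1 basal term) than samples.  For any node whose
#' candidate equation exceeds the cap, candidate regulators are ranked by
#' the absolute Pearson correlation of the constructed regressor with the
#' response (the bilinear product `p_i * p_j` for PPI terms and
#' `m_v * g_x` for miRNA-repression terms; the raw regulator series
#' otherwise) and only the top `nSamples - 2` are kept, ties broken by
#' lexicographic regulator id.  The cap is per target equation: a symmetric
#' PPI interaction may survive as a candidate for one endpoint and be
#' dropped from the other's equation, so the result is marked `capped`.
#'
#' @param net a [CandidateGWGEN][CandidateGWGEN-class].
#' @param data an [ExpressionDataset][ExpressionDataset-class] covering all
#'   network nodes.
#' @param nSamples sample count; defaults to `ncol(data)`.  Must be >= 3.
#' @return A capped [CandidateGWGEN][CandidateGWGEN-class].
#' @export
applyDegreeCap <- function(net, data, nSamples = ncol(data)) {
  stopifnot(methods::is(net, "CandidateGWGEN"),
            methods::is(data, "ExpressionDataset"))
  nSamples <- .assertCount(nSamples, "nSamples")
  if (nSamples < 3L)
    stop("refusing to cap with nSamples < 3: no degrees of freedom")
  m <- exprValues(data)
  miss <- setdiff(networkNodes(net)$node_id, rownames(m))
  if (length(miss))
    stop(sprintf("expression data missing node(s): %s",
                 paste(utils::head(miss, 5L), collapse = ", ")))
  cap <- nSamples - 2L
  ed <- networkEdges(net)
  drop <- logical(nrow(ed))
  edKey <- paste(ed$source_id, ed$target_id, ed$edge_type)
  for (tg in .equationNodes(net)) {
    cand <- candidateRegulators(net, tg)
    if (nrow(cand) <= cap) next
    y <- m[tg, ]
    score <- vapply(seq_len(nrow(cand)), function(i) {
      reg <- m[cand$regulator_id[i], ]
      x <- if (cand$edge_type[i] == "ppi" ||
               grepl("^mirna_", cand$edge_type[i])) reg * y else reg
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
      abs(stats::cor(x, y))
    }, numeric(1L))
    keepIdx <- order(-score, cand$regulator_id)[seq_len(cap)]
    lost <- cand[-keepIdx, , drop = FALSE]
    drop <- drop | edKey %in% paste(lost$regulator_id, tg, lost$edge_type)
  }
  if (!any(drop) && !net@capped) return(net)
  CandidateGWGEN(networkNodes(net), ed[!drop, , drop = FALSE], capped = TRUE)
}
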