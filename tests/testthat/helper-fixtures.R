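# In-code fixtures shared across test files.

# Tiny typed node table + expression matrix for hand-built regression tests.
tinyNodes <- function() {
  data.frame(
    node_id = c("P001", "P002", "TF001", "TF002", "LNC001", "MIR001",
                "G001"),
    kind = c("protein", "protein", "TF", "TF", "lncRNA", "miRNA", "gene"),
    stringsAsFactors = FALSE)
}

tinyData <- function(values) {
  nodes <- tinyNodes()
  m <- matrix(0, nrow(nodes), ncol = length(values[[1L]]),
              dimnames = list(nodes$node_id, NULL))
  for (id in names(values)) m[id, ] <- values[[id]]
  ExpressionDataset(m, kind = stats::setNames(nodes$kind, nodes$node_id))
}

# Assemble a RealGWGEN directly from an ability edge list (for PNP tests).
makeRealGWGEN <- function(nodes, edges) {
  models <- list()
  for (tg in unique(edges$target_id)) {
    rows <- edges[edges$target_id == tg, , drop = FALSE]
    rows <- rows[order(rows$source_id), , drop = FALSE]
    models[[tg]] <- methods::new(
      "NodeModel", nodeId = tg, regulators = rows$source_id,
      abilities = stats::setNames(rows$ability, rows$source_id),
      edgeTypes = stats::setNames(rows$edge_type, rows$source_id),
      basal = 0, rss = 0, sigma2 = 0, aic = 0, order = nrow(rows),
      orderByKind = stats::setNames(integer(5L),
                                    c("protein", "receptor", "TF",
                                      "lncRNA", "miRNA")))
  }
  ed <- edges
  ed$basal <- 0; ed$aic <- 0; ed$order <- 1L
  methods::new("RealGWGEN", nodes = nodes, models = models, edges = ed)
}

# A small seeded synthetic study reused by several files.
smallStudy <- function(seed = 11, nSamples = 60, noiseSd = 0) {
  gw <- generateCandidateGWGEN(20, 30, 8, 4, trueDensity = 0.08,
                               decoyRatio = 2, seed = seed)
  data <- simulateExpression(gw$truth, nSamples, seed = seed + 100,
                             noiseSd = noiseSd)
  list(gw = gw, data = data)
}
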