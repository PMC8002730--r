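# I/O round trips and the sample-count degree cap.

test_that("expression TSV round trip is lossless", {
  st <- smallStudy(seed = 2, nSamples = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(st$data, path)
  back <- readExpression(path)
  expect_equal(dim(back), dim(st$data))
  expect_lt(max(abs(exprValues(back) - exprValues(st$data))), 1e-12)
  expect_identical(nodeKinds(back), nodeKinds(st$data))
})

test_that("malformed expression files are rejected with row context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_id\tnode_kind\tS1",
               "G001\tgene\t1.5",
               "G001\tgene\t2.0"), path)
  expect_error(readExpression(path), "G001")
  writeLines(c("node_id\tnode_kind\tS1",
               "G001\tgene\tnot_a_number"), path)
  expect_error(readExpression(path), "row 1")
  writeLines(c("node_id\tnode_kind\tS1",
               "G001\tplasmid\t1.0"), path)
  expect_error(readExpression(path), "plasmid")
})

test_that("network TSV round trip preserves the edge set and PPI symmetry", {
  gw <- generateCandidateGWGEN(15, 20, 6, 4, trueDensity = 0.1,
                               decoyRatio = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(gw$candidate, path)
  back <- readNetwork(path)
  expect_setequal(edgeKeys(networkEdges(back)),
                  edgeKeys(networkEdges(gw$candidate)))
  ppi <- networkEdges(back)[networkEdges(back)$edge_type == "ppi", ]
  if (nrow(ppi)) {
    # both orientations queryable
    expect_true(all(paste(ppi$target_id, ppi$source_id) %in%
                      paste(ppi$source_id, ppi$target_id)))
  }
})

test_that("kind-incompatible edges are rejected", {
  nodes <- data.frame(node_id = c("MIR001", "G001"),
                      kind = c("miRNA", "gene"))
  edges <- data.frame(source_id = "MIR001", target_id = "G001",
                      edge_type = "tf_gene")
  expect_error(CandidateGWGEN(nodes, edges), "incompatible")
  edges$edge_type <- "mirna_gene"
  expect_s4_class(CandidateGWGEN(nodes, edges), "CandidateGWGEN")
})

test_that("identified-network TSV round trip reconstructs edges and models", {
  st <- smallStudy(seed = 5, nSamples = 40)
  real <- identifyGWGEN(st$gw$candidate, st$data)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRealGWGEN(real, path)
  back <- readRealGWGEN(path)
  expect_setequal(edgeKeys(networkEdges(back)),
                  edgeKeys(networkEdges(real)))
  ab0 <- networkEdges(real)$ability[order(edgeKeys(networkEdges(real)))]
  ab1 <- networkEdges(back)$ability[order(edgeKeys(networkEdges(back)))]
  expect_equal(ab1, ab0, tolerance = 1e-12)
})

test_that("degree cap keeps every equation under the sample count", {
  # node with 10 candidate regulators, 5 samples -> at most 3 kept
  nodes <- data.frame(
    node_id = c(sprintf("TF%03d", 1:10), "G001"),
    kind = c(rep("TF", 10), "gene"))
  edges <- data.frame(source_id = sprintf("TF%03d", 1:10),
                      target_id = "G001", edge_type = "tf_gene")
  net <- CandidateGWGEN(nodes, edges)
  m <- matrix(rlnorm(11 * 5), 11, 5, dimnames = list(nodes$node_id, NULL))
  data <- ExpressionDataset(m, stats::setNames(nodes$kind, nodes$node_id))
  capped <- applyDegreeCap(net, data)
  expect_lte(nrow(candidateRegulators(capped, "G001")), 3L)
  expect_error(applyDegreeCap(net, data, nSamples = 2), "nSamples < 3")
})

test_that("capping keeps the top candidates by absolute correlation", {
  set.seed(99)
  nTF <- 12; n <- 8
  nodes <- data.frame(node_id = c(sprintf("TF%03d", 1:nTF), "G001"),
                      kind = c(rep("TF", nTF), "gene"))
  edges <- data.frame(source_id = sprintf("TF%03d", 1:nTF),
                      target_id = "G001", edge_type = "tf_gene")
  net <- CandidateGWGEN(nodes, edges)
  m <- matrix(rlnorm((nTF + 1) * n), nTF + 1, n,
              dimnames = list(nodes$node_id, NULL))
  data <- ExpressionDataset(m, stats::setNames(nodes$kind, nodes$node_id))
  capped <- applyDegreeCap(net, data)
  kept <- candidateRegulators(capped, "G001")$regulator_id
  # brute-force correlation ranking oracle
  y <- m["G001", ]
  sc <- sapply(sprintf("TF%03d", 1:nTF), function(id) abs(cor(m[id, ], y)))
  oracle <- names(sort(sc, decreasing = TRUE))[seq_len(n - 2)]
  expect_setequal(kept, oracle)
})

test_that("a network already under the cap is returned unchanged", {
  st <- smallStudy(seed = 8, nSamples = 50)
  capped <- applyDegreeCap(st$gw$candidate, st$data)
  expect_identical(networkEdges(capped), networkEdges(st$gw$candidate))
})

test_that("the cap holds for all equations of a dense network", {
  gw <- generateCandidateGWGEN(20, 25, 10, 4, trueDensity = 0.3,
                               decoyRatio = 1, seed = 21)
  data <- simulateExpression(gw$truth, 12, seed = 22)
  capped <- applyDegreeCap(gw$candidate, data)
  nd <- networkNodes(capped)
  for (tg in nd$node_id[nd$kind %in% c("protein", "gene", "lncRNA", "miRNA")])
    expect_lt(nrow(candidateRegulators(capped, tg)) + 1L, 12)
})

test_that("drug catalog and signature files round trip", {
  cat <- makeDrugCatalogFixture(c("G001", "G002"), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  writeDrugCatalog(cat, path)
  back <- readDrugCatalog(path)
  expect_equal(back@table$connectivity_score, cat@table$connectivity_score,
               tolerance = 1e-12)
  sig <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_id\tdirection", "G001\tup", "G002\tdown"), sig)
  expect_identical(readSignature(sig), c(G001 = "up", G002 = "down"))
})
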