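# Principal network projection: W assembly, SVD energy, projection scores,
# core extraction.

pnpNodes <- function() {
  data.frame(
    node_id = c("TF001", "TF002", "MIR001", "G001", "G002", "LNC001"),
    kind = c("TF", "TF", "miRNA", "gene", "gene", "lncRNA"))
}

test_that("the combined matrix places each ability exactly once in its block", {
  nodes <- pnpNodes()
  edges <- data.frame(
    source_id = c("TF001", "TF002", "MIR001"),
    target_id = c("G001", "G002", "G001"),
    edge_type = c("tf_gene", "tf_gene", "mirna_gene"),
    ability = c(0.7, -0.4, -0.2))
  cm <- buildCombinedMatrix(makeRealGWGEN(nodes, edges))
  W <- as.matrix(cm@W)
  expect_equal(W["G001", "TF001"], 0.7)
  expect_equal(W["G002", "TF002"], -0.4)
  expect_equal(W["G001", "MIR001"], -0.2)
  expect_equal(sum(W != 0), 3L)
  # nonzero multiset equals the ability multiset
  expect_setequal(W[W != 0], edges$ability)
  # rows are target-capable kinds, columns regulator-capable kinds
  expect_true(all(cm@rowKinds %in% c("protein", "gene", "lncRNA", "miRNA")))
  expect_true(all(cm@colKinds %in% c("protein", "receptor", "TF", "lncRNA",
                                     "miRNA")))
  empty <- makeRealGWGEN(nodes, edges)
  empty@edges <- empty@edges[0, ]
  expect_error(buildCombinedMatrix(empty), "empty")
})

test_that("the SVD reconstructs W and sorts singular values descending", {
  set.seed(12)
  st <- smallStudy(seed = 12, nSamples = 50)
  real <- identifyGWGEN(st$gw$candidate, st$data)
  cm <- buildCombinedMatrix(real)
  dec <- decomposeNetwork(cm)
  W <- as.matrix(cm@W)
  rec <- dec$Tmat %*% diag(dec$d, length(dec$d)) %*% t(dec$Hmat)
  expect_lt(norm(W - rec, "F"), 1e-10 * norm(W, "F"))
  expect_true(all(diff(dec$d) <= 1e-12))
  # diagonal example
  diagRG <- makeRealGWGEN(
    pnpNodes(),
    data.frame(source_id = c("TF001", "TF002"),
               target_id = c("G001", "G002"),
               edge_type = "tf_gene", ability = c(3, 1)))
  d <- decomposeNetwork(buildCombinedMatrix(diagRG))$d
  expect_equal(d[1:2], c(3, 1))
})

test_that("eigenexpression fractions are energy shares summing to one", {
  expect_equal(eigenexpressionFractions(c(2, 0, 0)), c(1, 0, 0))
  expect_equal(eigenexpressionFractions(c(3, 1)), c(0.9, 0.1))
  set.seed(4)
  d <- sort(abs(rnorm(10)), decreasing = TRUE)
  E <- eigenexpressionFractions(d)
  oracle <- vapply(seq_along(d), function(s) d[s]^2 / sum(d^2), numeric(1))
  expect_lt(max(abs(E - oracle)), 1e-14)
  expect_equal(sum(E), 1, tolerance = 1e-12)
  expect_error(eigenexpressionFractions(c(0, 0)), "zero")
})

test_that("the selected rank is minimal for the energy threshold", {
  expect_identical(selectRank(c(0.9, 0.1), 0.85), 1L)
  expect_identical(selectRank(rep(0.25, 4), 0.85), 4L)
  E <- eigenexpressionFractions(c(3, 2, 1, 0.5))
  expect_identical(selectRank(E, 1.0), 4L)
  # rank-1 matrix: a single component carries all the energy
  rg <- makeRealGWGEN(
    pnpNodes(),
    data.frame(source_id = c("TF001", "TF001"),
               target_id = c("G001", "G002"),
               edge_type = "tf_gene", ability = c(1, 2)))
  E1 <- eigenexpressionFractions(decomposeNetwork(buildCombinedMatrix(rg))$d)
  expect_equal(E1[1L], 1, tolerance = 1e-12)
})

test_that("projection scores obey Parseval and grow with the rank", {
  st <- smallStudy(seed = 33, nSamples = 50)
  real <- identifyGWGEN(st$gw$candidate, st$data)
  cm <- buildCombinedMatrix(real)
  dec <- decomposeNetwork(cm)
  W <- as.matrix(cm@W)
  full <- length(dec$d[dec$d > 1e-12])
  pr <- projectionScores(cm, dec, S = length(dec$d))
  expect_lt(max(abs(pr@Qdown - sqrt(colSums(W^2)))), 1e-8)
  expect_lt(max(abs(pr@Qup - sqrt(rowSums(W^2)))), 1e-8)
  expect_lt(abs(sum(pr@Qdown^2) - norm(W, "F")^2), 1e-8)
  expect_true(all(pr@Qdown >= 0) && all(pr@Qup >= 0))
  # monotone non-decreasing in S
  prev <- rep(0, ncol(W))
  for (S in seq_len(full)) {
    q <- projectionScores(cm, dec, S = S)@Qdown
    expect_true(all(q - prev >= -1e-10))
    prev <- q
  }
  # an all-zero column is insignificant
  zeroCols <- colnames(W)[colSums(abs(W)) == 0]
  if (length(zeroCols)) expect_true(all(pr@Qdown[zeroCols] == 0))
})

test_that("projection scores are invariant to node order", {
  st <- smallStudy(seed = 41, nSamples = 50)
  real <- identifyGWGEN(st$gw$candidate, st$data)
  proj1 <- projectNetwork(real)
  perm <- real
  set.seed(1)
  perm@nodes <- perm@nodes[sample(nrow(perm@nodes)), ]
  perm@edges <- perm@edges[sample(nrow(perm@edges)), ]
  proj2 <- projectNetwork(perm)
  ids <- names(proj1@Qdown)
  expect_equal(proj2@Qdown[ids], proj1@Qdown[ids], tolerance = 1e-10)
  expect_equal(proj2@Qup[names(proj1@Qup)], proj1@Qup, tolerance = 1e-10)
})

test_that("core extraction keeps the top-scored nodes with induced edges", {
  st <- smallStudy(seed = 47, nSamples = 50)
  real <- identifyGWGEN(st$gw$candidate, st$data)
  proj <- projectNetwork(real)
  whole <- extractCore(real, proj, topK = 10000)
  expect_identical(nrow(whole@nodes), nrow(networkNodes(real)))
  core3 <- extractCore(real, proj, topK = 3)
  # independent sort oracle over max(upstream, downstream)
  all <- networkNodes(real)$node_id
  sc <- pmax(proj@Qdown[all], proj@Qup[all], na.rm = TRUE)
  sc[is.na(sc)] <- 0
  oracle <- names(sort(sc, decreasing = TRUE))
  expect_setequal(core3@nodes$node_id,
                  utils::head(oracle[order(-sc[oracle], oracle)], 3))
  ed <- core3@edges
  expect_true(all(ed$source_id %in% core3@nodes$node_id))
  expect_true(all(ed$target_id %in% core3@nodes$node_id))
})

test_that("high-ability hubs of the planted network land in the core", {
  gw <- generateCandidateGWGEN(30, 60, 12, 6, trueDensity = 0.1,
                               decoyRatio = 1, seed = 53)
  data <- simulateExpression(gw$truth, 60, seed = 54)
  real <- identifyGWGEN(applyDegreeCap(gw$candidate, data), data)
  proj <- projectNetwork(real)
  n <- nrow(networkNodes(real))
  core <- extractCore(real, proj, topK = ceiling(0.25 * n))
  tr <- trueEdges(gw$truth)
  # hub strength: summed |ability| over a node's planted edges (either role)
  strength <- tapply(abs(tr$ability), tr$target_id, sum)
  src <- tapply(abs(tr$ability), tr$source_id, sum)
  for (id in names(src))
    strength[id] <- max(strength[id], src[id], na.rm = TRUE)
  hubs <- names(strength)[strength >= stats::quantile(strength, 0.9)]
  expect_gte(mean(hubs %in% core@nodes$node_id), 0.9)
})
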