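# Synthetic-data module: planted networks and model-consistent samples.

test_that("candidate network contains the planted edges plus the requested decoys", {
  noDecoy <- generateCandidateGWGEN(20, 30, 8, 4, trueDensity = 0.08,
                                    decoyRatio = 0, seed = 5)
  candKeys <- edgeKeys(networkEdges(noDecoy$candidate))
  trueKeys <- edgeKeys(trueEdges(noDecoy$truth))
  expect_setequal(unique(candKeys), trueKeys)

  withDecoys <- generateCandidateGWGEN(20, 30, 8, 4, trueDensity = 0.08,
                                       decoyRatio = 2, seed = 5)
  ck <- unique(edgeKeys(networkEdges(withDecoys$candidate)))
  tk <- edgeKeys(trueEdges(withDecoys$truth))
  expect_true(all(tk %in% ck))
  expect_equal(length(ck), length(tk) + round(2 * length(tk)))
  expect_identical(tk, trueKeys)  # decoys do not disturb the truth draw
})

test_that("generation is deterministic given the seed", {
  a <- generateCandidateGWGEN(15, 20, 6, 4, trueDensity = 0.1,
                              decoyRatio = 1.5, seed = 42)
  b <- generateCandidateGWGEN(15, 20, 6, 4, trueDensity = 0.1,
                              decoyRatio = 1.5, seed = 42)
  expect_identical(networkEdges(a$candidate), networkEdges(b$candidate))
  expect_identical(a$truth@coef, b$truth@coef)
  expect_identical(a$truth@basal, b$truth@basal)
  dA <- simulateExpression(a$truth, 25, seed = 9)
  dB <- simulateExpression(b$truth, 25, seed = 9)
  expect_identical(exprValues(dA), exprValues(dB))
})

test_that("an infeasible decoy ratio is reported as a parameter error", {
  expect_error(
    generateCandidateGWGEN(10, 10, 4, 2, trueDensity = 0.5,
                           decoyRatio = 50, seed = 1),
    "parameter error")
})

test_that("generated edges always satisfy the regulator/target kind rules", {
  srcKind <- c(tf_gene = "TF", tf_lncrna = "TF", tf_mirna = "TF",
               lncrna_gene = "lncRNA", lncrna_lncrna = "lncRNA",
               lncrna_mirna = "lncRNA", mirna_gene = "miRNA",
               mirna_lncrna = "miRNA", mirna_mirna = "miRNA")
  tgtKind <- c(tf_gene = "gene", tf_lncrna = "lncRNA", tf_mirna = "miRNA",
               lncrna_gene = "gene", lncrna_lncrna = "lncRNA",
               lncrna_mirna = "miRNA", mirna_gene = "gene",
               mirna_lncrna = "lncRNA", mirna_mirna = "miRNA")
  for (seed in 1:3) {
    gw <- generateCandidateGWGEN(20, 25, 9, 5, trueDensity = 0.1,
                                 decoyRatio = 2, seed = seed)
    ed <- networkEdges(gw$candidate)
    kind <- stats::setNames(networkNodes(gw$candidate)$kind,
                            networkNodes(gw$candidate)$node_id)
    dir <- ed[ed$edge_type != "ppi", ]
    expect_true(all(kind[dir$source_id] == srcKind[dir$edge_type]))
    expect_true(all(kind[dir$target_id] == tgtKind[dir$edge_type]))
    ppi <- ed[ed$edge_type == "ppi", ]
    expect_true(all(kind[ppi$source_id] %in% c("protein", "receptor", "TF")))
    expect_true(all(kind[ppi$target_id] %in% c("protein", "receptor", "TF")))
  }
})

test_that("simulated data satisfy the generating equations exactly at zero noise", {
  for (seed in c(3, 17)) {
    st <- smallStudy(seed = seed, nSamples = 40, noiseSd = 0)
    res <- modelResiduals(st$gw$truth, st$data)
    expect_lt(max(abs(res)), 1e-12)
    expect_true(all(exprValues(st$data)[nodeKinds(st$data) == "miRNA", ] >= 0))
  }
})

test_that("hand-written closed forms of the target models are honoured", {
  nodes <- data.frame(
    node_id = c("TF001", "MIR001", "G001", "G002"),
    kind = c("TF", "miRNA", "gene", "gene"),
    role = c("source", "source", "target", "target"))
  # gene G001 = alpha * t + psi with alpha = 2, psi = 1
  # gene G002 = psi / (1 + gamma * m) with gamma = 1, psi = 4
  truth <- methods::new(
    "GroundTruthModel", nodes = nodes,
    coef = data.frame(
      target_id = c("G001", "G002"), regulator_id = c("TF001", "MIR001"),
      edge_type = c("tf_gene", "mirna_gene"), ability = c(2, -1)),
    basal = c(G001 = 1, G002 = 4), noiseSd = 0)
  m <- matrix(0, 4, 3, dimnames = list(nodes$node_id, NULL))
  m["TF001", ] <- c(1, 2, 3)
  m["MIR001", ] <- c(1, 3, 0)
  m["G001", ] <- 2 * c(1, 2, 3) + 1          # 3 5 7
  m["G002", ] <- 4 / (1 + c(1, 3, 0))        # 2 1 4
  data <- ExpressionDataset(m, stats::setNames(nodes$kind, nodes$node_id))
  expect_lt(max(abs(modelResiduals(truth, data))), 1e-12)
  # and the simulator reproduces the same closed forms on its own draws
  sim <- simulateExpression(truth, 20, seed = 2)
  sm <- exprValues(sim)
  expect_equal(sm["G001", ], 2 * sm["TF001", ] + 1, tolerance = 1e-12)
  expect_equal(sm["G002", ], 4 / (1 + sm["MIR001", ]), tolerance = 1e-12)
})

test_that("refitting each equation on noiseless data leaves no residual", {
  st <- smallStudy(seed = 23, nSamples = 50, noiseSd = 0)
  truthNet <- CandidateGWGEN(
    networkNodes(st$gw$candidate),
    trueEdges(st$gw$truth)[, c("source_id", "target_id", "edge_type")])
  nd <- networkNodes(truthNet)
  for (tg in head(nd$node_id[nd$kind %in% c("protein", "gene")], 20)) {
    prob <- if (nd$kind[nd$node_id == tg] == "protein")
      buildProteinRegression(tg, truthNet, st$data)
    else buildTargetRegression(tg, truthNet, st$data)
    expect_lt(solveLeastSquares(prob)$rss, 1e-16)
  }
})

test_that("noise is honest Gaussian jitter on the basal level", {
  st <- smallStudy(seed = 31, nSamples = 200, noiseSd = 0.05)
  res <- modelResiduals(st$gw$truth, st$data)
  # residual of the generating equation recovers the drawn noise term
  expect_gt(stats::sd(as.numeric(res)), 0.03)
  expect_lt(stats::sd(as.numeric(res)), 0.08)
  expect_lt(abs(mean(res)), 0.02)
})

test_that("condition pairs share a candidate network and the planted overlap", {
  pair <- generateConditionPair(20, 30, 8, 4, trueDensity = 0.08,
                                decoyRatio = 2, sharedTruthFraction = 0.5,
                                seed = 7)
  kA <- edgeKeys(trueEdges(pair$truthA))
  kB <- edgeKeys(trueEdges(pair$truthB))
  candKeys <- unique(edgeKeys(networkEdges(pair$candidate)))
  expect_true(all(kA %in% candKeys))
  expect_true(all(kB %in% candKeys))
  expect_equal(length(kA), length(kB))
  expect_equal(length(intersect(kA, kB)), round(0.5 * length(kA)))

  same <- generateConditionPair(20, 30, 8, 4, trueDensity = 0.08,
                                decoyRatio = 1, sharedTruthFraction = 1,
                                seed = 7)
  expect_identical(same$truthA@coef, same$truthB@coef)
  expect_identical(same$truthA@basal, same$truthB@basal)
})

test_that("the drug catalog fixture has a pass and a fail per target and in-range scores", {
  targets <- c("G001", "G002", "G003")
  cat <- makeDrugCatalogFixture(targets, seed = 13)
  tb <- cat@table
  expect_true(all(abs(tb$connectivity_score) <= 1))
  expect_true(all(tb$ld50_mg_per_kg > 0))
  for (tg in targets) {
    sub <- tb[tb$target == tg, ]
    expect_gte(nrow(sub), 2L)
    pass <- sub$connectivity_score <= -0.5 & sub$ld50_mg_per_kg >= 500
    expect_true(any(pass))
    expect_true(any(!pass))
  }
  one <- makeDrugCatalogFixture("G001", seed = 13)
  expect_gte(length(unique(one@table$drug)), 2L)
})
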