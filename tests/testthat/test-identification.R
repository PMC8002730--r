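# Constrained least squares, AIC order selection and network identification.

test_that("the protein regression uses bilinear partner products plus a basal column", {
  data <- tinyData(list(P001 = c(2, 3), P002 = c(1, 4)))
  nodes <- tinyNodes()
  net <- CandidateGWGEN(nodes, data.frame(
    source_id = "P002", target_id = "P001", edge_type = "ppi"))
  prob <- buildProteinRegression("P001", net, data)
  expect_equal(unname(prob@regressors),
               cbind(c(2 * 1, 3 * 4), c(1, 1)))
  expect_identical(prob@labels, c("P002", "basal"))
  expect_false(any(prob@constrained))

  # zero partners: intercept-only fit returns the mean as basal
  lone <- CandidateGWGEN(nodes, data.frame(source_id = character(0),
                                           target_id = character(0),
                                           edge_type = character(0)))
  fit <- solveLeastSquares(buildProteinRegression("P001", lone, data))
  expect_equal(unname(fit$coef[["basal"]]), mean(c(2, 3)))
})

test_that("the target regression follows the TF, lncRNA, miRNA, basal block order", {
  data <- tinyData(list(TF001 = c(1, 2), MIR001 = c(3, 1), G001 = c(5, 4),
                        LNC001 = c(2, 6)))
  nodes <- tinyNodes()
  net <- CandidateGWGEN(nodes, data.frame(
    source_id = c("TF001", "MIR001"), target_id = "G001",
    edge_type = c("tf_gene", "mirna_gene")))
  prob <- buildTargetRegression("G001", net, data)
  expect_equal(unname(prob@regressors),
               rbind(c(1, 15, 1), c(2, 4, 1)))  # t, g*m, 1
  expect_identical(prob@labels, c("TF001", "MIR001", "basal"))
  expect_identical(prob@constrained, c(FALSE, TRUE, FALSE))

  withLnc <- CandidateGWGEN(nodes, data.frame(
    source_id = c("MIR001", "LNC001", "TF001"), target_id = "G001",
    edge_type = c("mirna_gene", "lncrna_gene", "tf_gene")))
  prob2 <- buildTargetRegression("G001", withLnc, data)
  expect_identical(prob2@labels, c("TF001", "LNC001", "MIR001", "basal"))
  expect_identical(prob2@constrained, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("regression matrices match an element-wise loop oracle", {
  st <- smallStudy(seed = 14, nSamples = 20)
  m <- exprValues(st$data)
  nd <- networkNodes(st$gw$candidate)
  prots <- nd$node_id[nd$kind == "protein"]
  tg <- prots[which.max(vapply(prots, function(p)
    nrow(candidateRegulators(st$gw$candidate, p)), numeric(1L)))]
  prob <- buildProteinRegression(tg, st$gw$candidate, st$data)
  cand <- candidateRegulators(st$gw$candidate, tg)
  oracle <- matrix(0, nrow(prob@regressors), nrow(cand))
  for (n in seq_len(nrow(prob@regressors)))
    for (j in seq_len(nrow(cand)))
      oracle[n, j] <- m[tg, n] * m[cand$regulator_id[j], n]
  expect_equal(unname(prob@regressors[, seq_len(nrow(cand))]), oracle)
})

test_that("unconstrained solutions match the normal-equations oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 30; k <- sample(1:5, 1)
    X <- cbind(matrix(rnorm(n * k), n, k), 1)
    colnames(X) <- c(sprintf("TF%03d", seq_len(k)), "basal")
    y <- rnorm(n)
    prob <- methods::new("RegressionProblem", targetId = "G001",
                         response = y, regressors = X,
                         labels = colnames(X),
                         constrained = rep(FALSE, k + 1L),
                         regulatorKinds = stats::setNames(
                           rep("TF", k), colnames(X)[seq_len(k)]),
                         edgeTypes = stats::setNames(
                           rep("tf_gene", k), colnames(X)[seq_len(k)]))
    fit <- solveLeastSquares(prob)
    oracle <- solve(crossprod(X), crossprod(X, y))
    expect_lt(max(abs(fit$coef - as.numeric(oracle))), 1e-8)
  }
})

test_that("constrained fits satisfy KKT and match the enumeration oracle", {
  set.seed(21)
  for (rep in 1:40) {
    n <- 25
    k <- sample(2:7, 1)
    nNeg <- sample(1:min(3, k), 1)
    neg <- c(rep(FALSE, k - nNeg), rep(TRUE, nNeg), FALSE)
    X <- cbind(matrix(rnorm(n * k), n, k), 1)
    y <- rnorm(n)
    kinds <- ifelse(neg[seq_len(k)], "miRNA", "TF")
    labels <- c(sprintf("X%03d", seq_len(k)), "basal")
    colnames(X) <- labels
    prob <- methods::new("RegressionProblem", targetId = "G001",
                         response = y, regressors = X, labels = labels,
                         constrained = neg,
                         regulatorKinds = stats::setNames(kinds,
                                                          labels[seq_len(k)]),
                         edgeTypes = stats::setNames(
                           ifelse(neg[seq_len(k)], "mirna_gene", "tf_gene"),
                           labels[seq_len(k)]))
    fit <- solveLeastSquares(prob)
    b <- unname(fit$coef)
    expect_true(all(b[neg] <= 1e-10))
    expect_true(kktHolds(X, y, neg, b))
    oracle <- qpOracle(X, y, neg)
    expect_lt(abs(fit$rss - oracle$obj), 1e-8)
  }
})

test_that("a truly positive effect in a constrained slot is clamped to zero", {
  set.seed(3)
  n <- 50
  x <- rlnorm(n)
  y <- 2 * x + rnorm(n, sd = 0.1)   # positive association
  X <- cbind(x, 1)
  colnames(X) <- c("MIR001", "basal")
  prob <- methods::new("RegressionProblem", targetId = "G001",
                       response = y, regressors = X,
                       labels = colnames(X), constrained = c(TRUE, FALSE),
                       regulatorKinds = c(MIR001 = "miRNA"),
                       edgeTypes = c(MIR001 = "mirna_gene"))
  fit <- solveLeastSquares(prob)
  expect_identical(unname(fit$coef[["MIR001"]]), 0)
  # constrained objective is never below the unconstrained one
  free <- prob; free@constrained <- c(FALSE, FALSE)
  expect_gte(fit$rss, solveLeastSquares(free)$rss)
})

test_that("the AIC formula and its degenerate cases behave as documented", {
  expect_equal(computeAIC(rss = 4, n = 4, delta = 2), 1.0)
  aics <- sapply(1:5, function(d) computeAIC(rss = 10, n = 20, delta = d))
  expect_true(all(diff(aics) > 0))
  expect_equal(computeAIC(rss = 0, n = 10, delta = 3),
               log10(1e-12) + 6 / 10)
  expect_lt(computeAIC(rss = 0, n = 10, delta = 1),
            computeAIC(rss = 0, n = 10, delta = 2))
})

test_that("order selection recovers a planted model among decoys on noiseless data", {
  set.seed(5)
  n <- 40
  tfs <- sprintf("TF%03d", 1:5)
  m <- matrix(rlnorm(6 * n), 6, n, dimnames = list(c(tfs, "G001"), NULL))
  m["G001", ] <- 1.5 * m["TF001", ] - 0.8 * m["TF002", ] + 2
  nodes <- data.frame(node_id = c(tfs, "G001"),
                      kind = c(rep("TF", 5), "gene"))
  net <- CandidateGWGEN(nodes, data.frame(source_id = tfs,
                                          target_id = "G001",
                                          edge_type = "tf_gene"))
  data <- ExpressionDataset(m, stats::setNames(nodes$kind, nodes$node_id))
  model <- selectOrder(buildTargetRegression("G001", net, data))
  expect_identical(model@order, 2L)
  expect_setequal(model@regulators, c("TF001", "TF002"))
  expect_equal(unname(model@abilities[c("TF001", "TF002")]), c(1.5, -0.8),
               tolerance = 1e-8)
  expect_equal(model@basal, 2, tolerance = 1e-8)
})

test_that("identification never invents edges and recovers a noiseless planted network", {
  st <- smallStudy(seed = 19, nSamples = 60, noiseSd = 0)
  real <- identifyGWGEN(st$gw$candidate, st$data)
  expect_true(all(edgeKeys(networkEdges(real)) %in%
                    edgeKeys(networkEdges(st$gw$candidate))))
  rec <- evaluateRecovery(real, st$gw$truth)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  expect_lt(rec$maxAbilityError, 1e-8)
  # every reported miRNA-slot coefficient is non-positive
  ed <- networkEdges(real)
  mi <- grepl("^mirna_", ed$edge_type)
  expect_true(all(ed$ability[mi] <= 0))
})

test_that("parameter error shrinks as the noise level falls", {
  errAt <- function(sd) {
    st <- smallStudy(seed = 29, nSamples = 80, noiseSd = 0)
    sdv <- if (sd > 0) sd * signalSd(st$gw$truth, 80, seed = 129) else 0
    data <- simulateExpression(st$gw$truth, 80, seed = 129, noiseSd = sdv)
    real <- identifyGWGEN(applyDegreeCap(st$gw$candidate, data), data)
    evaluateRecovery(real, st$gw$truth)$maxAbilityError
  }
  errs <- c(errAt(0.1), errAt(0.01), errAt(0))
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[3], 1e-8)
})
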