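## Pipeline module: simulate -> cap -> identify -> project -> compare ->
## drugs, with config validation, per-stage error context and a
## reproducible JSON run manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the package defaults: a
#' two-condition synthetic study (50 proteins, 100 genes, 20 miRNAs, 5
#' lncRNAs; candidate network at decoy ratio 2; 80 samples per condition;
#' noiseless), identification with the common-log AIC, projection at the
#' 0.85 energy threshold with a top-2000 core, and drug filters at
#' |score| >= 0.5 and LD50 >= 500 mg/kg.
#'
#' @return named list of configuration values.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    outdir = "gwgenet-run",
    n_proteins = 50L, n_genes = 100L, n_mirnas = 20L, n_lncrnas = 5L,
    true_density = 0.05, decoy_ratio = 2,
    shared_truth_fraction = 0.5,
    n_samples = 80L,
    noise_sd = 0,            # absolute noise sd (per-target Gaussian)
    noise_relative = 0,      # if > 0, noise sd = this x per-target signal sd
    condition_a = "caseA", condition_b = "caseB",
    aic_base = 10, aic_floor = 1e-12,
    pnp_threshold = 0.85, top_k = 2000L,
    min_abs_score = 0.5, min_ld50 = 500,
    biomarker_count = 5L,
    biomarkers = NULL,       # optional explicit biomarker node ids
    drug_catalog = NULL)     # optional catalog file; default: fixture
}

.validateConfig <- function(config) {
  base <- defaultPipelineConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(base, config, keep.null = TRUE)
  .assertFraction(cfg$pnp_threshold, "pnp_threshold", loOpen = TRUE)
  .assertFraction(cfg$shared_truth_fraction, "shared_truth_fraction")
  .assertFraction(cfg$min_abs_score, "min_abs_score")
  .assertCount(cfg$top_k, "top_k")
  .assertCount(cfg$n_samples, "n_samples", min = 3L)
  if (cfg$noise_sd < 0 || cfg$noise_relative < 0)
    stop("noise levels must be >= 0")
  cfg
}

.stage <- function(name, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)),
    message = function(m) invokeRestart("muffleMessage"))
}

#' Run the full systems-medicine pipeline on a synthetic condition pair
#'
#' Executes, in order: synthetic study generation (shared candidate GWGEN
#' with planted per-condition truths and model-consistent expression
#' samples), degree capping, per-condition identification, principal
#' network projection and core extraction, core comparison with direction
#' labels, and signature-reversal drug design.  All stage outputs are
#' written under `config$outdir` together with a JSON run manifest; reruns
#' with the same configuration are byte-identical.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or the
#'   path to a YAML file of overrides.  Unknown keys are rejected.
#' @return (invisibly) a list with all intermediate objects: `candidate`,
#'   `truthA/B`, `dataA/B`, `realA/B`, `projA/B`, `coreA/B`, `comparison`,
#'   `signature`, `catalog`, `proposal`, `recoveryA/B`, `manifest`.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- .validateConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(cfg$outdir, ...)

  sim <- .stage("simulate", {
    pair <- generateConditionPair(
      cfg$n_proteins, cfg$n_genes, cfg$n_mirnas, cfg$n_lncrnas,
      trueDensity = cfg$true_density, decoyRatio = cfg$decoy_ratio,
      sharedTruthFraction = cfg$shared_truth_fraction,
      noiseSd = cfg$noise_sd, seed = cfg$seed)
    sdFor <- function(truth, seedOff) {
      if (cfg$noise_relative > 0)
        cfg$noise_relative * signalSd(truth, cfg$n_samples,
                                      cfg$seed + seedOff)
      else cfg$noise_sd
    }
    dataA <- simulateExpression(pair$truthA, cfg$n_samples,
                                seed = cfg$seed + 1L,
                                noiseSd = sdFor(pair$truthA, 1L),
                                condition = cfg$condition_a)
    dataB <- simulateExpression(pair$truthB, cfg$n_samples,
                                seed = cfg$seed + 2L,
                                noiseSd = sdFor(pair$truthB, 2L),
                                condition = cfg$condition_b)
    writeExpression(dataA, pth("expression_a.tsv"))
    writeExpression(dataB, pth("expression_b.tsv"))
    writeNetwork(pair$candidate, pth("candidate_network.tsv"))
    writeNetwork(pair$candidate, pth("truth_a.tsv"), truth = pair$truthA,
                 nodesPath = pth("truth_a_nodes.tsv"))
    writeNetwork(pair$candidate, pth("truth_b.tsv"), truth = pair$truthB,
                 nodesPath = pth("truth_b_nodes.tsv"))
    list(pair = pair, dataA = dataA, dataB = dataB)
  })

  cappedA <- .stage("cap", applyDegreeCap(sim$pair$candidate, sim$dataA,
                                          cfg$n_samples))
  cappedB <- .stage("cap", applyDegreeCap(sim$pair$candidate, sim$dataB,
                                          cfg$n_samples))

  realA <- .stage("identify",
                  identifyGWGEN(cappedA, sim$dataA, base = cfg$aic_base,
                                floor = cfg$aic_floor))
  realB <- .stage("identify",
                  identifyGWGEN(cappedB, sim$dataB, base = cfg$aic_base,
                                floor = cfg$aic_floor))
  writeRealGWGEN(realA, pth("identified_a.tsv"))
  writeRealGWGEN(realB, pth("identified_b.tsv"))

  pnpA <- .stage("pnp", {
    proj <- projectNetwork(realA, threshold = cfg$pnp_threshold)
    list(proj = proj, core = extractCore(realA, proj, topK = cfg$top_k))
  })
  pnpB <- .stage("pnp", {
    proj <- projectNetwork(realB, threshold = cfg$pnp_threshold)
    list(proj = proj, core = extractCore(realB, proj, topK = cfg$top_k))
  })
  writeCore(pnpA$core, pth("core_a.tsv"))
  writeCore(pnpB$core, pth("core_b.tsv"))

  cmp <- .stage("compare", {
    rep <- compareCores(pnpA$core, pnpB$core, cfg$condition_a,
                        cfg$condition_b)
    dir <- directionLabels(pnpA$core, sim$dataA, sim$dataB)
    rep <- withDirections(rep, dir)
    writeComparison(rep, pth("comparison.json"), pth("comparison_nodes.tsv"))
    rep
  })

  drugs <- .stage("drugs", {
    biomarkers <- cfg$biomarkers
    if (is.null(biomarkers)) {
      pool <- cmp@commonNodes
      nodesA <- pnpA$core@nodes
      genes <- nodesA[nodesA$node_id %in% pool & nodesA$kind == "gene", ,
                      drop = FALSE]
      if (!nrow(genes))
        genes <- nodesA[nodesA$node_id %in% pool, , drop = FALSE]
      biomarkers <- utils::head(genes$node_id[order(-genes$score,
                                                    genes$node_id)],
                                cfg$biomarker_count)
    }
    if (!length(biomarkers)) stop("no biomarker targets available")
    sigAll <- directionLabels(pnpA$core, sim$dataA, sim$dataB)
    signature <- sigAll[biomarkers]
    signature[is.na(signature) | signature == "unknown"] <- "up"
    names(signature) <- biomarkers
    catalog <- if (!is.null(cfg$drug_catalog))
      readDrugCatalog(cfg$drug_catalog)
    else
      makeDrugCatalogFixture(biomarkers, seed = cfg$seed + 3L,
                             directions = signature)
    writeDrugCatalog(catalog, pth("drug_catalog.csv"))
    proposal <- designDrugs(catalog, signature,
                            minAbsScore = cfg$min_abs_score,
                            minLd50 = cfg$min_ld50)
    writeProposal(proposal, pth("drug_proposal.tsv"))
    utils::write.table(
      data.frame(node_id = names(signature), direction = unname(signature)),
      pth("signature.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    list(signature = signature, catalog = catalog, proposal = proposal)
  })

  recoveryA <- evaluateRecovery(realA, sim$pair$truthA)
  recoveryB <- evaluateRecovery(realB, sim$pair$truthB)
  manifest <- list(
    package = "GWGENet",
    version = as.character(utils::packageVersion("GWGENet")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("outdir"))],
    outputs = c("expression_a.tsv", "expression_b.tsv",
                "candidate_network.tsv", "truth_a.tsv", "truth_b.tsv",
                "identified_a.tsv", "identified_b.tsv", "core_a.tsv",
                "core_b.tsv", "comparison.json", "comparison_nodes.tsv",
                "signature.tsv", "drug_catalog.csv", "drug_proposal.tsv",
                "manifest.json"),
    stats = list(
      n_candidate_edges = length(.edgeKey(networkEdges(sim$pair$candidate))),
      n_identified_edges_a = nrow(networkEdges(realA)),
      n_identified_edges_b = nrow(networkEdges(realB)),
      recovery_a = recoveryA, recovery_b = recoveryB,
      selected_rank_a = pnpA$proj@S, selected_rank_b = pnpB$proj@S,
      n_common_core_nodes = length(cmp@commonNodes),
      proposed_drugs = drugs$proposal@drugs,
      uncovered_targets = drugs$proposal@uncovered))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  invisible(list(candidate = sim$pair$candidate, truthA = sim$pair$truthA,
                 truthB = sim$pair$truthB, dataA = sim$dataA,
                 dataB = sim$dataB, cappedA = cappedA, cappedB = cappedB,
                 realA = realA, realB = realB, projA = pnpA$proj,
                 projB = pnpB$proj, coreA = pnpA$core, coreB = pnpB$core,
                 comparison = cmp, signature = drugs$signature,
                 catalog = drugs$catalog, proposal = drugs$proposal,
                 recoveryA = recoveryA, recoveryB = recoveryB,
                 manifest = manifest))
}
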