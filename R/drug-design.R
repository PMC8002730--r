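## Drug-design module: signature-reversal filtering by connectivity score
## sign, toxicity filtering by predicted LD50, and greedy assembly of a
## minimal multi-molecule drug set covering all biomarker targets.

#' Filter a drug catalog by regulation ability (signature reversal)
#'
#' A drug is a candidate for a biomarker when its connectivity score
#' opposes the biomarker's abnormal direction: an upregulated biomarker
#' needs a negatively correlated (reversing) drug, a downregulated one a
#' positively correlated drug.  Entries must also reach `minAbsScore` in
#' magnitude.  Each per-target candidate list is sorted by |score|
#' descending.
#'
#' @param catalog a [DrugCatalog][DrugCatalog-class].
#' @param signature named character vector of biomarker directions
#'   (`up`/`down`).
#' @param minAbsScore minimum |connectivity score| in \[0, 1\]
#'   (default 0.5).
#' @return named list (one data.frame per biomarker target).  Targets
#'   absent from the catalog yield an empty frame with a warning.
#' @export
filterByRegulation <- function(catalog, signature, minAbsScore = 0.5) {
  stopifnot(methods::is(catalog, "DrugCatalog"))
  minAbsScore <- .assertFraction(minAbsScore, "minAbsScore")
  if (!length(signature) || is.null(names(signature)))
    stop("'signature' must be a non-empty named direction vector")
  bad <- setdiff(unique(signature), c("up", "down"))
  if (length(bad))
    stop(sprintf("unknown direction(s): %s", paste(bad, collapse = ", ")))
  tb <- catalog@table
  out <- list()
  for (tg in names(signature)) {
    rows <- tb[tb$target == tg, , drop = FALSE]
    if (!nrow(rows)) {
      warning(sprintf("target '%s' absent from the drug catalog", tg))
      out[[tg]] <- rows
      next
    }
    sc <- rows$connectivity_score
    keep <- if (signature[[tg]] == "up") sc <= -minAbsScore
            else sc >= minAbsScore
    rows <- rows[keep, , drop = FALSE]
    rows <- rows[order(-abs(rows$connectivity_score), rows$drug), ,
                 drop = FALSE]
    rownames(rows) <- NULL
    out[[tg]] <- rows
  }
  out
}

#' Filter candidates by toxicity (predicted LD50)
#'
#' Keeps entries with predicted LD50 at least `minLd50` mg/kg (a higher
#' median lethal dose means lower acute toxicity); the bound is closed, so
#' a drug exactly at the threshold survives.
#'
#' @param candidates per-target candidate list from [filterByRegulation()]
#'   (or a single data.frame with an `ld50_mg_per_kg` column).
#' @param minLd50 minimum predicted LD50 in mg/kg, >= 0 (default 500).
#' @return the filtered candidates, same shape as the input.
#' @export
filterByToxicity <- function(candidates, minLd50 = 500) {
  if (!is.numeric(minLd50) || minLd50 < 0)
    stop("'minLd50' must be >= 0")
  filt <- function(df) {
    df <- df[df$ld50_mg_per_kg >= minLd50, , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  if (is.data.frame(candidates)) filt(candidates)
  else lapply(candidates, filt)
}

#' Assemble a minimal multi-molecule drug proposal
#'
#' Greedy weighted set cover over the surviving (drug, target) pairs:
#' repeatedly select the drug covering the most still-uncovered biomarkers,
#' breaking ties by larger summed |connectivity score| over the newly
#' covered targets, then larger mean LD50, then lexicographic drug name;
#' stops when every biomarker is covered or no drug adds coverage.
#' Biomarkers no surviving drug can cover are reported in `uncovered`
#' rather than treated as an error.
#'
#' @param candidates per-target candidate lists (after both filters).
#' @return A [MultiDrugProposal][MultiDrugProposal-class].
#' @export
assembleMultiDrug <- function(candidates) {
  if (!is.list(candidates) || is.data.frame(candidates))
    stop("'candidates' must be a named list of per-target tables")
  targets <- names(candidates)
  pairs <- do.call(rbind, c(lapply(targets, function(tg) {
    df <- candidates[[tg]]
    if (!nrow(df)) return(NULL)
    data.frame(drug = df$drug, target = tg,
               connectivity_score = df$connectivity_score,
               ld50_mg_per_kg = df$ld50_mg_per_kg,
               stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
  if (is.null(pairs))
    pairs <- data.frame(drug = character(0), target = character(0),
                        connectivity_score = numeric(0),
                        ld50_mg_per_kg = numeric(0))
  uncovered <- targets
  selected <- character(0)
  while (length(uncovered)) {
    live <- pairs[pairs$target %in% uncovered &
                    !pairs$drug %in% selected, , drop = FALSE]
    if (!nrow(live)) break
    stats <- do.call(rbind, lapply(split(live, live$drug), function(df) {
      data.frame(drug = df$drug[1L], n = nrow(df),
                 scoreSum = sum(abs(df$connectivity_score)),
                 ld50 = mean(df$ld50_mg_per_kg),
                 stringsAsFactors = FALSE)
    }))
    stats <- stats[order(-stats$n, -stats$scoreSum, -stats$ld50,
                         stats$drug), , drop = FALSE]
    pick <- stats$drug[1L]
    selected <- c(selected, pick)
    uncovered <- setdiff(uncovered, pairs$target[pairs$drug == pick])
  }
  details <- pairs[pairs$drug %in% selected, , drop = FALSE]
  details <- details[order(match(details$drug, selected), details$target), ,
                     drop = FALSE]
  rownames(details) <- NULL
  coverage <- matrix(FALSE, length(selected), length(targets),
                     dimnames = list(selected, targets))
  for (i in seq_len(nrow(details)))
    coverage[details$drug[i], details$target[i]] <- TRUE
  methods::new("MultiDrugProposal", drugs = selected, coverage = coverage,
               details = details, uncovered = sort(uncovered))
}

#' Full drug-design pass
#'
#' Applies the regulation-ability and toxicity filters and assembles the
#' multi-molecule proposal in one call.
#'
#' @inheritParams filterByRegulation
#' @inheritParams filterByToxicity
#' @return A [MultiDrugProposal][MultiDrugProposal-class].
#' @export
designDrugs <- function(catalog, signature, minAbsScore = 0.5,
                        minLd50 = 500) {
  cand <- filterByRegulation(catalog, signature, minAbsScore)
  cand <- filterByToxicity(cand, minLd50)
  assembleMultiDrug(cand)
}

setMethod("show", "MultiDrugProposal", function(object) {
  cat(sprintf("MultiDrugProposal: %d drug(s) covering %d/%d target(s)\n",
              length(object@drugs),
              ncol(object@coverage) - length(object@uncovered),
              ncol(object@coverage)))
  if (length(object@drugs)) {
    mat <- ifelse(object@coverage, "x", ".")
    print(as.data.frame(mat))
  }
  if (length(object@uncovered))
    cat("  uncovered:", paste(object@uncovered, collapse = ", "), "\n")
})

setMethod("show", "DrugCatalog", function(object) {
  cat(sprintf("DrugCatalog: %d (drug, target) pairs, %d drugs, %d targets\n",
              nrow(object@table), length(unique(object@table$drug)),
              length(unique(object@table$target))))
})

#' Write a multi-drug proposal
#'
#' Writes the proposal table (drug, targets covered, scores, LD50) and the
#' drug-by-target 0/1 coverage matrix.
#'
#' @param proposal a [MultiDrugProposal][MultiDrugProposal-class].
#' @param path proposal TSV path; the coverage matrix goes to
#'   `<stem>_matrix.tsv`.
#' @export
writeProposal <- function(proposal, path) {
  stopifnot(methods::is(proposal, "MultiDrugProposal"))
  det <- proposal@details
  rows <- lapply(proposal@drugs, function(d) {
    sub <- det[det$drug == d, , drop = FALSE]
    data.frame(drug = d,
               targets_covered = paste(sub$target, collapse = ","),
               connectivity_scores = paste(.fmtNum(sub$connectivity_score),
                                           collapse = ","),
               ld50_mg_per_kg = .fmtNum(sub$ld50_mg_per_kg[1L]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug = character(0), targets_covered = character(0),
               connectivity_scores = character(0),
               ld50_mg_per_kg = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mat <- data.frame(drug = rownames(proposal@coverage),
                    proposal@coverage + 0L, check.names = FALSE)
  utils::write.table(mat, sub("(\\.[^.]+)?$", "_matrix.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
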