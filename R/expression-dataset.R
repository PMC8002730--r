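#' Construct an ExpressionDataset
#'
#' Bundles a node-by-sample matrix of expression levels with node kinds and
#' an optional condition label into an
#' [ExpressionDataset][ExpressionDataset-class].
#'
#' @param expr numeric matrix, nodes in rows (rownames = node ids), samples
#'   in columns.  Column names default to `S1, S2, ...`.
#' @param kind character vector of node kinds (one of [gwgenNodeKinds()]),
#'   parallel to the rows of `expr`, or a named vector covering all row
#'   names.
#' @param condition optional condition label (e.g. `"TNBC"`).
#'
#' @return An `ExpressionDataset`.
#' @examples
#' m <- matrix(rlnorm(6), 3, 2,
#'             dimnames = list(c("TF01", "G001", "G002"), NULL))
#' ExpressionDataset(m, kind = c("TF", "gene", "gene"), condition = "case")
#' @export
ExpressionDataset <- function(expr, kind, condition = NA_character_) {
  if (is.null(rownames(expr)))
    stop("'expr' must have node ids as rownames")
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("S", seq_len(ncol(expr)))
  if (!is.null(names(kind))) kind <- kind[rownames(expr)]
  if (length(kind) != nrow(expr))
    stop("'kind' must have one entry per row of 'expr'")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr),
    rowData = S4Vectors::DataFrame(kind = unname(kind)),
    metadata = list(condition = condition))
  methods::new("ExpressionDataset", se)
}

#' Accessors for ExpressionDataset
#'
#' `exprValues()` returns the node-by-sample matrix, `nodeKinds()` the named
#' kind vector, and `conditionLabel()` the condition label.
#'
#' @param x an [ExpressionDataset][ExpressionDataset-class].
#' @return A matrix, named character vector, or scalar label respectively.
#' @export
exprValues <- function(x) {
  stopifnot(methods::is(x, "ExpressionDataset"))
  SummarizedExperiment::assay(x, "expr")
}

#' @rdname exprValues
#' @export
nodeKinds <- function(x) {
  stopifnot(methods::is(x, "ExpressionDataset"))
  stats::setNames(SummarizedExperiment::rowData(x)$kind, rownames(x))
}

#' @rdname exprValues
#' @export
conditionLabel <- function(x) {
  stopifnot(methods::is(x, "ExpressionDataset"))
  cond <- S4Vectors::metadata(x)$condition
  if (is.null(cond)) NA_character_ else cond
}

setMethod("show", "ExpressionDataset", function(object) {
  kinds <- table(nodeKinds(object))
  cat(sprintf("ExpressionDataset: %d nodes x %d samples (condition: %s)\n",
              nrow(object), ncol(object), conditionLabel(object)))
  cat("  node kinds:",
      paste(sprintf("%s=%d", names(kinds), as.integer(kinds)), collapse = " "),
      "\n")
})
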