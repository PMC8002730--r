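## Internal helpers.

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

## stable numeric formatting so written files are byte-reproducible
.fmtNum <- function(x) {
  out <- vapply(x, function(v) sprintf("%.15g", v), character(1L))
  out[is.na(x)] <- "NA"
  out
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

.assertFraction <- function(x, name, lo = 0, hi = 1, loOpen = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x > hi || x < lo || (loOpen && x == lo))
    stop(sprintf("'%s' must be a number in %s%g, %g]", name,
                 if (loOpen) "(" else "[", lo, hi))
  as.numeric(x)
}

## edge identity key used for set algebra over edge tables
.edgeKey <- function(edges) {
  if (!nrow(edges)) return(character(0))
  ifelse(edges$edge_type == "ppi",
         paste(pmin(edges$source_id, edges$target_id),
               pmax(edges$source_id, edges$target_id), "ppi", sep = "|"),
         paste(edges$source_id, edges$target_id, edges$edge_type, sep = "|"))
}

.emptyEdgeTable <- function(extra = character(0)) {
  base <- data.frame(source_id = character(0), target_id = character(0),
                     edge_type = character(0), stringsAsFactors = FALSE)
  for (col in extra) base[[col]] <- numeric(0)
  base
}
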