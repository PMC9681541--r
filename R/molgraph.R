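#' Construct a molecular graph from an edge list
#'
#' @param edges two-column character matrix (or object coercible to one),
#'   one unordered edge per row.
#' @param vertices optional character vector of vertex identifiers; defaults
#'   to the endpoints appearing in `edges`.
#' @return a validated [MolecularGraph-class] object.
#' @examples
#' molecularGraph(rbind(c("a", "b"), c("b", "c")))
#' @export
molecularGraph <- function(edges, vertices = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have exactly two columns")
  storage.mode(edges) <- "character"
  if (is.null(vertices)) vertices <- unique(as.vector(t(edges)))
  new("MolecularGraph", vertices = as.character(vertices), edges = edges)
}

#' Read a hydrogen-suppressed molecular graph from an edge-list file
#'
#' Format: UTF-8 text, one edge per line as two whitespace-separated vertex
#' tokens; blank lines and lines starting with `#` are skipped. One graph per
#' file. The graph must be simple and connected; violations are errors that
#' name the offending line where possible.
#'
#' @param path path to the edge-list file.
#' @return a validated [MolecularGraph-class] object.
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c", "# comment", "c a"), f)
#' readEdgeList(f)
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L)
    stop("edge-list file contains no edges: ", path)
  toks <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad))
    stop(sprintf("line %d of %s: expected two vertex tokens, got %d",
      keep[bad[1L]], path, lengths(toks)[bad[1L]]))
  e <- do.call(rbind, toks)
  if (any(e[, 1L] == e[, 2L])) {
    i <- which(e[, 1L] == e[, 2L])[1L]
    stop(sprintf("line %d of %s: self-loop on vertex '%s'",
      keep[i], path, e[i, 1L]))
  }
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("line %d of %s: duplicate edge %s-%s",
      keep[i], path, e[i, 1L], e[i, 2L]))
  }
  molecularGraph(e)
}

#' @describeIn vertexDegrees number of vertices
#' @export
vertexCount <- function(g) length(g@vertices)

#' Graph accessors
#'
#' `vertexDegrees` returns the degree (adjacent-vertex count) of every vertex;
#' `edgeCount` and `vertexCount` return graph sizes; `edgeMatrix` and
#' `vertexNames` expose the underlying edge list and vertex identifiers.
#'
#' @param g a [MolecularGraph-class].
#' @return `vertexDegrees`: named integer vector over all vertices (isolated
#'   vertices cannot occur in a valid connected graph of >= 2 vertices).
#' @examples
#' g <- molecularGraph(rbind(c("a", "b"), c("b", "c")))
#' vertexDegrees(g)   # a: 1, b: 2, c: 1
#' @export
vertexDegrees <- function(g) {
  tab <- table(factor(as.vector(g@edges), levels = g@vertices))
  stats::setNames(as.integer(tab), names(tab))
}

#' @describeIn vertexDegrees number of edges
#' @export
edgeCount <- function(g) {
  if (is(g, "EdgePartition")) return(sum(g@counts$count))
  nrow(g@edges)
}

#' @describeIn vertexDegrees edge list as a two-column character matrix
#' @export
edgeMatrix <- function(g) g@edges

#' @describeIn vertexDegrees vertex identifiers
#' @export
vertexNames <- function(g) g@vertices

#' Build an edge partition
#'
#' Tallies, for every edge uv, the unordered endpoint-degree pair
#' (min(d_u, d_v), max(d_u, d_v)). The resulting class counts |E_{m,n}| are a
#' sufficient statistic for all nine degree-based indices.
#'
#' `edgePartition(g)` derives the partition from a graph;
#' `edgePartitionFromCounts()` builds one directly from printed class counts.
#'
#' @param g a [MolecularGraph-class].
#' @return an [EdgePartition-class]; counts sum to the edge count of `g`.
#' @examples
#' g <- molecularGraph(rbind(c("a", "b"), c("b", "c")))
#' edgePartition(g)   # E_{1,2} = 2
#' @export
edgePartition <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  deg <- vertexDegrees(g)
  du <- deg[g@edges[, 1L]]
  dv <- deg[g@edges[, 2L]]
  m <- pmin(du, dv)
  n <- pmax(du, dv)
  agg <- stats::aggregate(
    list(count = rep.int(1L, length(m))),
    by = list(m = as.integer(m), n = as.integer(n)), FUN = sum)
  agg <- agg[order(agg$m, agg$n), , drop = FALSE]
  rownames(agg) <- NULL
  new("EdgePartition", counts = agg)
}

#' @rdname edgePartition
#' @param m,n,count parallel integer vectors of degree pairs (m <= n after
#'   canonicalisation, which is applied automatically) and their edge counts.
#' @export
edgePartitionFromCounts <- function(m, n, count) {
  d <- data.frame(m = as.integer(pmin(m, n)), n = as.integer(pmax(m, n)),
                  count = as.integer(count))
  d <- d[order(d$m, d$n), , drop = FALSE]
  rownames(d) <- NULL
  new("EdgePartition", counts = d)
}

#' @rdname edgePartition
#' @param p an [EdgePartition-class].
#' @return `partitionCounts`: the underlying data.frame of m, n, count.
#' @export
partitionCounts <- function(p) p@counts
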