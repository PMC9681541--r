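# Per-edge terms of the nine degree-based topological indices. Each is a
# symmetric function t(m, n) of the endpoint degrees; an index value is the
# sum of t over edges, i.e. sum over degree classes of |E_{m,n}| * t(m, n).
#
#   ABC  atom-bond connectivity  sqrt((m + n - 2) / (m * n))
#   RA   Randic                  1 / sqrt(m * n)
#   S    sum-connectivity        1 / sqrt(m + n)
#   GA   geometric-arithmetic    2 * sqrt(m * n) / (m + n)
#   M1   first Zagreb            m + n
#   M2   second Zagreb           m * n
#   H    harmonic                2 / (m + n)
#   HM   hyper-Zagreb            (m + n)^2
#   F    forgotten               m^2 + n^2
.edge_terms <- list(
  ABC = function(m, n) sqrt((m + n - 2) / (m * n)),
  RA  = function(m, n) 1 / sqrt(m * n),
  S   = function(m, n) 1 / sqrt(m + n),
  GA  = function(m, n) 2 * sqrt(m * n) / (m + n),
  M1  = function(m, n) m + n,
  M2  = function(m, n) m * n,
  H   = function(m, n) 2 / (m + n),
  HM  = function(m, n) (m + n)^2,
  F   = function(m, n) m^2 + n^2
)

#' Canonical topological index names
#'
#' @return the nine supported index identifiers in canonical reporting order:
#'   ABC, RA, S, GA, M1, M2, H, HM, F.
#' @export
indexNames <- function() names(.edge_terms)

.match_index <- function(name) {
  nm <- toupper(as.character(name))
  if (length(nm) != 1L || !nm %in% names(.edge_terms))
    stop("unknown index name '", name, "'; valid names: ",
         paste(names(.edge_terms), collapse = ", "))
  nm
}

#' Compute a degree-based topological index from an edge partition
#'
#' Evaluates the named index as the partition-weighted sum
#' sum_{(m,n)} |E_{m,n}| * t(m, n), where t is the per-edge term of the index
#' definition. Computation is at full floating precision; rounding to the
#' 2-decimal convention of descriptor tables is presentation only
#' (see [roundHalfUp()]).
#'
#' @param p an [EdgePartition-class] (non-empty).
#' @param name index identifier, case-insensitive, one of [indexNames()].
#' @return a single numeric value; M1, M2, HM and F are exact integers for
#'   integer degree data.
#' @examples
#' psoralen <- edgePartitionFromCounts(
#'   m = c(1, 2, 2, 3), n = c(3, 2, 3, 3), count = c(1, 3, 10, 2))
#' computeIndex(psoralen, "M1")   # 78
#' computeIndex(psoralen, "ABC")  # 11.34 at 2 decimals
#' @export
computeIndex <- function(p, name) {
  stopifnot(is(p, "EdgePartition"))
  d <- p@counts
  if (nrow(d) == 0L) stop("empty edge partition")
  term <- .edge_terms[[.match_index(name)]]
  sum(d$count * term(d$m, d$n))
}

#' Compute all nine indices of an edge partition
#'
#' @inheritParams computeIndex
#' @return named numeric vector in canonical order (see [indexNames()]).
#' @examples
#' computeAllIndices(edgePartitionFromCounts(2, 2, 6))  # 6-cycle
#' @export
computeAllIndices <- function(p) {
  vapply(indexNames(), function(nm) computeIndex(p, nm), numeric(1))
}

#' Compute an index directly from a graph by summing over edges
#'
#' Independent evaluation path: instead of aggregating the edge partition,
#' the per-edge term is summed edge by edge from the endpoint degrees. Used
#' as an internal cross-check of the partition route; the two agree to
#' floating-point accuracy on every valid graph.
#'
#' @param g a [MolecularGraph-class].
#' @param name index identifier, one of [indexNames()].
#' @return a single numeric value.
#' @examples
#' g <- molecularGraph(rbind(c("a", "b"), c("b", "c")))
#' computeIndexFromGraph(g, "RA")  # sqrt(2)
#' @export
computeIndexFromGraph <- function(g, name) {
  stopifnot(is(g, "MolecularGraph"))
  if (nrow(g@edges) == 0L) stop("graph has no edges")
  term <- .edge_terms[[.match_index(name)]]
  deg <- vertexDegrees(g)
  du <- as.numeric(deg[g@edges[, 1L]])
  dv <- as.numeric(deg[g@edges[, 2L]])
  sum(term(pmin(du, dv), pmax(du, dv)))
}

#' Round half away from zero
#'
#' Descriptor tables in the QSPR literature round half-up (11.335 -> 11.34),
#' unlike R's round-half-even. Used only for presentation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}
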