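#' @import methods
NULL

#' Hydrogen-suppressed molecular graph
#'
#' An undirected, simple, connected graph whose vertices are heavy
#' (non-hydrogen) atoms and whose edges are bonds with multiplicity collapsed.
#' Vertex identifiers are arbitrary non-whitespace tokens; element labels are
#' not needed because every descriptor computed here depends on vertex degrees
#' only.
#'
#' @slot vertices character vector of unique vertex identifiers.
#' @slot edges two-column character matrix; each row is one unordered edge.
#'
#' @seealso [readEdgeList()], [edgePartition()], [vertexDegrees()]
#' @export
setClass("MolecularGraph",
  representation(vertices = "character", edges = "matrix"))

setValidity("MolecularGraph", function(object) {
  v <- object@vertices
  e <- object@edges
  msgs <- character()
  if (length(v) < 1L) msgs <- c(msgs, "graph must have at least one vertex")
  if (anyDuplicated(v)) msgs <- c(msgs, "duplicate vertex identifiers")
  if (!is.character(e) || ncol(e) != 2L)
    return("edges must be a two-column character matrix")
  if (nrow(e) > 0L) {
    if (!all(e %in% v))
      msgs <- c(msgs, "edge endpoint not among declared vertices")
    if (any(e[, 1L] == e[, 2L])) msgs <- c(msgs, "self-loop present")
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate edge present")
  }
  if (length(msgs) == 0L && length(v) > 1L) {
    comp <- igraph::components(
      igraph::graph_from_data_frame(
        as.data.frame(e, stringsAsFactors = FALSE),
        directed = FALSE, vertices = data.frame(name = v)))
    if (comp$no > 1L)
      msgs <- c(msgs, sprintf(
        "graph is disconnected: %d components of sizes %s",
        comp$no, paste(sort(comp$csize, decreasing = TRUE), collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Endpoint-degree edge partition
#'
#' Counts of edges per unordered endpoint-degree class: an edge joining
#' vertices of degree m and n belongs to class E_{m,n} with m <= n. All nine
#' degree-based topological indices supported by this package are symmetric
#' per-edge functions of (m, n), so a partition determines every index value.
#'
#' @slot counts data.frame with integer columns `m`, `n` (m <= n, both >= 1)
#'   and `count` (positive); one row per occupied degree class.
#'
#' @seealso [edgePartition()], [computeIndex()]
#' @export
setClass("EdgePartition", representation(counts = "data.frame"))

setValidity("EdgePartition", function(object) {
  d <- object@counts
  if (!all(c("m", "n", "count") %in% names(d)))
    return("counts must have columns m, n, count")
  if (nrow(d) == 0L) return(TRUE)
  if (any(d$m < 1L) || any(d$n < 1L)) return("degrees must be >= 1")
  if (any(d$m > d$n)) return("degree pairs must be canonical (m <= n)")
  if (any(d$count < 1L) || any(d$count != round(d$count)))
    return("counts must be positive integers")
  if (anyDuplicated(paste(d$m, d$n))) return("duplicate degree class")
  TRUE
})

#' Univariate structure-property regression fit
#'
#' Ordinary least-squares fit of one physicochemical property P on one
#' topological index TI under the model P = A + b * TI, with the diagnostic
#' statistics conventional in QSPR reporting: Pearson r, coefficient of
#' determination r^2, standard error of estimate sqrt(SSE / (n - 2)), and the
#' single-predictor F test on (1, n - 2) degrees of freedom.
#'
#' @slot intercept,slope OLS estimates A and b.
#' @slot n sample size after pairwise deletion of missing values.
#' @slot r,r2 Pearson correlation and its square.
#' @slot se standard error of estimate, in property units.
#' @slot fstat,pvalue F statistic and its upper-tail p value; `fstat` is
#'   `Inf` for an exact linear relationship.
#' @slot index,property labels of the descriptor and response.
#'
#' @seealso [fitPropertyModel()], [predictProperty()]
#' @export
setClass("TopoRegression",
  representation(intercept = "numeric", slope = "numeric", n = "integer",
    r = "numeric", r2 = "numeric", se = "numeric", fstat = "numeric",
    pvalue = "numeric", index = "character", property = "character"))

setValidity("TopoRegression", function(object) {
  if (object@n < 3L) return("n must be >= 3")
  if (abs(object@r) > 1 + 1e-12) return("r outside [-1, 1]")
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12) return("r2 outside [0, 1]")
  if (abs(object@r2 - object@r^2) > 1e-12) return("r2 must equal r^2")
  if (object@se < 0) return("se must be non-negative")
  TRUE
})

setMethod("show", "MolecularGraph", function(object) {
  deg <- vertexDegrees(object)
  cat(sprintf("MolecularGraph: %d vertices, %d edges, max degree %d\n",
    length(object@vertices), nrow(object@edges),
    if (length(deg)) max(deg) else 0L))
})

setMethod("show", "EdgePartition", function(object) {
  d <- object@counts
  cat(sprintf("EdgePartition: %d edges in %d degree classes\n",
    sum(d$count), nrow(d)))
  if (nrow(d))
    cat(paste(sprintf("  E_{%d,%d} = %d", d$m, d$n, d$count), collapse = "\n"),
        "\n")
})

setMethod("show", "TopoRegression", function(object) {
  cat(sprintf("TopoRegression: %s = %.4g %+.4g * %s  (n = %d)\n",
    object@property, object@intercept, object@slope, object@index, object@n))
  cat(sprintf("  r = %.4f, r2 = %.4f, SE = %.4g, F(1,%d) = %.4g, p = %.4g\n",
    object@r, object@r2, object@se, object@n - 2L, object@fstat,
    object@pvalue))
})
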