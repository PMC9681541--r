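# Seeded generators of chemistry-like random graphs and synthetic linear
# property data, for end-to-end validation with known ground truth. Only the
# degree structure matters to the indices, so the generator makes no attempt
# at realistic rings or heteroatom patterns; it guarantees simplicity,
# connectivity and a valence-like degree cap.

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Generate a random connected graph with bounded degrees
#'
#' Construction: a random spanning tree grown vertex by vertex, each new
#' vertex attaching to a uniformly chosen existing vertex with spare degree
#' capacity, followed by `extraEdges` additional edges drawn uniformly from
#' the non-adjacent pairs whose endpoints are both below the cap (fewer are
#' added if the cap exhausts the candidates). The default cap of 4 mirrors
#' carbon valence in a hydrogen-suppressed skeleton.
#'
#' @param nVertices number of vertices (>= 2).
#' @param maxDegree degree cap (>= 1); `maxDegree = 1` is only feasible for
#'   `nVertices = 2`.
#' @param seed integer seed; the same seed always yields the same graph.
#' @param extraEdges number of extra edges beyond the spanning tree
#'   requested; default `NULL` draws it uniformly from 0 to
#'   `floor(nVertices / 4)`.
#' @return a validated [MolecularGraph-class] with vertices "v1".."vN".
#' @examples
#' g <- randomMolecularGraph(20, maxDegree = 3, seed = 7)
#' max(vertexDegrees(g))  # <= 3
#' @export
randomMolecularGraph <- function(nVertices, maxDegree = 4, seed,
                                 extraEdges = NULL) {
  stopifnot(nVertices >= 2, maxDegree >= 1)
  if (maxDegree == 1 && nVertices > 2)
    stop("infeasible: maxDegree 1 cannot connect more than 2 vertices")
  .with_seed(seed, {
    v <- paste0("v", seq_len(nVertices))
    deg <- integer(nVertices)
    edges <- matrix(character(), 0L, 2L)
    for (i in seq_len(nVertices)[-1L]) {
      open <- which(deg[seq_len(i - 1L)] < maxDegree)
      if (length(open) == 0L)
        stop("infeasible: degree cap exhausted while growing spanning tree")
      j <- open[sample.int(length(open), 1L)]
      edges <- rbind(edges, c(v[j], v[i]))
      deg[j] <- deg[j] + 1L
      deg[i] <- deg[i] + 1L
    }
    nExtra <- if (is.null(extraEdges))
      sample.int(nVertices %/% 4L + 1L, 1L) - 1L else extraEdges
    if (nExtra > 0L) {
      # adjacency keyed by vertex index pair (tree edges have j < i)
      adj <- paste(match(edges[, 1L], v), match(edges[, 2L], v))
      for (k in seq_len(nExtra)) {
        open <- which(deg < maxDegree)
        if (length(open) < 2L) break
        cand <- utils::combn(open, 2L)   # columns sorted: first < second
        key <- paste(cand[1L, ], cand[2L, ])
        cand <- cand[, !(key %in% adj), drop = FALSE]
        if (ncol(cand) == 0L) break
        pick <- cand[, sample.int(ncol(cand), 1L)]
        edges <- rbind(edges, v[pick])
        adj <- c(adj, paste(pick[1L], pick[2L]))
        deg[pick] <- deg[pick] + 1L
      }
    }
    molecularGraph(edges, vertices = v)
  })
}

#' Simulate property values from the linear QSPR model
#'
#' Generates P = A + b * TI + eps with eps ~ Normal(0, noiseSd^2) i.i.d.;
#' `noiseSd = 0` returns the exact line.
#'
#' @param x numeric vector of index values.
#' @param intercept,slope true model coefficients A and b.
#' @param noiseSd standard deviation of the Gaussian noise (>= 0).
#' @param seed integer seed (reproducible draws).
#' @return numeric vector of simulated property values.
#' @export
linearProperty <- function(x, intercept, slope, noiseSd = 0, seed = NULL) {
  stopifnot(noiseSd >= 0)
  .with_seed(seed,
    intercept + slope * as.numeric(x) + stats::rnorm(length(x), 0, noiseSd))
}

#' Parameter-recovery experiment on synthetic molecules
#'
#' Generates `nMolecules` random graphs, computes the named index for each,
#' simulates properties from the true line, refits with
#' [fitPropertyModel()], and reports estimates alongside the truth. With
#' `noiseSd = 0` the estimates recover the truth to floating-point accuracy;
#' with noise, absolute errors shrink as `nMolecules` grows.
#'
#' @param nMolecules number of molecules (>= 3).
#' @param index index identifier, one of [indexNames()].
#' @param intercept,slope,noiseSd true generating model.
#' @param seed master integer seed; per-molecule graph seeds and the noise
#'   seed are derived from it and reported for replay.
#' @param nVertices vertex-count range for the random graphs (inclusive).
#' @param maxDegree degree cap passed to [randomMolecularGraph()].
#' @return list with elements `truth` (named A, b), `estimate` (named A, b),
#'   `abs_error`, `r`, `fit` (the [TopoRegression-class]), `ti` (index
#'   values), `seeds` (per-molecule graph seeds and noise seed).
#' @export
recoveryExperiment <- function(nMolecules, index, intercept, slope,
                               noiseSd = 0, seed, nVertices = c(8, 30),
                               maxDegree = 4) {
  stopifnot(nMolecules >= 3)
  index <- .match_index(index)
  sizes <- .with_seed(seed,
    sample(seq.int(nVertices[1L], nVertices[2L]), nMolecules, replace = TRUE))
  graphSeeds <- seed + seq_len(nMolecules)
  noiseSeed <- seed + nMolecules + 1L
  ti <- vapply(seq_len(nMolecules), function(i) {
    g <- randomMolecularGraph(sizes[i], maxDegree, seed = graphSeeds[i])
    computeIndex(edgePartition(g), index)
  }, numeric(1))
  y <- linearProperty(ti, intercept, slope, noiseSd, seed = noiseSeed)
  fit <- fitPropertyModel(ti, y, index = index, property = "synthetic")
  est <- fitCoefficients(fit)
  list(
    truth = c(A = intercept, b = slope),
    estimate = c(A = est[["intercept"]], b = est[["slope"]]),
    abs_error = c(A = abs(est[["intercept"]] - intercept),
                  b = abs(est[["slope"]] - slope)),
    r = fit@r, fit = fit, ti = ti,
    seeds = list(graphs = graphSeeds, noise = noiseSeed))
}

#' Write a synthetic descriptor/property dataset
#'
#' Generates random molecules and noisy linear properties for one index and
#' writes them as descriptor and property CSVs in the same dialect the QSPR
#' reporting functions consume.
#'
#' @inheritParams recoveryExperiment
#' @param outDir output directory (created if absent).
#' @param property name of the simulated property column.
#' @param force overwrite existing files.
#' @return invisibly, the paths of the two files written.
#' @export
simulateDataset <- function(nMolecules, index, intercept, slope,
                            noiseSd, seed, outDir, property = "synthetic",
                            nVertices = c(8, 30), maxDegree = 4,
                            force = FALSE) {
  index <- .match_index(index)
  sizes <- .with_seed(seed,
    sample(seq.int(nVertices[1L], nVertices[2L]), nMolecules, replace = TRUE))
  names <- sprintf("mol%03d", seq_len(nMolecules))
  desc <- do.call(rbind, lapply(seq_len(nMolecules), function(i) {
    p <- edgePartition(
      randomMolecularGraph(sizes[i], maxDegree, seed = seed + i))
    as.data.frame(as.list(computeAllIndices(p)))
  }))
  desc <- cbind(name = names, desc)
  y <- linearProperty(desc[[index]], intercept, slope, noiseSd,
                      seed = seed + nMolecules + 1L)
  props <- data.frame(name = names, y)
  names(props)[2L] <- property
  paths <- file.path(outDir, c("synthetic_descriptors.csv",
                               "synthetic_properties.csv"))
  .write_report_csv(desc, paths[1L], force = force,
    meta = sprintf("synthetic dataset; index %s; A=%g b=%g sd=%g seed=%d",
                   index, intercept, slope, noiseSd, seed))
  .write_report_csv(props, paths[2L], force = force,
    meta = sprintf("synthetic dataset; index %s; A=%g b=%g sd=%g seed=%d",
                   index, intercept, slope, noiseSd, seed))
  invisible(paths)
}
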