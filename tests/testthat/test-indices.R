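psoralen <- edgePartitionFromCounts(
  m = c(1, 2, 2, 3), n = c(3, 2, 3, 3), count = c(1, 3, 10, 2))
azathioprine <- edgePartitionFromCounts(
  m = c(1, 1, 2, 2, 3), n = c(2, 3, 2, 3, 3), count = c(1, 1, 5, 9, 4))

test_that("worked partitions reproduce the published index values", {
  expect_equal(computeIndex(psoralen, "M1"), 78)
  expect_equal(computeIndex(psoralen, "M2"), 93)
  expect_equal(computeIndex(psoralen, "F"), 200)
  expect_equal(computeIndex(psoralen, "HM"), 386)
  expect_equal(roundHalfUp(computeIndex(psoralen, "ABC"), 2), 11.34)
  expect_equal(roundHalfUp(computeIndex(psoralen, "S"), 2), 7.29)
  expect_equal(roundHalfUp(computeIndex(psoralen, "GA"), 2), 15.66)
  expect_equal(roundHalfUp(computeIndex(psoralen, "H"), 2), 6.67)

  expect_equal(computeIndex(azathioprine, "M1"), 96)
  expect_equal(computeIndex(azathioprine, "M2"), 115)
  expect_equal(computeIndex(azathioprine, "F"), 244)
  expect_equal(computeIndex(azathioprine, "HM"), 474)
  expect_equal(roundHalfUp(computeIndex(azathioprine, "S"), 2), 9.24)
  expect_equal(roundHalfUp(computeIndex(azathioprine, "RA"), 2), 8.79)
  expect_equal(roundHalfUp(computeIndex(azathioprine, "H"), 2), 8.60)
})

test_that("degenerate and closed-form partitions evaluate exactly", {
  single <- edgePartitionFromCounts(1, 1, 1)
  expect_equal(computeIndex(single, "ABC"), 0)  # (1+1-2) numerator
  expect_equal(computeIndex(single, "GA"), 1)   # equal degrees
  expect_equal(computeIndex(single, "RA"), 1)

  expect_equal(computeIndex(edgePartitionFromCounts(1, 2, 2), "H"), 4 / 3)

  # single class (2,2) with k edges: closed forms, cross-checked on a k-cycle
  for (k in c(3, 7, 12)) {
    p <- edgePartitionFromCounts(2, 2, k)
    expect_equal(computeAllIndices(p)[c("M1", "M2", "F", "HM", "H", "RA", "GA")],
      c(M1 = 4 * k, M2 = 4 * k, F = 8 * k, HM = 16 * k, H = k / 2,
        RA = k / 2, GA = k))
    expect_equal(computeIndexFromGraph(cycle_graph(k), "M1"), 4 * k)
  }

  expect_equal(computeIndexFromGraph(cycle_graph(6), "M1"), 24)
  expect_equal(computeIndexFromGraph(path_graph(3), "RA"), sqrt(2))
  expect_equal(computeIndexFromGraph(star_graph(3), "F"), 30)
})

test_that("unknown names and empty partitions are rejected; names are case-insensitive", {
  expect_error(computeIndex(psoralen, "WIENER"), "unknown index")
  expect_error(
    computeIndex(new("EdgePartition",
      counts = data.frame(m = integer(), n = integer(), count = integer())),
      "M1"),
    "empty")
  expect_equal(computeIndex(psoralen, "abc"), computeIndex(psoralen, "ABC"))
  expect_equal(names(computeAllIndices(psoralen)),
               c("ABC", "RA", "S", "GA", "M1", "M2", "H", "HM", "F"))
})

test_that("partition route, direct edge-sum and brute force agree on random graphs", {
  for (seed in 1:40) {
    g <- randomMolecularGraph(sample(4:35, 1), maxDegree = 4, seed = seed)
    p <- edgePartition(g)
    for (nm in indexNames()) {
      a <- computeIndex(p, nm)
      b <- computeIndexFromGraph(g, nm)
      expect_equal(a, b, tolerance = 1e-12)
      expect_equal(a, brute_force_index(g, nm), tolerance = 1e-12)
    }
  }
})

test_that("algebraic identities hold: HM = F + 2*M2 and M1 = sum of squared degrees", {
  for (seed in 41:70) {
    g <- randomMolecularGraph(sample(4:35, 1), maxDegree = 4, seed = seed)
    v <- computeAllIndices(edgePartition(g))
    expect_identical(v[["HM"]], v[["F"]] + 2 * v[["M2"]])
    expect_equal(v[["M1"]], sum(vertexDegrees(g)^2))
  }
  # and on the worked partitions, exactly
  for (p in list(psoralen, azathioprine)) {
    v <- computeAllIndices(p)
    expect_identical(v[["HM"]], v[["F"]] + 2 * v[["M2"]])
  }
})

test_that("index inequalities and monotonicity hold", {
  for (seed in 71:90) {
    g <- randomMolecularGraph(sample(4:30, 1), maxDegree = 4, seed = seed)
    p <- edgePartition(g)
    v <- computeAllIndices(p)
    ne <- edgeCount(g)
    expect_lte(v[["H"]], v[["RA"]] + 1e-12)    # AM-GM per edge
    expect_lte(v[["GA"]], ne + 1e-12)
    expect_lte(v[["M1"]], v[["HM"]])

    # adding a class strictly increases the additive integer indices
    d <- partitionCounts(p)
    grown <- edgePartitionFromCounts(c(d$m, 5), c(d$n, 6),
                                     c(d$count, 1))
    for (nm in c("M1", "M2", "F", "HM"))
      expect_gt(computeIndex(grown, nm), v[[nm]])
  }
  # GA equals |E| iff every class has m = n
  expect_equal(computeIndex(edgePartitionFromCounts(2, 2, 9), "GA"), 9)
  expect_lt(computeIndex(edgePartitionFromCounts(1, 2, 9), "GA"), 9)
})

test_that("half-up rounding is a presentation-only convention", {
  expect_equal(roundHalfUp(6.8265, 2), 6.83)
  expect_equal(roundHalfUp(11.3422, 2), 11.34)
  expect_equal(roundHalfUp(-2.5, 0), -3)
  expect_equal(roundHalfUp(274.4632, 3), 274.463)
})
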