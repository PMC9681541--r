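# Small graph builders and edge-list files used across the suite.

path_graph <- function(n, prefix = "p") {
  v <- paste0(prefix, seq_len(n))
  molecularGraph(cbind(v[-n], v[-1L]))
}

cycle_graph <- function(n, prefix = "c") {
  v <- paste0(prefix, seq_len(n))
  molecularGraph(cbind(v, v[c(seq_len(n)[-1L], 1L)]))
}

star_graph <- function(nLeaves, center = "x") {
  molecularGraph(cbind(center, paste0("leaf", seq_len(nLeaves))))
}

write_edge_file <- function(lines) {
  f <- tempfile(fileext = ".edges")
  writeLines(lines, f)
  f
}

# brute-force oracle: index as an explicit loop over edges, independent of
# the package's vectorised partition and edge-sum paths
brute_force_index <- function(g, name) {
  deg <- vertexDegrees(g)
  e <- edgeMatrix(g)
  terms <- list(
    ABC = function(a, b) sqrt((a + b - 2) / (a * b)),
    RA = function(a, b) 1 / sqrt(a * b),
    S = function(a, b) 1 / sqrt(a + b),
    GA = function(a, b) 2 * sqrt(a * b) / (a + b),
    M1 = function(a, b) a + b,
    M2 = function(a, b) a * b,
    H = function(a, b) 2 / (a + b),
    HM = function(a, b) (a + b)^2,
    F = function(a, b) a^2 + b^2)
  total <- 0
  for (i in seq_len(nrow(e)))
    total <- total + terms[[name]](deg[[e[i, 1L]]], deg[[e[i, 2L]]])
  total
}
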