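# Independent oracles used across the test files.

# Brute-force clustering oracle: pairwise distance matrix, adjacency at
# strictly < eps, connected components via igraph.  Independent of the
# package's queue-based region-expansion implementation.
brute_force_components <- function(xyz, eps) {
  n <- nrow(xyz)
  if (n == 0L) return(integer())
  d <- as.matrix(stats::dist(xyz))
  adj <- d < eps
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel isolated points as 0 (noise), clusters as 1..k like the scorer
  sizes <- table(comp)
  lab <- integer(n)
  k <- 0L
  for (cl in names(sizes)[sizes >= 2]) {
    k <- k + 1L
    lab[comp == as.integer(cl)] <- k
  }
  lab
}

# Classify oracle components into SSB/sDSB/cDSB with the same rules as the
# scorer, but from the oracle labels.
brute_force_summary <- function(breaks, eps, strandless = FALSE) {
  lab <- brute_force_components(as.matrix(breaks[, c("x", "y", "z")]), eps)
  n_ssb <- sum(lab == 0L)
  sdsb <- cdsb <- 0L
  for (cl in setdiff(unique(lab), 0L)) {
    idx <- lab == cl
    size <- sum(idx)
    both <- strandless || length(unique(breaks$strand[idx])) == 2L
    if (both && size == 2L) sdsb <- sdsb + 1L
    else if (both && size >= 3L) cdsb <- cdsb + 1L
    else n_ssb <- n_ssb + size
  }
  list(n_ssb = n_ssb, n_sdsb = sdsb, n_cdsb = cdsb)
}

# Fine-step Euler integration of dE/dx down a path; independent of the
# range-inversion route used by residual_energy().
euler_residual <- function(E0, path, table = alphacell::default_stopping_table,
                           step = 1e-3) {
  tab <- alphacell::load_stopping_table()
  E <- E0
  travelled <- 0
  while (travelled < path && E > 0.05) {
    s <- alphacell::stopping_power(E, tab)
    dl <- min(step, path - travelled)
    E <- E - s * dl
    travelled <- travelled + dl
  }
  max(E, 0)
}

# deterministic small RNG helper for parameterised cases
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(code)
}
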