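# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain normal equations, an explicit double loop
# over clusters, and base-R aggregation.

oracle_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

oracle_cluster_vcov <- function(X, resid, cluster) {
  bread <- solve(crossprod(X))
  p <- ncol(X)
  meat <- matrix(0, p, p)
  for (g in unique(cluster)) {
    i <- which(cluster == g)
    sg <- t(X[i, , drop = FALSE]) %*% resid[i]
    meat <- meat + sg %*% t(sg)
  }
  bread %*% meat %*% bread
}

# tiny deterministic dataset used by several tests
fixture_trial <- function() {
  simulate_trial(K = 4, n_staff = 5, scenario = 9, seed = 42)
}

# brute-force enumeration of all region-stratified half-split allocations,
# returned as a list of arm-1 cluster-id vectors
enumerate_half_splits <- function(clusters) {
  regions <- split(clusters$cluster_id, clusters$region)
  per <- lapply(regions, function(ids) {
    utils::combn(ids, length(ids) %/% 2, simplify = FALSE)
  })
  grids <- expand.grid(lapply(per, seq_along))
  lapply(seq_len(nrow(grids)), function(i) {
    unlist(lapply(seq_along(per), function(j) per[[j]][[grids[i, j]]]))
  })
}
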