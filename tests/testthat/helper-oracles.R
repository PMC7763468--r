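# Independent oracles used to cross-check the implementation.

# Exhaustive O(n^2) DBSCAN reference: full distance matrix, core mask,
# connected components of the core-core graph (igraph), border points to
# their nearest core (ties -> lowest index). Shares only the convention,
# not the code path, with dbscan_cluster().
oracle_dbscan <- function(points, eps, min_pts) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(pts))
  core <- rowSums(d <= eps) >= min_pts
  assignments <- integer(n)
  core_idx <- which(core)
  if (length(core_idx)) {
    sub <- d[core_idx, core_idx, drop = FALSE] <= eps
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    assignments[core_idx] <- comp
  }
  for (i in which(!core)) {
    cand <- core_idx[d[i, core_idx] <= eps]
    if (!length(cand)) next
    nearest <- cand[order(d[i, cand], cand)][1]
    assignments[i] <- assignments[nearest]
  }
  assignments
}

# Relabel cluster ids by first appearance so two labelings can be compared
# up to permutation of ids (noise stays 0).
canonical_labels <- function(a) {
  out <- integer(length(a))
  seen <- integer(0)
  for (i in seq_along(a)) {
    if (a[i] == 0L) next
    pos <- match(a[i], seen)
    if (is.na(pos)) {
      seen <- c(seen, a[i])
      pos <- length(seen)
    }
    out[i] <- pos
  }
  out
}

# Brute-force overlap on a 1-unit grid: fraction of the pattern interval's
# units also covered by the observed interval, as a percent of D_n.
grid_overlap_pct <- function(s_obs, d_obs, s_pat, d_pat, unit = 1) {
  grid <- seq(s_pat, s_pat + d_pat - unit, by = unit)
  covered <- grid >= s_obs & grid < s_obs + d_obs
  sum(covered) * unit * 100 / d_pat
}

# Fine-grid quadrature centroid of a membership function on [0, 1].
quadrature_centroid <- function(mu_fn, n = 200001L) {
  y <- seq(0, 1, length.out = n)
  mu <- mu_fn(y)
  num <- sum((y * mu)[-1] + (y * mu)[-n]) / 2
  den <- sum(mu[-1] + mu[-n]) / 2
  num / den
}

# Small simulated world shared by several tests.
make_sim <- function(seed = 1, days = 63) {
  generate_routine_log(routine_spec(days = days, seed = seed))
}
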