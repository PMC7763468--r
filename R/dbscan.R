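# Density-based clustering with noise labeling (DBSCAN), used to learn the
# routine from (start time, duration) points. Standard semantics: a core
# point has >= min_pts neighbors within eps (Euclidean, inclusive boundary,
# the point counts itself); clusters are the density-connected components of
# core points; a border point joins the cluster of its nearest core point
# (ties broken by lowest point index); everything else is noise.

#' DBSCAN clustering
#'
#' @param points numeric matrix (n x d) or data.frame of finite coordinates.
#' @param eps neighborhood radius (inclusive boundary); must be positive.
#' @param min_pts minimum neighborhood size (including the point itself) for
#'   a core point; must be >= 1.
#' @return List of class \code{dbscan_result}: \code{assignments} (integer
#'   vector, cluster id from 1, or 0 for noise), \code{n_clusters},
#'   \code{is_core} (logical vector). Cluster ids are assigned in order of
#'   first core-point appearance, so the labeling is deterministic.
#' @export
dbscan_cluster <- function(points, eps, min_pts) {
  stopifnot(eps > 0, min_pts >= 1)
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (is.null(n) || n == 0) {
    return(structure(list(assignments = integer(0), n_clusters = 0L,
                          is_core = logical(0)), class = "dbscan_result"))
  }
  if (!all(is.finite(pts))) stop("points must be finite")
  d <- as.matrix(stats::dist(pts))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- lengths(neighbors) >= min_pts
  assignments <- integer(n)  # 0 = noise / unvisited
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || assignments[i] != 0L) next
    cluster_id <- cluster_id + 1L
    # expand the density-connected component of core points from i
    assignments[i] <- cluster_id
    frontier <- i
    while (length(frontier)) {
      nb <- unique(unlist(neighbors[frontier]))
      nxt <- nb[is_core[nb] & assignments[nb] == 0L]
      assignments[nxt] <- cluster_id
      frontier <- nxt
    }
  }
  # border points: non-core with a core neighbor -> nearest core's cluster
  border <- which(!is_core & assignments == 0L)
  for (i in border) {
    cores <- neighbors[[i]][is_core[neighbors[[i]]]]
    if (!length(cores)) next
    nearest <- cores[order(d[i, cores], cores)][1]
    assignments[i] <- assignments[nearest]
  }
  structure(list(assignments = assignments, n_clusters = cluster_id,
                 is_core = is_core), class = "dbscan_result")
}

#' @export
print.dbscan_result <- function(x, ...) {
  cat(sprintf("DBSCAN: %d cluster(s), %d point(s), %d noise\n",
              x$n_clusters, length(x$assignments), sum(x$assignments == 0L)))
  invisible(x)
}
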