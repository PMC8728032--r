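# Euclidean minimum spanning tree and the depth-first ranking used by the
# multivariate Kolmogorov-Smirnov tests.

# Prim's algorithm on the full Euclidean graph; ties broken by smallest
# vertex index (which.min's first-match rule), so the tree is deterministic
# even with duplicate points. Returns a 2-column edge matrix.
euclidean_mst <- function(x) {
  n <- nrow(x)
  if (n < 2) abort("Need at least 2 points to build a spanning tree.")
  d <- as.matrix(dist(x))
  if (!all(is.finite(d))) abort("Pairwise distances must be finite.")
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best_dist <- d[1, ]
  best_from <- rep(1L, n)
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_dist[cand])]
    edges[k, ] <- c(best_from[v], v)
    in_tree[v] <- TRUE
    upd <- !in_tree & d[v, ] < best_dist
    best_dist[upd] <- d[v, upd]
    best_from[upd] <- v
  }
  edges
}

mst_adjacency <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]
    j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

# Graph eccentricity (in edge counts) of every node of a tree, by BFS.
tree_eccentricities <- function(adj) {
  n <- length(adj)
  vapply(seq_len(n), function(s) {
    depth <- rep(NA_integer_, n)
    depth[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(depth[u])) {
          depth[u] <- depth[v] + 1L
          queue <- c(queue, u)
        }
      }
    }
    max(depth)
  }, integer(1))
}

# Subtree sizes of a rooted tree (iterative post-order).
subtree_sizes <- function(adj, root) {
  n <- length(adj)
  parent <- rep(0L, n)
  order_ <- integer(n)
  parent[root] <- -1L
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order_[k] <- v
    for (u in adj[[v]]) {
      if (parent[u] == 0L && u != root) {
        parent[u] <- v
        stack <- c(stack, u)
      }
    }
  }
  size <- rep(1L, n)
  for (v in rev(order_)) {
    if (parent[v] > 0L) size[parent[v]] <- size[parent[v]] + size[v]
  }
  list(size = size, parent = parent)
}

#' Minimum-spanning-tree ranking of multivariate samples
#'
#' Imposes a one-dimensional ordering on pooled multivariate samples, the
#' preliminary step of the MST-based Kolmogorov-Smirnov tests. In
#' `"location"` mode the Euclidean MST is rooted at a node of maximum
#' eccentricity (smallest index on ties) and samples are ranked by a
#' depth-first high-directed-preorder traversal that visits children in
#' decreasing subtree size (ties by sample index) -- points at opposite ends
#' of the tree land at opposite ends of the ranking, which is sensitive to
#' mean shifts. In `"scale"` mode samples are ranked by increasing Euclidean
#' distance from the pooled centroid, a radial ordering sensitive to spread
#' differences.
#'
#' @param pooled Samples x variables numeric matrix.
#' @param mode `"location"` or `"scale"`.
#' @return An integer vector `r`, a permutation of `1..n`, with `r[i]` the
#'   rank of sample `i`.
#' @export
mst_hdp_ranks <- function(pooled, mode = c("location", "scale")) {
  mode <- match.arg(mode)
  x <- as_sample_matrix(pooled)
  n <- nrow(x)
  if (mode == "scale") {
    radii <- sqrt(rowSums(sweep(x, 2, colMeans(x))^2))
    ranks <- integer(n)
    ranks[order(radii)] <- seq_len(n) # stable: index order on ties
    return(ranks)
  }
  adj <- mst_adjacency(euclidean_mst(x), n)
  ecc <- tree_eccentricities(adj)
  root <- which.max(ecc)
  st <- subtree_sizes(adj, root)
  visited <- logical(n)
  ranks <- integer(n)
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (visited[v]) next
    visited[v] <- TRUE
    k <- k + 1L
    ranks[v] <- k
    children <- adj[[v]][!visited[adj[[v]]]]
    if (length(children)) {
      # push smallest subtree first so the largest pops first; reversed
      # index order on size ties so the smallest index pops first
      ord <- order(st$size[children], -children)
      stack <- c(stack, children[ord])
    }
  }
  ranks
}
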