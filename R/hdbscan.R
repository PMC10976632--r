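# Hierarchical density-based clustering (HDBSCAN-style), built on
# mutual-reachability single linkage with condensed-tree excess-of-mass
# cluster selection. Suited to the moderate frame counts used here
# (full distance matrix in memory).

.hdbscan <- function(x, min_cluster_size, min_samples) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  k <- min(min_samples, n - 1)
  # core distance: distance to the k-th nearest neighbor (self excluded)
  core <- apply(d, 1, function(r) sort(r, partial = k + 1)[k + 1])
  mr <- pmax(d, matrix(core, n, n), matrix(core, n, n, byrow = TRUE))
  hc <- hclust(as.dist(mr), method = "single")
  merge <- hc$merge
  height <- hc$height

  size <- integer(n - 1)
  for (j in seq_len(n - 1)) {
    a <- merge[j, 1]
    b <- merge[j, 2]
    size[j] <- (if (a < 0) 1L else size[a]) + (if (b < 0) 1L else size[b])
  }
  node_size <- function(u) if (u < 0) 1L else size[u]
  collect <- function(node) {
    if (node < 0) return(-node)
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      nd <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (u in merge[nd, ]) {
        if (u < 0) out <- c(out, -u) else stack <- c(stack, u)
      }
    }
    out
  }
  lam <- function(h) if (h <= 1e-12) 1e12 else 1 / h

  # condensed tree: cluster bookkeeping
  parent <- integer(0)
  birth <- numeric(0)
  size_birth <- integer(0)
  sum_leave <- numeric(0)  # sum over members of the lambda at which they left
  children <- list()
  new_cluster <- function(p, b, s) {
    parent[length(parent) + 1] <<- p
    birth[length(birth) + 1] <<- b
    size_birth[length(size_birth) + 1] <<- s
    sum_leave[length(sum_leave) + 1] <<- 0
    children[[length(children) + 1]] <<- integer(0)
    length(parent)
  }

  point_cluster <- integer(n)  # condensed cluster each point fell out of
  root <- new_cluster(0L, 0, n)
  stack_node <- n - 1L
  stack_clus <- root
  while (length(stack_node)) {
    j <- stack_node[length(stack_node)]
    cl <- stack_clus[length(stack_clus)]
    stack_node <- stack_node[-length(stack_node)]
    stack_clus <- stack_clus[-length(stack_clus)]
    l <- lam(height[j])
    a <- merge[j, 1]
    b <- merge[j, 2]
    sa <- node_size(a)
    sb <- node_size(b)
    if (sa >= min_cluster_size && sb >= min_cluster_size) {
      # true split: cluster cl dies, two children are born
      sum_leave[cl] <- sum_leave[cl] + l * (sa + sb)
      ca <- new_cluster(cl, l, sa)
      cb <- new_cluster(cl, l, sb)
      children[[cl]] <- c(ca, cb)
      stack_node <- c(stack_node, a, b)
      stack_clus <- c(stack_clus, ca, cb)
    } else if (sa >= min_cluster_size || sb >= min_cluster_size) {
      big <- if (sa >= min_cluster_size) a else b
      small <- if (sa >= min_cluster_size) b else a
      pts <- collect(small)
      point_cluster[pts] <- cl
      sum_leave[cl] <- sum_leave[cl] + l * length(pts)
      stack_node <- c(stack_node, big)
      stack_clus <- c(stack_clus, cl)
    } else {
      pts <- c(collect(a), collect(b))
      point_cluster[pts] <- cl
      sum_leave[cl] <- sum_leave[cl] + l * length(pts)
    }
  }

  n_clusters_total <- length(parent)
  stability <- sum_leave - size_birth * birth

  # excess-of-mass selection; the root cluster is never reported
  selected <- logical(n_clusters_total)
  value <- numeric(n_clusters_total)
  deselect_subtree <- function(ids) {
    while (length(ids)) {
      selected[ids] <<- FALSE
      ids <- unlist(children[ids])
    }
  }
  for (cl in rev(seq_len(n_clusters_total))) {
    ch <- children[[cl]]
    if (length(ch) == 0) {
      selected[cl] <- TRUE
      value[cl] <- stability[cl]
    } else if (stability[cl] > sum(value[ch]) && cl != root) {
      selected[cl] <- TRUE
      deselect_subtree(ch)
      value[cl] <- stability[cl]
    } else {
      value[cl] <- sum(value[ch])
    }
  }
  selected[root] <- FALSE

  # a cluster that never split off the root is the root itself: with no
  # true split there is nothing to report
  labels <- integer(n)
  if (any(selected)) {
    # map each point's fallout cluster to its nearest selected ancestor
    anc <- integer(n_clusters_total)
    for (cl in seq_len(n_clusters_total)) {
      cur <- cl
      while (cur != 0 && !selected[cur]) cur <- parent[cur]
      anc[cl] <- cur
    }
    lab_of <- anc[point_cluster]
    keep <- which(selected)
    # order reported clusters by decreasing membership
    counts <- vapply(keep, function(s) sum(lab_of == s), integer(1))
    keep <- keep[order(-counts)]
    for (i in seq_along(keep)) labels[lab_of == keep[i]] <- i
  }
  attr(labels, "n_clusters") <- length(unique(labels[labels > 0]))
  labels
}
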