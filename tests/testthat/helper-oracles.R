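# Independent brute-force oracles used to verify the package's statistics.

# Benjamini-Hochberg step-up by the textbook definition:
# adj(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1, mapped back to the
# input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(pmin(m * ps[i:m] / (i:m), 1)), numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Directional UMI clustering, written independently: explicit directed
# adjacency matrix, then set expansion from the highest-count seed.
dir_cluster_oracle <- function(umis, counts, threshold = 2) {
  n <- length(umis)
  ord <- order(-counts, umis)
  umis <- umis[ord]; counts <- counts[ord]
  A <- matrix(FALSE, n, n)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u != v && hamming_str(umis[u], umis[v]) == 1 &&
        counts[u] >= threshold * counts[v] - 1)
      A[u, v] <- TRUE
  }
  assigned <- rep(FALSE, n)
  clusters <- list()
  for (seed in seq_len(n)) {
    if (assigned[seed]) next
    members <- seed
    assigned[seed] <- TRUE
    repeat {
      reach <- which(!assigned &
                     apply(A[members, , drop = FALSE], 2, any))
      if (!length(reach)) break
      assigned[reach] <- TRUE
      members <- c(members, reach)
    }
    clusters[[length(clusters) + 1L]] <-
      list(representative = umis[seed], members = sort(umis[members]),
           total = sum(counts[members]),
           rep_count = counts[seed])
  }
  clusters
}

# Connected components of a bipartite edge list by breadth-first search
# over an adjacency list (independent of igraph).
bfs_components <- function(map) {
  nodes <- unique(c(paste0("w:", map$worm), paste0("m:", map$mammal)))
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(map))) {
    w <- paste0("w:", map$worm[i]); m <- paste0("m:", map$mammal[i])
    adj[[w]] <- c(adj[[w]], m)
    adj[[m]] <- c(adj[[m]], w)
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (nd in nodes) {
    if (seen[nd]) next
    queue <- nd; seen[nd] <- TRUE; comp <- character(0)
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      comp <- c(comp, x)
      for (y in adj[[x]]) if (!seen[y]) { seen[y] <- TRUE; queue <- c(queue, y) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

random_umis <- function(n, len = 6) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
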