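# Independent oracles, deliberately implemented with different algorithms
# than the package code paths they check.

# Brute-force BFS flood fill over an edge list; returns the partition as
# an unordered list of sorted label vectors.
bfs_components <- function(node_labels, edge_from, edge_to) {
  adj <- stats::setNames(vector("list", length(node_labels)), node_labels)
  for (k in seq_along(edge_from)) {
    adj[[edge_from[k]]] <- c(adj[[edge_from[k]]], edge_to[k])
    adj[[edge_to[k]]] <- c(adj[[edge_to[k]]], edge_from[k])
  }
  unvisited <- node_labels
  comps <- list()
  while (length(unvisited)) {
    queue <- unvisited[1L]
    seen <- character(0)
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (v %in% seen) next
      seen <- c(seen, v)
      queue <- c(queue, setdiff(adj[[v]], seen))
    }
    comps[[length(comps) + 1L]] <- sort(seen)
    unvisited <- setdiff(unvisited, seen)
  }
  comps
}

# Set-of-sets comparison, order-free
same_partition <- function(a, b) {
  canon <- function(x) sort(vapply(x, function(s) paste(sort(s),
                                                        collapse = "|"),
                                   character(1)))
  identical(canon(a), canon(b))
}

# Two-pass jackknife SE through stats::var:
# sum((x - mean)^2) == (n-1) * var(x)
jackknife_se_oracle <- function(theta) {
  n <- length(theta)
  sqrt((n - 1) / n * (n - 1) * stats::var(theta))
}
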